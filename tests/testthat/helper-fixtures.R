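# Small programmatic fixtures shared across the suite.

# 3 features x 2 samples toy table with known depths 6 and 9
toy_table <- function(study = "toy") {
  m <- matrix(c(5, 1, 0, 0, 2, 7), nrow = 3,
              dimnames = list(c("OTU1", "OTU2", "OTU3"), c("sA", "sB")))
  count_table(m, study_id = study)
}

# table with prescribed per-sample depths spread over one feature each
depth_table <- function(depths, study = "d") {
  n <- length(depths)
  m <- diag(depths, nrow = n)
  dimnames(m) <- list(paste0("OTU", seq_len(n)), paste0("s", seq_len(n)))
  count_table(m, study_id = study)
}

# hand-rolled effect_2x2 carrying given log-OR and SE (for pooling tests)
fake_effect <- function(study, log_or, se) {
  structure(list(study_id = study, cells = c(a = 1, b = 1, c = 1, d = 1),
                 or = exp(log_or), log_or = log_or, se_log_or = se,
                 ci = exp(log_or + c(-1.96, 1.96) * se), corrected = FALSE),
            class = "effect_2x2")
}

# quick multi-study synthetic collection (rarefied) for integration tests
quick_collection <- function(seed = 1, n_studies = 3, n_per_arm = 15,
                             n_features = 60, n_genera = 12,
                             study_effect_sd = 0.7, planted = NULL,
                             probiotics = 0, coupling = NULL) {
  spec <- synthetic_spec(
    n_studies = n_studies, n_case = n_per_arm, n_control = n_per_arm,
    n_features = n_features, n_genera = n_genera,
    study_effect_sd = study_effect_sd, planted_features = planted,
    depth_range = c(2000, 3000), n_probiotic_features = probiotics,
    probiotic_coupling = coupling, seed = seed)
  gen <- generate_collection(spec)
  gen$collection <- suppressMessages(
    preprocess_collection(gen$collection, min_depth = 1, seed = seed))
  gen
}

expect_named_error <- function(expr, pattern) {
  expect_error(expr, pattern, fixed = FALSE)
}
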