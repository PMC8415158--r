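test_that("per-sample dispersion is the row median off the diagonal", {
  m0 <- matrix(0, 3, 3, dimnames = list(paste0("s", 1:3), paste0("s", 1:3)))
  expect_equal(unname(per_sample_dispersion(m0)), rep(0, 3))
  # 4-sample toy: hand-computed row medians excluding the diagonal
  m <- matrix(c(0, 1, 2, 7,
                1, 0, 3, 7,
                2, 3, 0, 7,
                7, 7, 7, 0), 4, 4,
              dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  disp <- per_sample_dispersion(m)
  expect_equal(unname(disp), c(2, 3, 3, 7))
  expect_equal(names(which.max(disp)), "s4")    # the outlier
  expect_equal(unname(per_sample_dispersion(m, summary = "mean")),
               c(mean(c(1, 2, 7)), mean(c(1, 3, 7)), mean(c(2, 3, 7)), 7))
  expect_error(per_sample_dispersion(m[1:2, 1:2]), ">= 3")
})

test_that("median dichotomization pools arms and counts ties as negative", {
  c1 <- dichotomize_at_median(c(1, 2, 3, 4), c("control", "control", "case", "case"))
  expect_equal(c1[c("a", "b", "c", "d")], list(a = 0, b = 2, c = 2, d = 0))
  c2 <- dichotomize_at_median(rep(5, 6), rep(c("case", "control"), 3))
  expect_equal(c2$a + c2$c, 0)
  expect_true(c2$degenerate)
  # values [5,1,4,2,3], groups (ctl,ctl,case,case,case): median 3,
  # strictly above = {5 (ctl), 4 (case)}
  c3 <- dichotomize_at_median(c(5, 1, 4, 2, 3),
                              c("control", "control", "case", "case", "case"))
  expect_equal(c3[c("a", "b", "c", "d")], list(a = 1, b = 1, c = 1, d = 2))
  expect_error(dichotomize_at_median(1:3, c("case", "case", "control")), ">= 2")
})

test_that("odds ratio, Woolf SE and Haldane correction follow the formulas", {
  e1 <- odds_ratio(list(a = 10, b = 10, c = 10, d = 10))
  expect_equal(e1$or, 1)
  e2 <- odds_ratio(list(a = 30, b = 20, c = 20, d = 30))
  expect_equal(e2$or, (30 * 30) / (20 * 20))            # 2.25
  expect_equal(e2$se_log_or, sqrt(1/30 + 1/20 + 1/20 + 1/30), tolerance = 1e-12)
  expect_equal(e2$ci, exp(log(2.25) + c(-1, 1) * qnorm(0.975) * e2$se_log_or),
               tolerance = 1e-12)
  e3 <- odds_ratio(list(a = 0, b = 10, c = 10, d = 10))
  expect_true(e3$corrected)
  expect_equal(e3$or, (0.5 * 10.5) / (10.5 * 10.5))     # = 1/21
  expect_equal(e3$se_log_or, sqrt(1/0.5 + 3/10.5), tolerance = 1e-12)
  expect_error(odds_ratio(list(a = 0, b = 0, c = 5, d = 5)), "arm is empty")
})

test_that("pooling reduces correctly under homogeneity and symmetry", {
  k <- 4; theta <- 0.7; s <- 0.25
  es <- lapply(1:k, function(i) fake_effect(paste0("S", i), theta, s))
  fe <- pool_effects(es, "FE"); re <- pool_effects(es, "RE")
  expect_equal(fe$log_or, theta, tolerance = 1e-12)
  expect_equal(fe$se, s / sqrt(k), tolerance = 1e-12)
  expect_equal(fe$Q, 0, tolerance = 1e-12)
  expect_equal(re$tau2, 0)
  expect_equal(re$log_or, fe$log_or, tolerance = 1e-12)
  expect_equal(re$ci, fe$ci, tolerance = 1e-12)
  sym <- list(fake_effect("U", 0.8, 0.2), fake_effect("D", -0.8, 0.2))
  expect_equal(pool_effects(sym, "FE")$log_or, 0, tolerance = 1e-12)
  expect_error(pool_effects(es[1]), ">= 2 studies")
})

test_that("DerSimonian-Laird pooling matches the step-by-step oracle and metafor", {
  y <- c(0.2, 0.5, 0.9); s <- c(0.1, 0.2, 0.3)
  es <- mapply(fake_effect, c("S1", "S2", "S3"), y, s, SIMPLIFY = FALSE)
  # independent arithmetic oracle, written out from the DL definitions
  w <- 1 / s^2
  theta_fe <- sum(w * y) / sum(w)
  Q <- sum(w * (y - theta_fe)^2)
  tau2 <- max(0, (Q - 2) / (sum(w) - sum(w^2) / sum(w)))
  w_re <- 1 / (s^2 + tau2)
  theta_re <- sum(w_re * y) / sum(w_re)
  fe <- pool_effects(es, "FE"); re <- pool_effects(es, "RE")
  expect_equal(fe$log_or, theta_fe, tolerance = 1e-12)
  expect_equal(fe$se, 1 / sqrt(sum(w)), tolerance = 1e-12)
  expect_equal(re$Q, Q, tolerance = 1e-12)
  expect_equal(re$tau2, tau2, tolerance = 1e-12)
  expect_equal(re$log_or, theta_re, tolerance = 1e-12)
  expect_equal(re$se, 1 / sqrt(sum(w_re)), tolerance = 1e-12)
  expect_equal(re$I2, max(0, (Q - 2) / Q) * 100, tolerance = 1e-12)
  skip_if_not_installed("metafor")
  m_fe <- metafor::rma(yi = y, sei = s, method = "FE")
  m_dl <- metafor::rma(yi = y, sei = s, method = "DL")
  expect_equal(fe$log_or, as.numeric(m_fe$beta), tolerance = 1e-10)
  expect_equal(fe$se, m_fe$se, tolerance = 1e-10)
  expect_equal(re$log_or, as.numeric(m_dl$beta), tolerance = 1e-10)
  expect_equal(re$tau2, m_dl$tau2, tolerance = 1e-10)
})

test_that("OR is invariant under monotone transforms and reciprocal under label swap", {
  withr::with_seed(17, {
    for (r in 1:10) {
      v <- rnorm(24, mean = 5)
      g <- sample(rep(c("case", "control"), each = 12))
      c_raw <- dichotomize_at_median(v, g)
      c_log <- dichotomize_at_median(log(v - min(v) + 1), g)
      expect_identical(c_raw, c_log)
      e <- odds_ratio(c_raw)
      swapped <- ifelse(g == "case", "control", "case")
      e_sw <- odds_ratio(dichotomize_at_median(v, swapped))
      expect_equal(e_sw$or, 1 / e$or, tolerance = 1e-12)
    }
  })
})

test_that("RE intervals are never narrower than FE and coincide when tau2 = 0", {
  withr::with_seed(19, {
    for (r in 1:10) {
      es <- lapply(1:5, function(i)
        fake_effect(paste0("S", i), rnorm(1, 0, 0.8), runif(1, 0.1, 0.4)))
      fe <- pool_effects(es, "FE"); re <- pool_effects(es, "RE")
      expect_gte(re$se + 1e-12, fe$se)
      if (re$tau2 == 0) expect_equal(re$log_or, fe$log_or, tolerance = 1e-12)
    }
  })
})

test_that("or_meta composes the stages and drops degenerate studies", {
  v <- c(1, 2, 3, 4, 5, 6, 7, 8,  2, 2, 2, 2)
  g <- c(rep(c("control", "case"), each = 4), rep(c("control", "case"), 2))
  s <- rep(c("S1", "S2"), c(8, 4))
  expect_warning(try(or_meta(v, g, s, model = "FE"), silent = TRUE), "degenerate")
  # S2 dropped leaves one study, which pool_effects refuses
  expect_error(suppressWarnings(or_meta(v, g, s)), ">= 2")
  v2 <- c(v[1:8], 1, 2, 3, 4, 5, 6, 7, 8)
  g2 <- c(g[1:8], rep(c("control", "case"), each = 4))
  s2 <- rep(c("S1", "S3"), each = 8)
  fit2 <- or_meta(v2, g2, s2, metric = "toy")
  expect_s3_class(fit2, "or_meta")
  expect_equal(length(fit2$per_study), 2L)
  fd <- forest_data(fit2)
  expect_equal(nrow(fd), 4L)                       # 2 studies + RE + FE rows
  expect_equal(fd$model[3:4], c("RE", "FE"))
  expect_equal(coef(fit2), c(log_or = fit2$log_or))
  ci <- confint(fit2)
  expect_equal(exp(ci[1, ]), fit2$ci, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("a planted case-enriched taxon yields a significant OR below 1", {
  lfc <- c(OTU0001 = 2, OTU0002 = 2, OTU0011 = -2, OTU0012 = -2)
  gen <- quick_collection(seed = 23, n_studies = 3, n_per_arm = 100,
                          n_features = 50, n_genera = 10,
                          study_effect_sd = 0.5, planted = lfc)
  fit <- meta_analyze_metric(gen$collection, "taxon:OTU0001")
  expect_lt(fit$pooled_or, 1)                      # higher in cases => OR < 1
  expect_true(fit$significant)
  expect_true(fit$alternate$significant)
  fit_dep <- meta_analyze_metric(gen$collection, "taxon:OTU0011")
  expect_gt(fit_dep$pooled_or, 1)
})
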