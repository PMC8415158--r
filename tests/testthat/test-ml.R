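test_that("AUC follows the rank formulation including ties", {
  expect_equal(auc(c(1, 2, 3, 10, 11, 12), rep(c(0, 1), each = 3)), 1)
  expect_equal(auc(rep(0.5, 8), rep(c(0, 1), 4)), 0.5)
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(auc(1:4, rep(1, 4)), "both classes")
})

test_that("AUC equals the pair-enumeration and pROC oracles on random data", {
  withr::with_seed(43, {
    for (r in 1:10) {
      n <- 30
      s <- round(runif(n), 2)                       # forces some ties
      y <- rbinom(n, 1, 0.5)
      if (length(unique(y)) < 2) next
      pos <- which(y == 1); neg <- which(y == 0)
      pairs <- outer(s[pos], s[neg], function(a, b)
        (a > b) + 0.5 * (a == b))
      expect_equal(auc(s, y), mean(pairs), tolerance = 1e-12)
    }
    skip_if_not_installed("pROC")
    s <- runif(40); y <- rep(c(0, 1), 20)
    expect_equal(auc(s, y),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
                 tolerance = 1e-12)
  })
})

test_that("forward selection keeps the informative feature and is deterministic", {
  withr::with_seed(47, {
    n <- 120
    x <- matrix(rnorm(n * 12), n, 12,
                dimnames = list(paste0("s", 1:n), paste0("f", 1:12)))
    y <- rep(c("control", "case"), each = n / 2)
    x[y == "case", "f3"] <- x[y == "case", "f3"] + 2
  })
  ranking <- paste0("f", 1:12)
  sel1 <- stepwise_select(x, y, ranking, seed = 5)
  sel2 <- stepwise_select(x, y, ranking, seed = 5)
  expect_identical(sel1, sel2)
  expect_true("f3" %in% sel1$features)
  expect_true(all(sel1$features %in% ranking))
  full <- micrometa:::cv_auc(x, y, seed = 5)
  expect_gte(sel1$cv_auc, full - 0.02)
  expect_error(stepwise_select(x[1:10, ], y[1:10], ranking), "per fold")
})

test_that("all-noise selection stays small with chance-level AUC", {
  withr::with_seed(53, {
    n <- 80
    x <- matrix(rnorm(n * 8), n, 8,
                dimnames = list(paste0("s", 1:n), paste0("f", 1:8)))
    y <- rep(c("control", "case"), each = n / 2)
  })
  sel <- stepwise_select(x, y, paste0("f", 1:8), seed = 7)
  expect_lte(length(sel$features), 4)
  expect_lt(abs(sel$cv_auc - 0.5), 0.12)
})

test_that("LOO evaluation separates planted signal and keeps books straight", {
  withr::with_seed(59, {
    n <- 40
    x <- matrix(rnorm(n * 5), n, 5,
                dimnames = list(paste0("s", 1:n), paste0("f", 1:5)))
    y <- rep(c("control", "case"), each = n / 2)
    x[y == "case", 1:2] <- x[y == "case", 1:2] + 2.5
  })
  ev <- evaluate_loo(x, y, seed = 11, n_boot = 200)
  expect_gt(ev$auc, 0.9)
  pos <- y == "case"
  expect_equal(ev$sensitivity, mean(ev$probabilities[pos] > ev$threshold))
  expect_equal(ev$specificity, mean(ev$probabilities[!pos] <= ev$threshold))
  expect_true(all(c(ev$sensitivity, ev$specificity) >= 0 &
                  c(ev$sensitivity, ev$specificity) <= 1))
  expect_true(ev$auc_ci[1] <= ev$auc && ev$auc <= ev$auc_ci[2])
  expect_error(evaluate_loo(x[1:8, ], y[1:8]), "n >= 10")
})

test_that("importance ranking puts the planted feature first", {
  withr::with_seed(61, {
    n <- 100
    x <- matrix(rnorm(n * 6), n, 6,
                dimnames = list(paste0("s", 1:n), paste0("f", 1:6)))
    y <- rep(c("control", "case"), each = n / 2)
    x[y == "case", "f2"] <- x[y == "case", "f2"] + 2
  })
  imp <- importance_ranking(x, y, seed = 13)
  expect_equal(imp$feature[1], "f2")
  expect_equal(nrow(imp), 6L)
  # noise importances hover near zero
  expect_lt(max(abs(imp$mean_decrease_accuracy[-1])),
            imp$mean_decrease_accuracy[1])
})

test_that("duplicated studies transfer without loss", {
  lfc <- planted_genus_effects(40, 8, n_up = 2, n_down = 2, log2fc = 2, seed = 67)
  spec <- synthetic_spec(n_studies = 1, n_case = 15, n_control = 15,
                         n_features = 40, n_genera = 8, study_effect_sd = 0,
                         planted_features = lfc, depth_range = c(2000, 3000),
                         seed = 67)
  g <- generate_collection(spec)
  t1 <- g$collection$tables[[1]]
  t2 <- count_table(t1$counts, study_id = "Study2")
  colnames(t2$counts) <- sub("Study1", "Study2", colnames(t2$counts))
  md1 <- g$collection$metadata
  md2 <- md1; md2$sample_id <- sub("Study1", "Study2", md2$sample_id)
  md2$study_id <- "Study2"
  col <- study_collection(list(t1, t2), rbind(md1, md2),
                          g$collection$taxonomy)
  genus <- collapse_collection(col)
  tm <- suppressWarnings(transfer_matrix(genus, seed = 3, n_trees = 200))
  offd <- tm$auc[row(tm$auc) != col(tm$auc)]
  expect_equal(dim(tm$auc), c(2, 2))
  expect_gt(min(offd), min(diag(tm$auc)) - 0.1)   # no batch effect, no gap
})

test_that("LOOS returns one held-out AUC per study and a null stays at chance", {
  gen <- quick_collection(seed = 71, n_studies = 3, n_per_arm = 12,
                          n_features = 30, n_genera = 6,
                          study_effect_sd = 0.4, planted = NULL)
  genus <- collapse_collection(gen$collection)
  lv <- loos_validate(genus, seed = 5, n_trees = 150)
  expect_equal(sort(names(lv)), sort(study_ids(genus)))
  expect_true(all(lv > 0.15 & lv < 0.85))          # chance-level band
})

test_that("specificity assessment separates a disjoint-effect disease", {
  mk <- function(seed, planted) {
    gen <- quick_collection(seed = seed, n_studies = 2, n_per_arm = 35,
                            n_features = 60, n_genera = 12,
                            study_effect_sd = 0.3, planted = planted)
    collapse_collection(gen$collection)
  }
  up <- function(genes) {
    feats <- unlist(lapply(genes, function(g)
      sprintf("OTU%04d", which(rep(1:12, length.out = 60) == g))))
    setNames(rep(2, length(feats)), feats)
  }
  ref <- mk(73, up(c(1, 2)))
  other <- mk(74, up(c(7, 8)))                     # disjoint planted genera
  res <- specificity_assess(ref, list(other = other), seed = 9, n_trees = 200)
  expect_equal(res$collection, c("reference", "other"))
  expect_gt(res$mean_prob[1], res$mean_prob[2])
  expect_lt(res$t_p[2], 0.05)
  expect_true(all(res$mean_prob >= 0 & res$mean_prob <= 1))
})
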