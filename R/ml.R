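#' Area under the ROC curve (rank formulation)
#'
#' AUC computed as the Mann-Whitney statistic: the probability that a
#' random case scores above a random control, ties contributing 1/2.
#'
#' @param scores numeric predicted scores.
#' @param labels binary labels; 1/"case" = positive class.
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, labels) {
  pos <- labels %in% c(1, "case", TRUE)
  if (!any(pos) || all(pos)) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  n1 <- sum(pos); n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Seeded 500-tree random forest on a samples x features matrix.
rf_fit <- function(x, y, n_trees = 500, seed = 1L) {
  y <- factor(y, levels = c("control", "case"))
  withr::with_seed(as.integer(seed),
    randomForest::randomForest(x = as.data.frame(x), y = y, ntree = n_trees))
}

rf_prob <- function(fit, x) {
  stats::predict(fit, as.data.frame(x), type = "prob")[, "case"]
}

# Stratified k-fold assignment: folds balanced within each class.
stratified_folds <- function(labels, k, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    fold <- integer(length(labels))
    for (g in unique(labels)) {
      i <- which(labels == g)
      fold[i] <- sample(rep_len(seq_len(k), length(i)))
    }
    fold
  })
}

cv_auc <- function(x, y, k = 10, n_trees = 500, seed = 1L) {
  fold <- stratified_folds(y, k, seed = seed)
  prob <- numeric(length(y))
  for (f in unique(fold)) {
    tr <- fold != f
    fit <- rf_fit(x[tr, , drop = FALSE], y[tr], n_trees = n_trees,
                  seed = seed + f)
    prob[!tr] <- rf_prob(fit, x[!tr, , drop = FALSE])
  }
  auc(prob, y)
}

#' Forward stepwise feature selection by cross-validated AUC
#'
#' Single forward pass over the features in the given abundance-rank
#' order: each candidate is tentatively added, a 500-tree random forest
#' is scored by stratified 10-fold cross-validated AUC, and the candidate
#' is kept iff the mean CV AUC improves by at least \code{epsilon}.
#' Deterministic for a fixed seed.
#'
#' @param x samples x features matrix (e.g. relative abundances).
#' @param labels "case"/"control" per sample.
#' @param ranking feature ids in descending overall mean relative
#'   abundance (see \code{\link{common_features}}); must cover the
#'   columns tried.
#' @param k_folds folds for the CV (default 10).
#' @param epsilon minimum AUC improvement to keep a feature (default
#'   0.001).
#' @param n_trees trees per forest (default 500).
#' @param seed integer seed.
#' @return list(features, cv_auc, trace) — the kept ids in ranking
#'   order, the final CV AUC, and the per-step AUC trace.
#' @export
stepwise_select <- function(x, labels, ranking, k_folds = 10, epsilon = 0.001,
                            n_trees = 500, seed = 1L) {
  x <- as.matrix(x)
  if (nrow(x) < 2 * k_folds) stop("need at least 2 samples per fold")
  ranking <- ranking[ranking %in% colnames(x)]
  if (!length(ranking)) stop("ranking shares no features with x")
  kept <- character(0); best <- 0.5
  trace <- data.frame(feature = ranking, tried_auc = NA_real_, kept = FALSE,
                      stringsAsFactors = FALSE)
  for (i in seq_along(ranking)) {
    cand <- c(kept, ranking[i])
    a <- cv_auc(x[, cand, drop = FALSE], labels, k = k_folds,
                n_trees = n_trees, seed = seed)
    trace$tried_auc[i] <- a
    if (a >= best + epsilon) {
      kept <- cand
      best <- a
      trace$kept[i] <- TRUE
    }
  }
  if (!length(kept)) {
    # nothing beat the 0.5 baseline; fall back to the most abundant
    # feature so downstream models always have a design matrix
    kept <- ranking[1]
    best <- trace$tried_auc[1]
    trace$kept[1] <- TRUE
  }
  list(features = kept, cv_auc = best, trace = trace)
}

#' Leave-one-out evaluation of a random-forest classifier
#'
#' For each sample, a 500-tree forest is trained on the remaining samples
#' and the held-out case-probability recorded. AUC is computed from these
#' out-of-fold probabilities; sensitivity and specificity are taken at
#' the Youden-optimal threshold on the same probabilities, with 95\% CIs
#' from a bootstrap over samples. For n above \code{loo_cap} the per-sample
#' LOO is replaced by stratified 10-fold out-of-fold probabilities.
#'
#' @param x samples x features matrix.
#' @param labels "case"/"control" per sample (each class >= 2, n >= 10).
#' @param n_trees trees per forest.
#' @param seed integer seed.
#' @param n_boot bootstrap replicates for the CIs (default 2000).
#' @param loo_cap sample-size cap for exact LOO (default 500).
#' @return Object of class \code{classifier_eval}: auc, sensitivity,
#'   specificity with CIs, threshold, probabilities, labels.
#' @export
evaluate_loo <- function(x, labels, n_trees = 500, seed = 1L, n_boot = 2000,
                         loo_cap = 500) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 10) stop("need n >= 10")
  if (min(table(labels)) < 2) stop("each class needs >= 2 samples")
  if (n <= loo_cap) {
    prob <- vapply(seq_len(n), function(i) {
      fit <- rf_fit(x[-i, , drop = FALSE], labels[-i], n_trees = n_trees,
                    seed = seed + i)
      rf_prob(fit, x[i, , drop = FALSE])
    }, numeric(1))
  } else {
    message("evaluate_loo: n = ", n, " > ", loo_cap,
            "; using stratified 10-fold out-of-fold probabilities")
    fold <- stratified_folds(labels, 10, seed = seed)
    prob <- numeric(n)
    for (f in unique(fold)) {
      fit <- rf_fit(x[fold != f, , drop = FALSE], labels[fold != f],
                    n_trees = n_trees, seed = seed + f)
      prob[fold == f] <- rf_prob(fit, x[fold == f, , drop = FALSE])
    }
  }
  classifier_eval(prob, labels, seed = seed, n_boot = n_boot)
}

#' Summarize out-of-fold probabilities into AUC, sensitivity, specificity
#'
#' @param prob out-of-fold case probabilities.
#' @param labels true labels.
#' @param seed seed for the bootstrap.
#' @param n_boot bootstrap replicates.
#' @return A \code{classifier_eval} object.
#' @export
classifier_eval <- function(prob, labels, seed = 1L, n_boot = 2000) {
  pos <- labels %in% c(1, "case", TRUE)
  a <- auc(prob, labels)
  thr <- youden_threshold(prob, pos)
  sens <- mean(prob[pos] > thr)
  spec <- mean(prob[!pos] <= thr)
  boot <- withr::with_seed(as.integer(seed) + 999L, {
    t(vapply(seq_len(n_boot), function(b) {
      i <- sample(length(prob), replace = TRUE)
      if (!any(pos[i]) || all(pos[i])) return(c(NA, NA, NA))
      c(auc(prob[i], pos[i]),
        mean(prob[i][pos[i]] > thr),
        mean(prob[i][!pos[i]] <= thr))
    }, numeric(3)))
  })
  ci <- function(j) unname(stats::quantile(boot[, j], c(0.025, 0.975),
                                           na.rm = TRUE))
  structure(list(auc = a, auc_ci = ci(1),
                 sensitivity = sens, sensitivity_ci = ci(2),
                 specificity = spec, specificity_ci = ci(3),
                 threshold = thr, probabilities = prob, labels = labels),
            class = "classifier_eval")
}

# Threshold maximizing sensitivity + specificity - 1 over the observed
# probability cut points ("predict positive when prob > t").
youden_threshold <- function(prob, pos) {
  cuts <- sort(unique(c(-Inf, prob)))
  j <- vapply(cuts, function(t) mean(prob[pos] > t) + mean(prob[!pos] <= t) - 1,
              numeric(1))
  cuts[which.max(j)]
}

#' @export
print.classifier_eval <- function(x, ...) {
  cat(sprintf("classifier_eval: AUC = %.3f [%.3f, %.3f]\n",
              x$auc, x$auc_ci[1], x$auc_ci[2]))
  cat(sprintf("  sensitivity %.1f%% [%.1f, %.1f], specificity %.1f%% [%.1f, %.1f] at threshold %.3f\n",
              100 * x$sensitivity, 100 * x$sensitivity_ci[1], 100 * x$sensitivity_ci[2],
              100 * x$specificity, 100 * x$specificity_ci[1], 100 * x$specificity_ci[2],
              x$threshold))
  invisible(x)
}

# Relative-abundance design matrix (samples x features) for one study,
# restricted to `features` in that order.
study_design <- function(collection, study, features) {
  t(relative_abundance(collection$tables[[study]])[features, , drop = FALSE])
}

#' Study-to-study transfer matrix of AUCs
#'
#' Diagonal: within-study cross-validated AUC on the features selected in
#' that study (forward CV selection, then LOO evaluation). Off-diagonal
#' (i, j): the 500-tree forest trained on study i's samples with study
#' i's selected features, scored on study j.
#'
#' @param collection a \code{study_collection} (collapsed at the feature
#'   level of interest, e.g. genus).
#' @param seed integer seed.
#' @param n_trees trees per forest.
#' @param epsilon selection improvement threshold.
#' @param min_prevalence passed to \code{\link{common_features}}.
#' @return list of class \code{transfer_matrix}: auc (k x k matrix),
#'   selected (features per study).
#' @export
transfer_matrix <- function(collection, seed = 1L, n_trees = 500,
                            epsilon = 0.001, min_prevalence = 0) {
  studies <- study_ids(collection)
  if (length(studies) < 2) stop("need >= 2 studies")
  ranking <- common_features(collection, min_prevalence)
  m <- matrix(NA_real_, length(studies), length(studies),
              dimnames = list(train = studies, test = studies))
  selected <- list()
  for (i in seq_along(studies)) {
    s <- studies[i]
    xi <- study_design(collection, s, ranking)
    yi <- collection_groups(collection, s)
    if (length(unique(yi)) < 2) { warning("study '", s, "' lacks a class"); next }
    sel <- stepwise_select(xi, yi, ranking, epsilon = epsilon,
                           n_trees = n_trees, seed = seed + i)
    selected[[s]] <- sel$features
    ev <- evaluate_loo(xi[, sel$features, drop = FALSE], yi,
                       n_trees = n_trees, seed = seed + 100 + i, n_boot = 200)
    m[i, i] <- ev$auc
    fit <- rf_fit(xi[, sel$features, drop = FALSE], yi, n_trees = n_trees,
                  seed = seed + 200 + i)
    for (j in seq_along(studies)[-i]) {
      xj <- study_design(collection, studies[j], sel$features)
      yj <- collection_groups(collection, studies[j])
      if (length(unique(yj)) < 2) next
      m[i, j] <- auc(rf_prob(fit, xj), yj)
    }
  }
  structure(list(auc = m, selected = selected), class = "transfer_matrix")
}

#' @export
print.transfer_matrix <- function(x, ...) {
  cat("study-to-study AUC (rows train, columns test):\n")
  print(round(x$auc, 3))
  d <- diag(x$auc); o <- x$auc[row(x$auc) != col(x$auc)]
  cat(sprintf("median within-study %.3f, median transfer %.3f\n",
              stats::median(d, na.rm = TRUE), stats::median(o, na.rm = TRUE)))
  invisible(x)
}

#' Leave-one-study-out validation
#'
#' For each study s: pool all other studies, run forward CV feature
#' selection on the pooled training set, train a 500-tree forest, and
#' score study s.
#'
#' @param collection a \code{study_collection} (>= 3 studies).
#' @param seed integer seed.
#' @param n_trees trees per forest.
#' @param epsilon selection improvement threshold.
#' @param min_prevalence passed to \code{\link{common_features}}.
#' @return Named numeric vector: held-out AUC per study, with the
#'   selected feature sets in attribute \code{"selected"}.
#' @export
loos_validate <- function(collection, seed = 1L, n_trees = 500,
                          epsilon = 0.001, min_prevalence = 0) {
  studies <- study_ids(collection)
  if (length(studies) < 3) stop("need >= 3 studies")
  ranking <- common_features(collection, min_prevalence)
  out <- stats::setNames(rep(NA_real_, length(studies)), studies)
  selected <- list()
  for (i in seq_along(studies)) {
    s <- studies[i]
    train <- do.call(rbind, lapply(setdiff(studies, s), function(u)
      study_design(collection, u, ranking)))
    ytr <- unlist(lapply(setdiff(studies, s), function(u)
      collection_groups(collection, u)), use.names = FALSE)
    sel <- stepwise_select(train, ytr, ranking, epsilon = epsilon,
                           n_trees = n_trees, seed = seed + i)
    selected[[s]] <- sel$features
    fit <- rf_fit(train[, sel$features, drop = FALSE], ytr,
                  n_trees = n_trees, seed = seed + 300 + i)
    xte <- study_design(collection, s, sel$features)
    yte <- collection_groups(collection, s)
    out[s] <- auc(rf_prob(fit, xte), yte)
  }
  attr(out, "selected") <- selected
  out
}

#' Random-forest feature importance ranking
#'
#' Fits a seeded 500-tree forest on the full data with permutation
#' importance enabled and returns both mean decrease in accuracy and mean
#' decrease in Gini, sorted by descending accuracy importance.
#'
#' @param x samples x features matrix.
#' @param labels "case"/"control" per sample.
#' @param n_trees trees.
#' @param seed integer seed.
#' @return data.frame(feature, mean_decrease_accuracy,
#'   mean_decrease_gini).
#' @export
importance_ranking <- function(x, labels, n_trees = 500, seed = 1L) {
  y <- factor(labels, levels = c("control", "case"))
  fit <- withr::with_seed(as.integer(seed),
    randomForest::randomForest(x = as.data.frame(x), y = y, ntree = n_trees,
                               importance = TRUE))
  imp <- randomForest::importance(fit)
  out <- data.frame(feature = rownames(imp),
                    mean_decrease_accuracy = imp[, "MeanDecreaseAccuracy"],
                    mean_decrease_gini = imp[, "MeanDecreaseGini"],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_decrease_accuracy), ]
  rownames(out) <- NULL
  out
}

#' Disease specificity of a case/control classifier
#'
#' Scores the case samples of each "other disease" collection with a
#' model trained on the reference (target-disease) collection and
#' compares the predicted case-probabilities with those of the reference
#' collection's cases by Welch t-tests. Features missing from another
#' collection are zero-filled (and reported).
#'
#' @param collection the reference \code{study_collection} (collapsed).
#' @param others named list of other \code{study_collection}s.
#' @param seed integer seed.
#' @param n_trees trees per forest.
#' @param epsilon selection improvement threshold.
#' @return data.frame(collection, mean_prob, sd_prob, n, t_p) with the
#'   reference collection first (its t_p is NA).
#' @export
specificity_assess <- function(collection, others, seed = 1L, n_trees = 500,
                               epsilon = 0.001) {
  ranking <- common_features(collection)
  x <- do.call(rbind, lapply(study_ids(collection), function(s)
    study_design(collection, s, ranking)))
  y <- unlist(lapply(study_ids(collection), function(s)
    collection_groups(collection, s)), use.names = FALSE)
  sel <- stepwise_select(x, y, ranking, epsilon = epsilon,
                         n_trees = n_trees, seed = seed)
  fit <- rf_fit(x[, sel$features, drop = FALSE], y, n_trees = n_trees,
                seed = seed + 1)
  # out-of-bag probabilities for the reference cases avoid resubstitution bias
  ref_prob <- stats::predict(fit, type = "prob")[, "case"][y == "case"]
  score_cases <- function(col) {
    probs <- unlist(lapply(study_ids(col), function(s) {
      ra <- relative_abundance(col$tables[[s]])
      m <- matrix(0, ncol(ra), length(sel$features),
                  dimnames = list(colnames(ra), sel$features))
      have <- intersect(sel$features, rownames(ra))
      if (!length(have)) stop("no feature overlap with reference model")
      if (length(have) < length(sel$features))
        message("specificity_assess: zero-filled ",
                length(sel$features) - length(have), " missing feature(s)")
      m[, have] <- t(ra[have, , drop = FALSE])
      g <- collection_groups(col, s)
      rf_prob(fit, m)[g == "case"]
    }), use.names = FALSE)
    probs
  }
  rows <- data.frame(collection = "reference", mean_prob = mean(ref_prob),
                     sd_prob = stats::sd(ref_prob), n = length(ref_prob),
                     t_p = NA_real_, stringsAsFactors = FALSE)
  for (nm in names(others)) {
    p <- score_cases(others[[nm]])
    rows <- rbind(rows, data.frame(
      collection = nm, mean_prob = mean(p), sd_prob = stats::sd(p),
      n = length(p), t_p = stats::t.test(ref_prob, p)$p.value,
      stringsAsFactors = FALSE))
  }
  rows
}
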