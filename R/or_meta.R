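#' Per-sample beta-diversity dispersion
#'
#' Reduces a within-study distance matrix to one scalar per sample — the
#' median (or mean) dissimilarity of that sample to all other samples of
#' the same study — so that a beta-diversity metric can be median
#' dichotomized like any alpha metric.
#'
#' @param dm a \code{dist} or square symmetric matrix over the study's
#'   samples.
#' @param summary "median" (default) or "mean".
#' @return Named numeric vector, one value per sample.
#' @export
per_sample_dispersion <- function(dm, summary = c("median", "mean")) {
  summary <- match.arg(summary)
  m <- as.matrix(stats::as.dist(dm))
  if (nrow(m) < 3) stop("need >= 3 samples for per-sample dispersion")
  f <- if (summary == "median") stats::median else mean
  vals <- vapply(seq_len(nrow(m)), function(i) f(m[i, -i]), numeric(1))
  stats::setNames(vals, rownames(m))
}

#' Dichotomize a metric at the within-study median
#'
#' The median is taken over ALL samples of the study (cases and controls
#' pooled); values strictly above it are "positive", ties at the median
#' count as negative. Cells follow the contingency-table convention
#' a = controls positive, b = controls negative, c = cases positive,
#' d = cases negative.
#'
#' @param values numeric metric values, one per sample.
#' @param groups "case"/"control" label per sample.
#' @return list(a, b, c, d, degenerate) where \code{degenerate} flags an
#'   all-negative table (all values identical).
#' @export
dichotomize_at_median <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  if (!all(groups %in% c("case", "control"))) stop("groups must be case/control")
  if (sum(groups == "case") < 2 || sum(groups == "control") < 2)
    stop("need >= 2 samples per group")
  med <- stats::median(values)
  pos <- values > med
  cells <- list(a = sum(pos & groups == "control"),
                b = sum(!pos & groups == "control"),
                c = sum(pos & groups == "case"),
                d = sum(!pos & groups == "case"))
  cells$degenerate <- !any(pos)
  cells
}

#' Odds ratio with Haldane-Anscombe correction and Woolf standard error
#'
#' OR = (a d)/(b c); when any cell is zero, 0.5 is added to all four cells
#' before computing the OR, its log, and the Woolf SE
#' sqrt(1/a + 1/b + 1/c + 1/d). The 95\% CI is exp(log OR +/- 1.96 SE).
#' Orientation: OR > 1 means the metric is higher in controls than cases.
#'
#' @param cells list or vector with components a, b, c, d (see
#'   \code{\link{dichotomize_at_median}}).
#' @param study_id optional study label carried through.
#' @param conf_level confidence level (default 0.95).
#' @return list of class \code{effect_2x2}: cells, or, log_or, se_log_or,
#'   ci (lower, upper), corrected flag.
#' @export
odds_ratio <- function(cells, study_id = NA_character_, conf_level = 0.95) {
  a <- cells[["a"]]; b <- cells[["b"]]; c <- cells[["c"]]; d <- cells[["d"]]
  if ((a + b) == 0 || (c + d) == 0) stop("a whole study arm is empty")
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(study_id = study_id,
                 cells = c(a = cells[["a"]], b = cells[["b"]],
                           c = cells[["c"]], d = cells[["d"]]),
                 or = or, log_or = log(or), se_log_or = se,
                 ci = exp(log(or) + c(-1, 1) * z * se),
                 corrected = corrected), class = "effect_2x2")
}

#' @export
print.effect_2x2 <- function(x, ...) {
  cat(sprintf("2x2 effect [%s]: a=%d b=%d c=%d d=%d%s\n",
              x$study_id, x$cells["a"], x$cells["b"], x$cells["c"], x$cells["d"],
              if (x$corrected) " (+0.5 correction)" else ""))
  cat(sprintf("OR = %.4g [%.4g, %.4g]\n", x$or, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Pool per-study log odds ratios (fixed- and random-effects)
#'
#' Fixed effects: inverse-variance weighted mean of the log ORs with
#' weights w_i = 1/se_i^2. Heterogeneity: Cochran's
#' Q = sum w_i (theta_i - theta_FE)^2 on k - 1 df,
#' I^2 = max(0, (Q - df)/Q) x 100. Random effects (DerSimonian-Laird):
#' tau^2 = max(0, (Q - df) / (sum w - sum w^2 / sum w)) and weights
#' 1/(se_i^2 + tau^2). Pooled CIs use normal quantiles.
#'
#' @param effects list of \code{effect_2x2} objects (>= 2 studies).
#' @param model "RE" (default) or "FE".
#' @param conf_level confidence level.
#' @return Object of class \code{meta_result}: model, pooled_or, ci,
#'   log_or, se, Q, df, I2 (percent), tau2, significant (CI excludes 1),
#'   per_study.
#' @export
pool_effects <- function(effects, model = c("RE", "FE"), conf_level = 0.95) {
  model <- match.arg(model)
  if (length(effects) < 2)
    stop("need >= 2 studies to pool; use odds_ratio() for a single study")
  y <- vapply(effects, `[[`, numeric(1), "log_or")
  se <- vapply(effects, `[[`, numeric(1), "se_log_or")
  w <- 1 / se^2
  theta_fe <- sum(w * y) / sum(w)
  df <- length(y) - 1
  Q <- sum(w * (y - theta_fe)^2)
  I2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  tau2 <- max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
  if (model == "FE") {
    theta <- theta_fe; se_p <- sqrt(1 / sum(w)); tau2_out <- 0
  } else {
    w_re <- 1 / (se^2 + tau2)
    theta <- sum(w_re * y) / sum(w_re); se_p <- sqrt(1 / sum(w_re))
    tau2_out <- tau2
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- exp(theta + c(-1, 1) * z * se_p)
  structure(list(model = model, pooled_or = exp(theta), ci = ci,
                 log_or = theta, se = se_p, Q = Q, df = df, I2 = I2,
                 tau2 = tau2_out, significant = ci[1] > 1 || ci[2] < 1,
                 per_study = effects),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("%s-model pooled OR = %.3f [%.3f, %.3f]%s\n", x$model,
              x$pooled_or, x$ci[1], x$ci[2],
              if (x$significant) " *" else ""))
  cat(sprintf("heterogeneity: Q = %.3f (df %d), I2 = %.1f%% (%s), tau2 = %.4f\n",
              x$Q, x$df, x$I2, if (x$I2 < 50) "low" else "high", x$tau2))
  invisible(x)
}

#' Median-dichotomized odds-ratio meta-analysis
#'
#' The central fit: per study, the metric is dichotomized at the pooled
#' within-study median, a 2x2 table against case/control status yields an
#' odds ratio with Haldane correction and Woolf SE, and the per-study log
#' ORs are pooled under fixed- and random-effects models. Studies whose
#' metric is degenerate (all samples tie at the median, so no sample is
#' "positive") are dropped with a warning and the degrees of freedom
#' adjusted.
#'
#' @param values numeric metric values, one per sample.
#' @param groups "case"/"control" per sample.
#' @param studies study id per sample.
#' @param model "RE" or "FE" for the primary fit (the other is kept in
#'   \code{$alternate}).
#' @param conf_level confidence level.
#' @param metric optional metric name carried into the printout.
#' @return Object of class \code{or_meta}: the primary
#'   \code{meta_result} plus \code{alternate}, \code{metric},
#'   \code{dropped} (degenerate studies).
#' @seealso \code{\link{meta_analyze_metric}} to run directly from a
#'   \code{study_collection}.
#' @export
or_meta <- function(values, groups, studies, model = c("RE", "FE"),
                    conf_level = 0.95, metric = "metric") {
  model <- match.arg(model)
  stopifnot(length(values) == length(groups), length(values) == length(studies))
  effects <- list(); dropped <- character(0)
  for (s in unique(as.character(studies))) {
    i <- studies == s
    cells <- dichotomize_at_median(values[i], groups[i])
    if (cells$degenerate) {
      warning("study '", s, "' degenerate (all values at the median); dropped")
      dropped <- c(dropped, s)
      next
    }
    effects[[s]] <- odds_ratio(cells, study_id = s, conf_level = conf_level)
  }
  fit <- pool_effects(effects, model = model, conf_level = conf_level)
  alt <- pool_effects(effects, model = setdiff(c("RE", "FE"), model),
                      conf_level = conf_level)
  structure(c(unclass(fit),
              list(alternate = alt, metric = metric, dropped = dropped)),
            class = c("or_meta", "meta_result"))
}

#' @export
print.or_meta <- function(x, ...) {
  cat(sprintf("Median-dichotomized OR meta-analysis of '%s' (%d studies%s)\n",
              x$metric, length(x$per_study),
              if (length(x$dropped)) paste0(", ", length(x$dropped), " dropped")
              else ""))
  NextMethod()
  cat(sprintf("%s model: OR = %.3f [%.3f, %.3f]\n", x$alternate$model,
              x$alternate$pooled_or, x$alternate$ci[1], x$alternate$ci[2]))
  cat("(OR > 1: metric higher in controls than cases)\n")
  invisible(x)
}

#' @export
summary.or_meta <- function(object, ...) {
  fp <- forest_data(object)
  cat(sprintf("Metric: %s\n", object$metric))
  print(fp, row.names = FALSE, digits = 4)
  invisible(fp)
}

#' @export
coef.or_meta <- function(object, ...) {
  c(log_or = object$log_or)
}

#' @export
confint.or_meta <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- matrix(object$log_or + c(-1, 1) * z * object$se, nrow = 1,
              dimnames = list("log_or", sprintf("%.1f %%", c((1 - level) / 2,
                                                             1 - (1 - level) / 2) * 100)))
  m
}

#' Forest-plot data for a pooled fit
#'
#' One row per study (cells, OR, CI, FE weight percent) plus the pooled
#' FE/RE rows — the numbers a forest plot displays.
#'
#' @param fit an \code{or_meta} or \code{meta_result}.
#' @return data.frame(study, a, b, c, d, or, ci_lo, ci_hi, weight, model).
#' @export
forest_data <- function(fit) {
  es <- fit$per_study
  w <- 1 / vapply(es, `[[`, numeric(1), "se_log_or")^2
  rows <- data.frame(
    study = vapply(es, `[[`, character(1), "study_id"),
    a = vapply(es, function(e) e$cells["a"], numeric(1)),
    b = vapply(es, function(e) e$cells["b"], numeric(1)),
    c = vapply(es, function(e) e$cells["c"], numeric(1)),
    d = vapply(es, function(e) e$cells["d"], numeric(1)),
    or = vapply(es, `[[`, numeric(1), "or"),
    ci_lo = vapply(es, function(e) e$ci[1], numeric(1)),
    ci_hi = vapply(es, function(e) e$ci[2], numeric(1)),
    weight = 100 * w / sum(w), model = "study",
    stringsAsFactors = FALSE)
  pooled <- list(fit)
  if (!is.null(fit$alternate)) pooled <- c(pooled, list(fit$alternate))
  for (p in pooled)
    rows <- rbind(rows, data.frame(study = paste0("pooled_", p$model),
                                   a = NA, b = NA, c = NA, d = NA,
                                   or = p$pooled_or, ci_lo = p$ci[1],
                                   ci_hi = p$ci[2], weight = 100,
                                   model = p$model, stringsAsFactors = FALSE))
  rownames(rows) <- NULL
  rows
}

#' Forest plot of an OR meta-analysis (base graphics)
#'
#' @param x an \code{or_meta}.
#' @param ... passed to \code{plot.default}.
#' @export
plot.or_meta <- function(x, ...) {
  fd <- forest_data(x)
  n <- nrow(fd)
  ys <- rev(seq_len(n))
  xlim <- range(c(fd$ci_lo, fd$ci_hi, 1))
  graphics::plot(fd$or, ys, log = "x", xlim = xlim, pch = 15,
                 yaxt = "n", xlab = "Odds ratio (log scale)", ylab = "",
                 main = paste("Forest plot:", x$metric), ...)
  graphics::segments(fd$ci_lo, ys, fd$ci_hi, ys)
  graphics::abline(v = 1, lty = 2)
  graphics::axis(2, at = ys, labels = fd$study, las = 1, cex.axis = 0.7)
  invisible(x)
}

#' Meta-analyze a per-sample metric across the studies of a collection
#'
#' Computes the requested metric for every sample of every study, then
#' runs the median-dichotomization OR meta-analysis
#' (\code{\link{or_meta}}). Supported metrics: \code{"richness"},
#' \code{"shannon"}, \code{"evenness"} (alpha diversity),
#' \code{"bray_dispersion"} (per-sample median Bray-Curtis distance to the
#' rest of the study), or \code{"taxon:<id>"} (relative abundance of one
#' feature).
#'
#' @param collection a \code{study_collection} (ideally rarefied).
#' @param metric metric name as above.
#' @param model primary pooling model, "RE" or "FE".
#' @param dispersion_summary "median" or "mean" for bray_dispersion.
#' @return An \code{or_meta} fit.
#' @export
meta_analyze_metric <- function(collection, metric = "shannon",
                                model = c("RE", "FE"),
                                dispersion_summary = "median") {
  model <- match.arg(model)
  values <- numeric(0); groups <- character(0); studies <- character(0)
  for (t in collection$tables) {
    v <- metric_values(t, metric, dispersion_summary)
    values <- c(values, v)
    groups <- c(groups, collection_groups(collection, t$study_id))
    studies <- c(studies, rep(t$study_id, length(v)))
  }
  or_meta(values, groups, studies, model = model, metric = metric)
}

metric_values <- function(table, metric, dispersion_summary = "median") {
  if (startsWith(metric, "taxon:")) {
    id <- sub("^taxon:", "", metric)
    if (!id %in% feature_ids(table))
      stop("feature '", id, "' absent from study '", table$study_id, "'")
    return(relative_abundance(table)[id, ])
  }
  switch(metric,
    richness = ,
    shannon = ,
    evenness = {
      a <- suppressWarnings(alpha_diversity(table))
      stats::setNames(a[[metric]], rownames(a))
    },
    bray_dispersion = per_sample_dispersion(bray_curtis(table),
                                            summary = dispersion_summary),
    stop("unknown metric: ", metric))
}

#' Export forest-plot data as TSV
#' @param fit an \code{or_meta} or \code{meta_result}.
#' @param path output path.
#' @export
write_forest_data <- function(fit, path) {
  utils::write.table(forest_data(fit), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
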