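#' Two-sided Wilcoxon rank-sum (Mann-Whitney) p-value
#'
#' Exact enumeration when both arms have at most 10 untied values,
#' otherwise the tie-corrected normal approximation.
#'
#' @param x case values (>= 2).
#' @param y control values (>= 2).
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("each arm needs >= 2 values")
  ties <- any(duplicated(c(x, y)))
  use_exact <- length(x) <= 10 && length(y) <= 10 && !ties
  suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = !use_exact)$p.value)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment with monotonicity enforcement; the mapping is
#' order preserving.
#'
#' @param pvals vector of p-values in [0, 1].
#' @return q-values in the input order.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Differential-abundance summary of the common taxa
#'
#' For every feature common to all studies of an (already collapsed)
#' collection: mean +/- sd percent relative abundance in cases and
#' controls pooled across studies, Wilcoxon rank-sum p on the pooled
#' samples, BH q across taxa, and the attached median-dichotomization OR
#' meta-analysis. Rows are sorted by the \code{importance} ranking when
#' supplied (random-forest mean decrease Gini), else by q.
#'
#' @param collection a \code{study_collection} collapsed at the rank of
#'   interest.
#' @param fdr FDR level used for the \code{significant} flag.
#' @param model pooling model for the attached meta fits.
#' @param importance optional named numeric vector of feature importances.
#' @return data.frame of class \code{taxon_summary_table} with one row per
#'   common taxon.
#' @export
summarize_taxa <- function(collection, fdr = 0.05, model = "RE",
                           importance = NULL) {
  feats <- common_features(collection)
  if (!length(feats)) {
    message("summarize_taxa: no common taxa")
    return(data.frame())
  }
  ra <- do.call(cbind, lapply(collection$tables, relative_abundance))
  md <- collection$metadata
  grp <- md$group[match(colnames(ra), md$sample_id)]
  case <- grp == "case"
  rows <- lapply(feats, function(f) {
    v <- 100 * ra[f, ]
    data.frame(taxon = f,
               case_mean = mean(v[case]), case_sd = stats::sd(v[case]),
               control_mean = mean(v[!case]), control_sd = stats::sd(v[!case]),
               p = wilcoxon_rank_sum(v[case], v[!case]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  metas <- lapply(feats, function(f)
    meta_analyze_metric(collection, paste0("taxon:", f), model = model))
  out$pooled_or <- vapply(metas, `[[`, numeric(1), "pooled_or")
  out$or_ci_lo <- vapply(metas, function(m) m$ci[1], numeric(1))
  out$or_ci_hi <- vapply(metas, function(m) m$ci[2], numeric(1))
  out$or_significant <- vapply(metas, `[[`, logical(1), "significant")
  out$significant <- out$q < fdr
  if (!is.null(importance)) {
    out$importance <- importance[out$taxon]
    out <- out[order(-replace(out$importance, is.na(out$importance), -Inf)), ]
  } else {
    out$importance <- NA_real_
    out <- out[order(out$q), ]
  }
  rownames(out) <- NULL
  attr(out, "meta_fits") <- stats::setNames(metas, feats)
  class(out) <- c("taxon_summary_table", "data.frame")
  out
}

#' @export
print.taxon_summary_table <- function(x, ...) {
  df <- as.data.frame(x)
  df$case <- sprintf("%.3g +/- %.3g", df$case_mean, df$case_sd)
  df$control <- sprintf("%.3g +/- %.3g", df$control_mean, df$control_sd)
  print(df[, c("taxon", "case", "control", "p", "q", "pooled_or",
               "significant")], digits = 3)
  invisible(x)
}

#' Export a taxon summary as TSV
#' @param summary a \code{taxon_summary_table}.
#' @param path output path.
#' @export
write_taxon_summary <- function(summary, path) {
  utils::write.table(as.data.frame(summary), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
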