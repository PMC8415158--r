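#' Alpha diversity: richness, Shannon (nats), Pielou evenness
#'
#' Richness is the number of nonzero features, Shannon entropy is computed
#' in natural log over nonzero proportions, and evenness is Pielou's
#' J = Shannon / ln(richness) (set to 0 and flagged when richness < 2).
#' Comparable values across samples require equal depths, so a warning is
#' issued on unrarefied input.
#'
#' @param table a \code{count_table}.
#' @return data.frame with rownames = sample ids and columns richness,
#'   shannon, evenness.
#' @export
alpha_diversity <- function(table) {
  d <- colSums(table$counts)
  if (any(d == 0))
    stop("zero-depth sample: ", colnames(table$counts)[which(d == 0)[1]])
  if (length(unique(d)) > 1)
    warning("unequal sample depths; rarefy before comparing alpha diversity")
  comm <- t(table$counts)
  richness <- vegan::specnumber(comm)
  shannon <- vegan::diversity(comm, index = "shannon")
  evenness <- ifelse(richness >= 2, shannon / log(richness), 0)
  data.frame(richness = as.integer(richness), shannon = shannon,
             evenness = evenness, row.names = colnames(table$counts))
}

#' Bray-Curtis distance matrix
#'
#' d(x, y) = sum|x_i - y_i| / sum(x_i + y_i), computed on counts (the
#' default; equivalent to proportions when depths are equal after
#' rarefaction) or on per-sample proportions.
#'
#' @param table a \code{count_table}.
#' @param use one of "counts" or "proportions".
#' @return A \code{dist} object over samples.
#' @export
bray_curtis <- function(table, use = c("counts", "proportions")) {
  use <- match.arg(use)
  if (ncol(table$counts) < 2) stop("need >= 2 samples")
  if (any(colSums(table$counts) == 0)) stop("all-zero sample: undefined Bray-Curtis")
  m <- if (use == "proportions") relative_abundance(table) else table$counts
  vegan::vegdist(t(m), method = "bray")
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centers -D^2/2 and eigendecomposes; axes are scaled by the
#' square root of their (positive) eigenvalues and ordered by descending
#' eigenvalue. Negative eigenvalues are reported, not corrected.
#'
#' @param dm a \code{dist} or square symmetric matrix of dissimilarities.
#' @param k number of axes requested (at most n - 1).
#' @return An object of class \code{pcoa_ord}: list(points, eig,
#'   prop_explained).
#' @export
pcoa <- function(dm, k = 2) {
  d <- stats::as.dist(dm)
  n <- attr(d, "Size")
  if (k > n - 1) stop("k must be <= n - 1")
  fit <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  npos <- sum(fit$eig > sqrt(.Machine$double.eps) * max(abs(fit$eig)))
  if (k > npos) {
    warning("only ", npos, " positive-eigenvalue axes available; returning ", npos)
    k <- npos
  }
  pts <- fit$points[, seq_len(k), drop = FALSE]
  colnames(pts) <- paste0("Axis", seq_len(k))
  pos <- pmax(fit$eig, 0)
  structure(list(points = pts, eig = fit$eig,
                 prop_explained = pos / sum(pos)),
            class = "pcoa_ord")
}

#' @export
print.pcoa_ord <- function(x, ...) {
  k <- ncol(x$points)
  cat(sprintf("PCoA: %d samples, %d axes kept\n", nrow(x$points), k))
  cat(sprintf("proportion explained: %s\n",
              paste(sprintf("%.1f%%", 100 * x$prop_explained[seq_len(k)]),
                    collapse = ", ")))
  invisible(x)
}

#' One-way PERMANOVA
#'
#' Partitions the total sum of squared dissimilarities into between- and
#' within-group components (Anderson's pseudo-F) and obtains the p-value
#' by free permutation of the group labels:
#' p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm).
#'
#' @param dm a \code{dist} or square symmetric dissimilarity matrix.
#' @param labels group label per sample (>= 2 groups, each >= 2 samples).
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @return list(pseudo_F, p_value, n_permutations, r_squared) of class
#'   \code{permanova_result}.
#' @export
permanova <- function(dm, labels, n_perm = 10000, seed = 1L) {
  d <- stats::as.dist(dm)
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("need >= 2 groups")
  if (any(table(labels) < 2)) stop("each group needs >= 2 samples")
  df <- data.frame(group = labels)
  fit <- withr::with_seed(as.integer(seed),
    vegan::adonis2(d ~ group, data = df, permutations = n_perm))
  structure(list(pseudo_F = fit$F[1], p_value = fit$`Pr(>F)`[1],
                 n_permutations = n_perm, r_squared = fit$R2[1]),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.3f, R2 = %.3f, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$r_squared, x$p_value, x$n_permutations))
  invisible(x)
}

#' Fit taxon vectors onto an ordination
#'
#' Per variable, least-squares projection onto the first two ordination
#' axes; r-squared is the fraction of the variable's variance explained
#' and the p-value comes from permuting the variable. Variables are
#' returned ranked by descending r-squared. Constant variables get
#' r-squared 0 with a flag.
#'
#' @param ord a \code{pcoa_ord} with >= 2 axes.
#' @param variables numeric matrix/data.frame, samples x variables,
#'   aligned to the ordination's samples.
#' @param n_perm permutations for the p-value.
#' @param seed integer seed.
#' @return data.frame(variable, axis1, axis2, r_squared, p_value,
#'   constant), rows sorted by descending r_squared; axis1/axis2 are unit
#'   direction cosines.
#' @export
fit_vectors <- function(ord, variables, n_perm = 999, seed = 1L) {
  stopifnot(inherits(ord, "pcoa_ord"), ncol(ord$points) >= 2)
  variables <- as.matrix(variables)
  if (nrow(variables) != nrow(ord$points))
    stop("variables must align with ordination samples")
  const <- apply(variables, 2, function(v) stats::var(v) == 0)
  res <- data.frame(variable = colnames(variables),
                    axis1 = 0, axis2 = 0, r_squared = 0, p_value = NA_real_,
                    constant = const, stringsAsFactors = FALSE)
  ok <- !const
  if (any(ok)) {
    ef <- withr::with_seed(as.integer(seed),
      vegan::envfit(ord$points[, 1:2],
                    as.data.frame(variables[, ok, drop = FALSE]),
                    permutations = n_perm))
    res$axis1[ok] <- ef$vectors$arrows[, 1]
    res$axis2[ok] <- ef$vectors$arrows[, 2]
    res$r_squared[ok] <- ef$vectors$r
    res$p_value[ok] <- ef$vectors$pvals
  }
  res[order(-res$r_squared), , drop = FALSE]
}
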