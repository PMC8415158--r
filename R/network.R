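#' Spearman rank correlation with t-approximation p-value
#'
#' rho on average ranks (ties handled); two-sided p from the t
#' approximation on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @return list(rho, p).
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 4) stop("need equal length >= 4")
  if (stats::var(x) == 0 || stats::var(y) == 0) stop("constant vector")
  rho <- stats::cor(x, y, method = "spearman")
  n <- length(x)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- if (abs(rho) >= 1) 0 else 2 * stats::pt(-abs(tstat), df = n - 2)
  list(rho = rho, p = p)
}

#' Genus-probiotic Spearman correlation network
#'
#' Tests every genus x probiotic pair on sample-aligned abundance tables
#' and retains edges passing BOTH thresholds: p < \code{p_max} and
#' |rho| > \code{r_min}. Edges carry a positive/negative sign; nodes
#' carry the genus enrichment label (case/control) and their degree.
#'
#' @param genus_table genera x samples abundance matrix.
#' @param probiotic_table samples x probiotics abundance matrix (as
#'   produced by the synthetic generator) or probiotics x samples with
#'   \code{probiotics_in_rows = TRUE}.
#' @param enrichment named character vector genus -> "case"/"control"
#'   (optional node annotation).
#' @param p_max p-value threshold (default 0.05).
#' @param r_min absolute-rho threshold (default 0.1).
#' @param adjust "none" (default, raw p as the filter) or "BH".
#' @param probiotics_in_rows set TRUE when probiotic_table is features x
#'   samples.
#' @return list of class \code{cor_network}: edges
#'   (data.frame source, target, rho, p, sign), nodes (data.frame node,
#'   type, enriched_in, degree), thresholds.
#' @export
build_network <- function(genus_table, probiotic_table, enrichment = NULL,
                          p_max = 0.05, r_min = 0.1, adjust = c("none", "BH"),
                          probiotics_in_rows = FALSE) {
  adjust <- match.arg(adjust)
  if (probiotics_in_rows) probiotic_table <- t(probiotic_table)
  shared <- intersect(colnames(genus_table), rownames(probiotic_table))
  if (!length(shared)) stop("no overlapping samples")
  g <- genus_table[, shared, drop = FALSE]
  p <- probiotic_table[shared, , drop = FALSE]
  pairs <- expand.grid(source = rownames(g), target = colnames(p),
                       stringsAsFactors = FALSE)
  stats_ <- t(mapply(function(gn, pn) {
    s <- spearman_cor(g[gn, ], p[, pn])
    c(s$rho, s$p)
  }, pairs$source, pairs$target))
  pairs$rho <- stats_[, 1]
  pairs$p <- if (adjust == "BH") bh_adjust(stats_[, 2]) else stats_[, 2]
  edges <- pairs[pairs$p < p_max & abs(pairs$rho) > r_min, , drop = FALSE]
  edges$sign <- ifelse(edges$rho > 0, "positive", "negative")
  rownames(edges) <- NULL
  nodes <- data.frame(
    node = c(rownames(g), colnames(p)),
    type = rep(c("genus", "probiotic"), c(nrow(g), ncol(p))),
    stringsAsFactors = FALSE)
  nodes$enriched_in <- if (is.null(enrichment)) NA_character_ else
    unname(enrichment[nodes$node])
  deg <- table(c(edges$source, edges$target))
  nodes$degree <- as.integer(ifelse(nodes$node %in% names(deg),
                                    deg[nodes$node], 0))
  structure(list(edges = edges, nodes = nodes,
                 thresholds = c(p_max = p_max, r_min = r_min)),
            class = "cor_network")
}

#' @export
print.cor_network <- function(x, ...) {
  cat(sprintf("cor_network: %d edges (p < %g, |rho| > %g) over %d genera x %d probiotics\n",
              nrow(x$edges), x$thresholds["p_max"], x$thresholds["r_min"],
              sum(x$nodes$type == "genus"), sum(x$nodes$type == "probiotic")))
  if (nrow(x$edges))
    cat(sprintf("  %d positive, %d negative\n",
                sum(x$edges$sign == "positive"), sum(x$edges$sign == "negative")))
  invisible(x)
}

#' Export a correlation network's edge list as TSV
#' @param network a \code{cor_network}.
#' @param path output path.
#' @export
write_edge_list <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a correlation network as GraphML
#' @param network a \code{cor_network}.
#' @param path output path.
#' @export
write_graphml <- function(network, path) {
  g <- igraph::graph_from_data_frame(
    network$edges[, c("source", "target", "rho", "p", "sign")],
    directed = FALSE, vertices = network$nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
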