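#' Construct an OTU/feature count table
#'
#' A count table is an integer matrix of features (rows) by samples
#' (columns) together with a study label. Column sums are the per-sample
#' sequencing depths.
#'
#' @param counts non-negative integer matrix, features x samples, with
#'   unique rownames (feature ids) and colnames (sample ids).
#' @param study_id single study label.
#' @return An object of class \code{count_table}.
#' @export
count_table <- function(counts, study_id = "study1") {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have feature ids (rownames) and sample ids (colnames)")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate feature id: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample id: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "double"   # integer-valued; double avoids 32-bit overflow on sums
  structure(list(counts = counts, study_id = study_id), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d features x %d samples (study '%s')\n",
              nrow(x$counts), ncol(x$counts), x$study_id))
  d <- sample_depths(x)
  cat(sprintf("depths: min %d, median %d, max %d\n",
              min(d), as.integer(stats::median(d)), max(d)))
  invisible(x)
}

#' Feature ids of a count table
#' @param table a \code{count_table}.
#' @export
feature_ids <- function(table) rownames(table$counts)

#' Sample ids of a count table
#' @param table a \code{count_table}.
#' @export
sample_ids <- function(table) colnames(table$counts)

#' Per-sample sequencing depths (column sums)
#' @param table a \code{count_table}.
#' @export
sample_depths <- function(table) {
  d <- colSums(table$counts)
  stats::setNames(as.integer(round(d)), colnames(table$counts))
}

#' Read a classic tab-separated OTU table
#'
#' First column holds feature ids, header row holds sample ids, cells are
#' non-negative integer counts. Row and column order are preserved.
#'
#' @param path path to a TSV file.
#' @param study_id study label to attach.
#' @param dialect table dialect; only \code{"classic_tsv"} is supported.
#' @return A \code{count_table}.
#' @export
read_count_table <- function(path, study_id = basename(path), dialect = "classic_tsv") {
  dialect <- match.arg(dialect, "classic_tsv")
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2) stop("malformed OTU table (need header plus >=1 feature row): ", path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2) stop("malformed header in ", path)
  samples <- header[-1]
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  feats <- vapply(body, `[[`, character(1), 1)
  mat <- matrix(NA_real_, nrow = length(body), ncol = length(samples),
                dimnames = list(feats, samples))
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) != length(samples) + 1)
      stop("row for feature '", feats[i], "' has ", length(row) - 1,
           " cells, expected ", length(samples))
    v <- suppressWarnings(as.numeric(row[-1]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad))
      stop("non-integer or negative count at feature '", feats[i],
           "', sample '", samples[bad[1]], "'")
    mat[i, ] <- v
  }
  count_table(mat, study_id = study_id)
}

#' Write a count table as classic TSV
#'
#' Round-trips bit-exactly with \code{\link{read_count_table}}.
#'
#' @param table a \code{count_table}.
#' @param path output path.
#' @param id_column name of the leading feature-id column in the header.
#' @export
write_count_table <- function(table, path, id_column = "#OTU ID") {
  mat <- table$counts
  header <- paste(c(id_column, colnames(mat)), collapse = "\t")
  rows <- vapply(seq_len(nrow(mat)), function(i)
    paste(c(rownames(mat)[i], format(mat[i, ], scientific = FALSE, trim = TRUE)),
          collapse = "\t"), character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a taxonomy map (feature id TAB lineage string)
#'
#' Lineages are SILVA-style semicolon-separated rank names
#' (phylum;class;order;family;genus); missing ranks are the explicit token
#' \code{"unassigned"}.
#'
#' @param path TSV path with two columns and no header.
#' @return Named character vector: feature id -> lineage string.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) != 2) stop("taxonomy file must have two tab-separated columns")
  if (anyDuplicated(df[[1]]))
    stop("duplicate feature id in taxonomy: ", df[[1]][duplicated(df[[1]])][1])
  stats::setNames(df[[2]], df[[1]])
}

#' Write a taxonomy map
#' @param taxonomy named character vector (feature id -> lineage).
#' @param path output path.
#' @export
write_taxonomy <- function(taxonomy, path) {
  writeLines(paste(names(taxonomy), taxonomy, sep = "\t"), path)
  invisible(path)
}

#' Read sample metadata (sample_id, study_id, group)
#'
#' @param path TSV path with a header row naming the three columns.
#' @return data.frame with columns sample_id, study_id, group.
#' @export
read_metadata <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("sample_id", "study_id", "group")
  if (!all(need %in% names(df)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample id in metadata: ", df$sample_id[duplicated(df$sample_id)][1])
  if (!all(df$group %in% c("case", "control")))
    stop("group must be 'case' or 'control'")
  df[need]
}

#' Write sample metadata
#' @param metadata data.frame with sample_id, study_id, group.
#' @param path output path.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove samples with low sequencing depth
#'
#' Samples whose depth is strictly below \code{min_depth} are dropped,
#' mirroring the convention that samples with fewer than 10000 sequences
#' are excluded from taxonomic and diversity analyses.
#'
#' @param table a \code{count_table}.
#' @param min_depth minimum depth retained (default 10000).
#' @return Filtered \code{count_table}; removed sample ids are reported via
#'   \code{message}.
#' @export
filter_low_depth <- function(table, min_depth = 10000) {
  stopifnot(min_depth >= 1)
  d <- sample_depths(table)
  keep <- d >= min_depth
  if (!any(keep))
    stop("all samples in study '", table$study_id, "' fall below depth ", min_depth)
  if (any(!keep))
    message("filter_low_depth [", table$study_id, "]: removed ",
            sum(!keep), " sample(s): ", paste(names(d)[!keep], collapse = ", "))
  count_table(table$counts[, keep, drop = FALSE], study_id = table$study_id)
}

#' Rarefy a count table to a common depth
#'
#' Each sample is subsampled without replacement (hypergeometric) to exactly
#' \code{depth} reads, so all post-rarefaction depths are equal.
#'
#' @param table a \code{count_table}.
#' @param depth target depth; defaults to the table's minimum sample depth.
#' @param seed integer seed; output is bit-identical for a fixed seed.
#' @return Rarefied \code{count_table}.
#' @export
rarefy <- function(table, depth = min(sample_depths(table)), seed = 1L) {
  d <- sample_depths(table)
  if (depth > min(d))
    stop("rarefaction depth ", depth, " exceeds sample '",
         names(d)[which.min(d)], "' depth ", min(d))
  if (nrow(table$counts) == 1) {
    # one feature: subsampling can only return the requested depth
    out <- matrix(depth, 1, ncol(table$counts),
                  dimnames = dimnames(table$counts))
  } else {
    out <- withr::with_seed(as.integer(seed), {
      # vegan warns when a table has no singleton counts; that heuristic
      # misfires on perfectly valid count data, so it is silenced here
      withCallingHandlers(
        t(vegan::rrarefy(t(table$counts), sample = depth)),
        warning = function(w) {
          if (grepl("observed counts", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
    })
    dimnames(out) <- dimnames(table$counts)
  }
  count_table(out, study_id = table$study_id)
}

.RANKS <- c("phylum", "class", "order", "family", "genus")

#' Split lineage strings into a rank matrix
#' @noRd
parse_lineage <- function(taxonomy) {
  parts <- strsplit(taxonomy, ";", fixed = TRUE)
  mat <- matrix("unassigned", nrow = length(parts), ncol = 5,
                dimnames = list(names(taxonomy), .RANKS))
  for (i in seq_along(parts)) {
    p <- trimws(parts[[i]])
    p <- p[nzchar(p)]
    if (length(p) > 5) stop("lineage has more than 5 ranks: ", taxonomy[i])
    if (length(p)) mat[i, seq_along(p)] <- p
  }
  mat[mat == ""] <- "unassigned"
  mat
}

#' Collapse a count table to a taxonomic rank
#'
#' Features sharing the same name at \code{rank} have their counts summed;
#' per-sample depths are preserved exactly. Features unmapped at that rank
#' fall into a single \code{"unassigned"} bucket (kept for depth
#' conservation; downstream inference excludes it).
#'
#' @param table a \code{count_table}.
#' @param taxonomy named character vector, feature id -> lineage string.
#' @param rank one of phylum, class, order, family, genus.
#' @return Collapsed \code{count_table}.
#' @export
collapse_taxonomy <- function(table, taxonomy, rank = "genus") {
  if (!rank %in% .RANKS) stop("unknown rank: ", rank)
  ids <- feature_ids(table)
  lin <- parse_lineage(taxonomy[intersect(ids, names(taxonomy))])
  name <- rep("unassigned", length(ids))
  hit <- ids %in% rownames(lin)
  name[hit] <- lin[ids[hit], rank]
  groups <- factor(name, levels = unique(name))
  out <- rowsum(table$counts, group = groups, reorder = FALSE)
  rownames(out) <- levels(groups)
  count_table(out, study_id = table$study_id)
}

#' Relative abundance matrix
#'
#' @param table a \code{count_table}.
#' @return Matrix of proportions; each column sums to 1.
#' @export
relative_abundance <- function(table) {
  d <- colSums(table$counts)
  if (any(d == 0))
    stop("zero-depth sample: ", colnames(table$counts)[which(d == 0)[1]])
  sweep(table$counts, 2, d, "/")
}
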