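#' Assemble a multi-study collection
#'
#' Bundles one count table per study with shared sample metadata and a
#' taxonomy map. Every sample in every table must have exactly one metadata
#' record; studies used for inference need both a case and a control arm.
#'
#' @param tables list of \code{count_table}s, one per study.
#' @param metadata data.frame with sample_id, study_id, group
#'   (case/control).
#' @param taxonomy named character vector, feature id -> lineage string.
#' @param probiotics optional samples x probiotic-feature abundance matrix
#'   (kept alongside, not part of the OTU tables).
#' @return An object of class \code{study_collection}.
#' @export
study_collection <- function(tables, metadata, taxonomy, probiotics = NULL) {
  ids <- vapply(tables, function(t) t$study_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate study id: ", ids[duplicated(ids)][1])
  names(tables) <- ids
  for (t in tables) {
    miss <- setdiff(sample_ids(t), metadata$sample_id)
    if (length(miss))
      stop("samples without metadata in study '", t$study_id, "': ",
           paste(utils::head(miss, 3), collapse = ", "))
  }
  structure(list(tables = tables, metadata = metadata, taxonomy = taxonomy,
                 probiotics = probiotics),
            class = "study_collection")
}

#' @export
print.study_collection <- function(x, ...) {
  cat(sprintf("study_collection: %d studies, %d samples total\n",
              length(x$tables), sum(vapply(x$tables, function(t) ncol(t$counts), 1))))
  for (t in x$tables) {
    g <- collection_groups(x, t$study_id)
    cat(sprintf("  %s: %d control / %d case\n", t$study_id,
                sum(g == "control"), sum(g == "case")))
  }
  invisible(x)
}

#' Study ids of a collection
#' @param collection a \code{study_collection}.
#' @export
study_ids <- function(collection) names(collection$tables)

#' Case/control labels for the samples of one study, in table column order
#' @param collection a \code{study_collection}.
#' @param study study id.
#' @export
collection_groups <- function(collection, study) {
  t <- collection$tables[[study]]
  md <- collection$metadata
  stats::setNames(md$group[match(sample_ids(t), md$sample_id)], sample_ids(t))
}

#' Features common to every study
#'
#' A feature is "common" when it is detected (nonzero) in strictly more
#' than \code{min_prevalence_per_study} of the samples of every study. The
#' result is sorted by descending overall mean relative abundance, ties
#' broken by feature id; this ordering is also the abundance ranking used
#' for forward feature selection.
#'
#' @param collection a \code{study_collection}.
#' @param min_prevalence_per_study per-study detection fraction threshold
#'   (default 0: present in at least one sample of each study).
#' @param exclude_unassigned drop the "unassigned" taxonomy bucket.
#' @return Character vector of feature ids (possibly empty).
#' @export
common_features <- function(collection, min_prevalence_per_study = 0,
                            exclude_unassigned = TRUE) {
  if (length(collection$tables) < 2) stop("need at least 2 studies")
  shared <- Reduce(intersect, lapply(collection$tables, feature_ids))
  if (exclude_unassigned) shared <- setdiff(shared, "unassigned")
  keep <- vapply(shared, function(f) {
    all(vapply(collection$tables, function(t) {
      mean(t$counts[f, ] > 0) > min_prevalence_per_study
    }, logical(1)))
  }, logical(1))
  feats <- shared[keep]
  if (!length(feats)) {
    message("common_features: no feature passes in every study")
    return(character(0))
  }
  ra <- do.call(cbind, lapply(collection$tables,
                              function(t) relative_abundance(t)[feats, , drop = FALSE]))
  mu <- rowMeans(ra)
  feats[order(-mu, feats)]
}

#' Restrict every table of a collection to a shared feature set
#'
#' @param collection a \code{study_collection}.
#' @param features feature ids to keep, in the given order.
#' @return A \code{study_collection} on the harmonized feature space.
#' @export
harmonize_features <- function(collection, features) {
  tables <- lapply(collection$tables, function(t) {
    miss <- setdiff(features, feature_ids(t))
    if (length(miss)) stop("study '", t$study_id, "' lacks features: ",
                           paste(utils::head(miss, 3), collapse = ", "))
    count_table(t$counts[features, , drop = FALSE], study_id = t$study_id)
  })
  study_collection(tables, collection$metadata, collection$taxonomy,
                   probiotics = collection$probiotics)
}

#' Apply depth filtering and per-study rarefaction across a collection
#'
#' Each study is filtered to samples with depth >= \code{min_depth}, then
#' rarefied to its own post-filter minimum depth.
#'
#' @param collection a \code{study_collection}.
#' @param min_depth depth threshold (default 10000).
#' @param seed integer seed for rarefaction.
#' @return A \code{study_collection} of equal-depth tables.
#' @export
preprocess_collection <- function(collection, min_depth = 10000, seed = 1L) {
  tables <- lapply(collection$tables, function(t) {
    t <- filter_low_depth(t, min_depth = min_depth)
    rarefy(t, seed = seed)
  })
  study_collection(tables, collection$metadata, collection$taxonomy,
                   probiotics = collection$probiotics)
}

#' Collapse every table of a collection to a taxonomic rank
#' @param collection a \code{study_collection}.
#' @param rank taxonomic rank (default "genus").
#' @return A \code{study_collection} of collapsed tables.
#' @export
collapse_collection <- function(collection, rank = "genus") {
  tables <- lapply(collection$tables, collapse_taxonomy,
                   taxonomy = collection$taxonomy, rank = rank)
  study_collection(tables, collection$metadata, collection$taxonomy,
                   probiotics = collection$probiotics)
}
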