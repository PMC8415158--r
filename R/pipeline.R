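#' Configuration for a full pipeline run
#'
#' Collects every tunable of the end-to-end analysis in one serializable
#' list. Either a \code{synthetic_spec} (demo mode) or input paths
#' (directory of per-study OTU tables + taxonomy.tsv + metadata.tsv)
#' must be supplied.
#'
#' @param spec optional \code{\link{synthetic_spec}} for demo mode.
#' @param input_dir optional directory holding \code{*_otu_table.tsv},
#'   \code{taxonomy.tsv}, \code{metadata.tsv} (and optionally
#'   \code{probiotics.tsv}).
#' @param min_depth depth-filter threshold.
#' @param rank taxonomic rank for genus-level stages.
#' @param n_perm PERMANOVA permutations.
#' @param n_trees,k_folds,epsilon random-forest settings.
#' @param fdr,p_max,r_min thresholds for differential taxa and network
#'   edges.
#' @param run_ml run the (slower) classifier stages.
#' @param seed integer master seed.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(spec = NULL, input_dir = NULL, min_depth = 10000,
                       rank = "genus", n_perm = 10000, n_trees = 500,
                       k_folds = 10, epsilon = 0.001, fdr = 0.05,
                       p_max = 0.05, r_min = 0.1, run_ml = TRUE, seed = 1L) {
  if (is.null(spec) && is.null(input_dir))
    stop("provide a synthetic spec or an input directory")
  structure(list(spec = spec, input_dir = input_dir, min_depth = min_depth,
                 rank = rank, n_perm = n_perm, n_trees = n_trees,
                 k_folds = k_folds, epsilon = epsilon, fdr = fdr,
                 p_max = p_max, r_min = r_min, run_ml = run_ml,
                 seed = as.integer(seed)), class = "run_config")
}

#' Read a collection from a directory of pipeline TSVs
#'
#' Counterpart of \code{\link{write_collection}}.
#'
#' @param dir directory holding \code{*_otu_table.tsv},
#'   \code{taxonomy.tsv} and \code{metadata.tsv}.
#' @return A \code{study_collection}.
#' @export
read_collection <- function(dir) {
  files <- list.files(dir, pattern = "_otu_table\\.tsv$", full.names = TRUE)
  if (!length(files)) stop("no *_otu_table.tsv files in ", dir)
  tables <- lapply(files, function(f)
    read_count_table(f, study_id = sub("_otu_table\\.tsv$", "", basename(f))))
  taxonomy <- read_taxonomy(file.path(dir, "taxonomy.tsv"))
  metadata <- read_metadata(file.path(dir, "metadata.tsv"))
  prob_path <- file.path(dir, "probiotics.tsv")
  probiotics <- if (file.exists(prob_path))
    as.matrix(utils::read.table(prob_path, sep = "\t", header = TRUE,
                                check.names = FALSE)) else NULL
  study_collection(tables, metadata, taxonomy, probiotics = probiotics)
}

#' Run the full cross-study analysis
#'
#' Executes the stages in order: depth filter -> per-study rarefaction ->
#' genus collapse -> alpha diversity -> Bray-Curtis PCoA + PERMANOVA ->
#' median-dichotomized OR meta-analysis (alpha metrics, Bray-Curtis
#' dispersion, common genera) -> FDR-controlled Wilcoxon genus summary ->
#' random-forest stages (within-study LOO, transfer matrix, LOOS,
#' importance) -> genus-probiotic network (when probiotic abundances are
#' present). All tables are written to \code{out_dir} together with a JSON
#' run manifest; any stage failure aborts naming the stage.
#'
#' @param config a \code{\link{run_config}}.
#' @param out_dir output directory (created).
#' @return Invisible list of the in-memory results (collection fits,
#'   summaries, matrices); files land in \code{out_dir}.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    cat(line, "\n", sep = "", file = log_path, append = TRUE)
    message(line)
  }
  stage <- function(name, expr) {
    logf("stage: %s", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  res <- list(config = config)

  loaded <- stage("load", {
    if (!is.null(config$spec)) generate_collection(config$spec)
    else list(collection = read_collection(config$input_dir), truth = NULL)
  })
  collection <- loaded$collection
  res$truth <- loaded$truth
  collection <- stage("filter+rarefy",
    preprocess_collection(collection, min_depth = config$min_depth,
                          seed = config$seed))
  genus <- stage("collapse", collapse_collection(collection, rank = config$rank))
  res$collection <- collection; res$genus <- genus

  alpha <- stage("alpha_diversity", {
    a <- do.call(rbind, lapply(collection$tables, alpha_diversity))
    utils::write.table(a, file.path(out_dir, "alpha_diversity.tsv"),
                       sep = "\t", quote = FALSE)
    a
  })
  res$alpha <- alpha

  res$permanova <- stage("pcoa+permanova", {
    pooled <- do.call(cbind, lapply(genus$tables, relative_abundance))
    dm <- vegan::vegdist(t(pooled), method = "bray")
    ord <- pcoa(dm, k = 2)
    utils::write.table(ord$points, file.path(out_dir, "pcoa_coords.tsv"),
                       sep = "\t", quote = FALSE)
    md <- collection$metadata
    grp <- md$group[match(labels(dm), md$sample_id)]
    pm <- permanova(dm, grp, n_perm = config$n_perm, seed = config$seed)
    logf("PERMANOVA group: F = %.3f, p = %.4g", pm$pseudo_F, pm$p_value)
    pm
  })

  res$meta <- stage("or_meta", {
    fits <- list()
    for (metric in c("richness", "shannon", "evenness", "bray_dispersion")) {
      fit <- tryCatch(suppressWarnings(meta_analyze_metric(collection, metric)),
                      error = function(e) {
                        logf("metric '%s' skipped: %s", metric,
                             conditionMessage(e))
                        NULL
                      })
      if (!is.null(fit)) fits[[metric]] <- fit
    }
    for (f in names(fits))
      write_forest_data(fits[[f]], file.path(out_dir, paste0("forest_", f, ".tsv")))
    fits
  })

  res$taxa <- stage("differential_taxa", {
    ts <- summarize_taxa(genus, fdr = config$fdr)
    write_taxon_summary(ts, file.path(out_dir, "taxon_summary.tsv"))
    ts
  })

  if (config$run_ml) {
    res$transfer <- stage("transfer_matrix", {
      tm <- transfer_matrix(genus, seed = config$seed,
                            n_trees = config$n_trees, epsilon = config$epsilon)
      utils::write.table(tm$auc, file.path(out_dir, "transfer_auc.tsv"),
                         sep = "\t", quote = FALSE)
      tm
    })
    res$loos <- stage("loos_validate", {
      lv <- loos_validate(genus, seed = config$seed, n_trees = config$n_trees,
                          epsilon = config$epsilon)
      utils::write.table(data.frame(study = names(lv), auc = lv),
                         file.path(out_dir, "loos_auc.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      lv
    })
    res$importance <- stage("importance", {
      feats <- common_features(genus)
      x <- do.call(rbind, lapply(study_ids(genus), function(s)
        study_design(genus, s, feats)))
      y <- unlist(lapply(study_ids(genus), function(s)
        collection_groups(genus, s)), use.names = FALSE)
      imp <- importance_ranking(x, y, n_trees = config$n_trees,
                                seed = config$seed)
      utils::write.table(imp, file.path(out_dir, "importance.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      imp
    })
  }

  if (!is.null(collection$probiotics)) {
    res$network <- stage("probiotic_network", {
      ra <- do.call(cbind, lapply(genus$tables, relative_abundance))
      ts <- res$taxa
      enr <- stats::setNames(
        ifelse(ts$case_mean > ts$control_mean, "case", "control"), ts$taxon)
      keep <- intersect(ts$taxon, rownames(ra))
      net <- build_network(ra[keep, , drop = FALSE], collection$probiotics,
                           enrichment = enr, p_max = config$p_max,
                           r_min = config$r_min)
      write_edge_list(net, file.path(out_dir, "network_edges.tsv"))
      write_graphml(net, file.path(out_dir, "network.graphml"))
      net
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("micrometa")),
    r_version = R.version.string,
    seed = config$seed,
    config = config[setdiff(names(config), "spec")],
    synthetic = !is.null(config$spec),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  logf("done")
  invisible(res)
}

#' Run the synthetic end-to-end demo
#'
#' Generates a scaled-down multi-study cohort with planted effects and
#' pushes it through \code{\link{run_pipeline}}.
#'
#' @param seed integer seed.
#' @param out_dir output directory.
#' @param n_studies,n_per_arm size of the demo cohort.
#' @param run_ml include the classifier stages.
#' @return Invisible result list from \code{\link{run_pipeline}}.
#' @export
demo_run <- function(seed = 1L, out_dir = tempfile("micrometa_demo"),
                     n_studies = 4, n_per_arm = 30, run_ml = TRUE) {
  spec <- synthetic_spec(
    n_studies = n_studies, n_case = n_per_arm, n_control = n_per_arm,
    n_features = 120, n_genera = 24, study_effect_sd = 0.8,
    planted_features = planted_genus_effects(n_features = 120, n_genera = 24,
                                             n_up = 3, n_down = 3,
                                             log2fc = 1.5, seed = seed),
    depth_range = c(12000, 20000), n_probiotic_features = 6,
    probiotic_coupling = NULL, seed = seed)
  config <- run_config(spec = spec, min_depth = 10000, n_perm = 999,
                       run_ml = run_ml, seed = seed)
  run_pipeline(config, out_dir)
}

#' Plant genus-level fold-changes for a synthetic spec
#'
#' Picks \code{n_up} case-enriched and \code{n_down} case-depleted genera
#' and returns the per-OTU log2 fold-change vector covering all their
#' member OTUs (features are assigned to genera cyclically, matching the
#' generator's taxonomy).
#'
#' @param n_features,n_genera dimensions matching the target spec.
#' @param n_up,n_down planted genus counts per direction.
#' @param log2fc absolute log2 fold-change.
#' @param seed integer seed for the genus draw.
#' @return Named numeric vector feature id -> log2 fold-change.
#' @export
planted_genus_effects <- function(n_features, n_genera, n_up = 5, n_down = 5,
                                  log2fc = 1.5, seed = 1L) {
  genus_idx <- rep(seq_len(n_genera), length.out = n_features)
  withr::with_seed(as.integer(seed) + 23L, {
    g <- sample(seq_len(n_genera), n_up + n_down)
    lfc <- rep(c(log2fc, -log2fc), c(n_up, n_down))
    v <- numeric(0)
    for (i in seq_along(g)) {
      feats <- sprintf("OTU%04d", which(genus_idx == g[i]))
      v <- c(v, stats::setNames(rep(lfc[i], length(feats)), feats))
    }
    v
  })
}
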