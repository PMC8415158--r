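#' Seven-study case/control design emulated by the default generator
#'
#' Per-study control (HC) and case (T2DM) arm sizes of the seven published
#' 16S gut-microbiome T2DM cohorts that the synthetic generator mirrors
#' (543 controls, 600 cases, 1143 samples in total).
#'
#' @return data.frame with columns study, n_control, n_case.
#' @export
paperlike_design <- function() {
  data.frame(
    study = c("PRJNA325931", "SRP168691", "PRJNA554535", "PRJNA472187",
              "PRJNA607849", "ERP107659", "PRJNA670300"),
    n_control = c(84, 35, 20, 76, 193, 40, 95),
    n_case    = c(28, 65, 40, 68, 98, 20, 281),
    stringsAsFactors = FALSE
  )
}

#' Specify a synthetic multi-study cohort
#'
#' The generative model is logistic-normal/multinomial: each sample's
#' expected composition is softmax(base + study effect + group effect +
#' sample noise) on the log scale, so study batch effects and planted
#' case/control fold-changes are additive in log space. Counts are drawn
#' multinomially at a per-sample depth uniform over the study's depth
#' range.
#'
#' @param n_studies number of studies.
#' @param n_case,n_control integer vectors (recycled) of arm sizes; each
#'   must be >= 2.
#' @param n_features number of OTU-level features.
#' @param n_genera number of genera the features are assigned to.
#' @param base_log_abundance baseline log-abundance vector (length
#'   \code{n_features}); drawn N(0, 1.3) from \code{seed} when NULL.
#' @param study_effect_sd sd of per-study, per-feature log-scale batch
#'   effects (0 = no batch effect).
#' @param sample_noise_sd sd of per-sample log-scale noise.
#' @param planted_features named numeric vector: feature id -> log2
#'   fold-change in cases (controls are baseline). NULL = no planted
#'   effects.
#' @param depth_range n_studies x 2 matrix of per-study [min, max]
#'   sequencing depth; a single length-2 vector is recycled.
#' @param n_probiotic_features number of probiotic stand-in features
#'   (separate species-level rows, not part of the OTU table).
#' @param probiotic_coupling data.frame(probiotic, genus, rho) of signed
#'   rank-correlation couplings; uncoupled probiotics are independent
#'   noise.
#' @param seed integer seed; the whole cohort is bit-reproducible from it.
#' @return An object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_studies = 2, n_case = 20, n_control = 20,
                           n_features = 100, n_genera = 20,
                           base_log_abundance = NULL,
                           study_effect_sd = 0, sample_noise_sd = 0.6,
                           planted_features = NULL,
                           depth_range = c(2000, 4000),
                           n_probiotic_features = 0,
                           probiotic_coupling = NULL,
                           seed = 1L) {
  n_case <- rep_len(as.integer(n_case), n_studies)
  n_control <- rep_len(as.integer(n_control), n_studies)
  if (any(n_case < 2) || any(n_control < 2)) stop("each arm needs >= 2 samples")
  if (is.null(dim(depth_range)))
    depth_range <- matrix(rep(depth_range, each = n_studies), ncol = 2)
  if (any(depth_range[, 1] < 1) || any(depth_range[, 2] < depth_range[, 1]))
    stop("invalid depth_range")
  if (n_genera > n_features) stop("n_genera must be <= n_features")
  if (is.null(base_log_abundance))
    base_log_abundance <- withr::with_seed(as.integer(seed) + 7L,
                                           stats::rnorm(n_features, 0, 1.3))
  if (length(base_log_abundance) != n_features)
    stop("base_log_abundance must have length n_features")
  feat_ids <- sprintf("OTU%04d", seq_len(n_features))
  if (!is.null(planted_features)) {
    if (!all(is.finite(planted_features))) stop("fold-changes must be finite")
    if (!all(names(planted_features) %in% feat_ids))
      stop("planted feature not in generated feature set: ",
           setdiff(names(planted_features), feat_ids)[1])
  }
  structure(list(
    n_studies = n_studies, n_case = n_case, n_control = n_control,
    n_features = n_features, n_genera = n_genera,
    base_log_abundance = base_log_abundance,
    study_effect_sd = study_effect_sd, sample_noise_sd = sample_noise_sd,
    planted_features = planted_features, depth_range = depth_range,
    n_probiotic_features = n_probiotic_features,
    probiotic_coupling = probiotic_coupling,
    seed = as.integer(seed)), class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("synthetic_spec: %d studies, %d features in %d genera, seed %d\n",
              x$n_studies, x$n_features, x$n_genera, x$seed))
  cat(sprintf("arms: %s\n", paste(x$n_control, x$n_case, sep = "/", collapse = ", ")))
  cat(sprintf("batch sd %.2f, %d planted features, %d probiotics\n",
              x$study_effect_sd, length(x$planted_features),
              x$n_probiotic_features))
  invisible(x)
}

#' Default cohort specification emulating the seven-study T2DM design
#'
#' Seven studies with the arm sizes of \code{\link{paperlike_design}}
#' (1143 samples), 300 OTUs in 60 genera, 5 case-enriched and 5
#' case-depleted planted genera, strong study batch effects, and 10
#' probiotic stand-in features coupled to the planted genera.
#'
#' @param seed integer seed.
#' @param n_case,n_control optional arm-size overrides (recycled over 7
#'   studies).
#' @param planted_log2fc absolute log2 fold-change of the planted genera.
#' @param study_effect_sd batch-effect sd (log scale).
#' @return A \code{synthetic_spec}.
#' @export
default_paperlike_spec <- function(seed = 1L, n_case = NULL, n_control = NULL,
                                   planted_log2fc = 1.5, study_effect_sd = 1.0) {
  des <- paperlike_design()
  if (is.null(n_case)) n_case <- des$n_case
  if (is.null(n_control)) n_control <- des$n_control
  n_features <- 300L; n_genera <- 60L
  otus_per_genus <- split(seq_len(n_features),
                          rep(seq_len(n_genera), length.out = n_features))
  planted <- withr::with_seed(as.integer(seed) + 11L, {
    g <- sample(seq_len(n_genera), 10)
    lfc <- rep(c(planted_log2fc, -planted_log2fc), each = 5)
    v <- numeric(0)
    for (i in seq_along(g))
      v <- c(v, stats::setNames(rep(lfc[i], length(otus_per_genus[[g[i]]])),
                                sprintf("OTU%04d", otus_per_genus[[g[i]]])))
    v
  })
  # per-study depth windows: distinct centers, some mass below the 10000
  # depth filter so preprocessing has realistic work to do
  lo <- withr::with_seed(as.integer(seed) + 13L,
                         sample(seq(9000, 16000, by = 500), 7, replace = TRUE))
  depth_range <- cbind(lo, lo + 15000)
  prob_genera <- withr::with_seed(as.integer(seed) + 17L, {
    pg <- planted_genera_of(planted, n_features, n_genera)
    data.frame(probiotic = sprintf("Probiotic%02d", 1:10),
               genus = sample(pg, 10, replace = TRUE),
               rho = round(stats::runif(10, 0.3, 0.7), 2) *
                 sample(c(-1, 1), 10, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  synthetic_spec(n_studies = 7, n_case = n_case, n_control = n_control,
                 n_features = n_features, n_genera = n_genera,
                 study_effect_sd = study_effect_sd, sample_noise_sd = 0.6,
                 planted_features = planted, depth_range = depth_range,
                 n_probiotic_features = 10,
                 probiotic_coupling = prob_genera, seed = seed)
}

#' Genus names carrying a planted effect
#' @noRd
planted_genera_of <- function(planted, n_features, n_genera) {
  idx <- as.integer(sub("OTU", "", names(planted)))
  g <- rep(seq_len(n_genera), length.out = n_features)[idx]
  unique(sprintf("Genus%03d", g))
}

#' Generate a synthetic multi-study cohort with ground truth
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return list with components \code{collection} (a
#'   \code{study_collection}; probiotic abundances, when requested, ride
#'   along as \code{collection$probiotics}) and \code{truth} (planted
#'   log2 fold-changes, per-study batch-effect vectors, probiotic
#'   coupling table).
#' @export
generate_collection <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, generate_collection_impl(spec))
}

generate_collection_impl <- function(spec) {
  nf <- spec$n_features
  feat_ids <- sprintf("OTU%04d", seq_len(nf))
  genus_idx <- rep(seq_len(spec$n_genera), length.out = nf)
  # deterministic nested lineage: 3 genera per family, 3 families per
  # order, and so on up to phylum
  fam <- ceiling(genus_idx / 3); ord <- ceiling(fam / 3)
  cls <- ceiling(ord / 3); phy <- ceiling(cls / 3)
  taxonomy <- stats::setNames(sprintf(
    "Phylum%02d;Class%02d;Order%02d;Family%02d;Genus%03d",
    phy, cls, ord, fam, genus_idx), feat_ids)

  lfc <- numeric(nf); names(lfc) <- feat_ids
  if (!is.null(spec$planted_features))
    lfc[names(spec$planted_features)] <- spec$planted_features
  base <- balance_planted_mass(spec$base_log_abundance, lfc)

  tables <- vector("list", spec$n_studies)
  md <- list()
  study_effects <- vector("list", spec$n_studies)
  for (s in seq_len(spec$n_studies)) {
    sid <- sprintf("Study%d", s)
    delta <- stats::rnorm(nf, 0, spec$study_effect_sd)
    study_effects[[s]] <- stats::setNames(delta, feat_ids)
    n_ctl <- spec$n_control[s]; n_cas <- spec$n_case[s]
    n <- n_ctl + n_cas
    grp <- c(rep("control", n_ctl), rep("case", n_cas))
    depths <- sample(seq(spec$depth_range[s, 1], spec$depth_range[s, 2]),
                     n, replace = TRUE)
    counts <- matrix(0, nrow = nf, ncol = n)
    for (j in seq_len(n)) {
      eta <- base + delta +
        (grp[j] == "case") * log(2) * lfc +
        stats::rnorm(nf, 0, spec$sample_noise_sd)
      p <- exp(eta - max(eta)); p <- p / sum(p)
      counts[, j] <- stats::rmultinom(1, size = depths[j], prob = p)
    }
    dimnames(counts) <- list(feat_ids, sprintf("%s_S%03d", sid, seq_len(n)))
    tables[[s]] <- count_table(counts, study_id = sid)
    md[[s]] <- data.frame(sample_id = colnames(counts), study_id = sid,
                          group = grp, stringsAsFactors = FALSE)
  }
  metadata <- do.call(rbind, md)

  probiotics <- NULL
  if (spec$n_probiotic_features > 0)
    probiotics <- generate_probiotics(spec, tables, metadata, genus_idx)

  collection <- study_collection(tables, metadata, taxonomy,
                                 probiotics = probiotics)
  truth <- list(planted = lfc[lfc != 0],
                planted_genera = if (any(lfc != 0))
                  planted_genera_of(lfc[lfc != 0], nf, spec$n_genera)
                else character(0),
                study_effects = study_effects,
                coupling = spec$probiotic_coupling)
  list(collection = collection, truth = truth)
}

# Mass-balance planted effects under compositional closure: when both
# case-enriched and case-depleted taxa are planted, the depleted taxa's
# baseline log-abundances are shifted by a common constant so the
# expected total mass of the planted set is identical in cases and
# controls. Null taxa then keep the same expected relative abundance in
# both arms, so planted truth stays clean for FDR calibration. With
# one-directional planting no balance is possible and the base is
# returned unchanged.
balance_planted_mass <- function(base, lfc) {
  up <- lfc > 0; dn <- lfc < 0
  if (!any(up) || !any(dn)) return(base)
  s_up <- sum(exp(base[up]) * (2^lfc[up] - 1))   # mass gained by enriched taxa
  s_dn <- sum(exp(base[dn]) * (2^lfc[dn] - 1))   # mass lost by depleted taxa (< 0)
  base[dn] <- base[dn] + log(s_up / -s_dn)
  base
}

# Probiotic stand-ins: Gaussian-copula coupling of a probiotic's ranks to a
# target genus's pooled relative-abundance ranks, then pushed through exp()
# (Spearman statistics are invariant to the monotone map).
generate_probiotics <- function(spec, tables, metadata, genus_idx) {
  genus_ra <- do.call(cbind, lapply(tables, function(t) {
    g <- collapse_taxonomy(t,
      stats::setNames(sprintf("u;u;u;u;Genus%03d", genus_idx), feature_ids(t)),
      rank = "genus")
    relative_abundance(g)
  }))
  n <- ncol(genus_ra)
  pro_ids <- sprintf("Probiotic%02d", seq_len(spec$n_probiotic_features))
  out <- matrix(NA_real_, nrow = n, ncol = length(pro_ids),
                dimnames = list(colnames(genus_ra), pro_ids))
  cpl <- spec$probiotic_coupling
  for (k in seq_along(pro_ids)) {
    rho <- 0; target_z <- NULL
    if (!is.null(cpl) && pro_ids[k] %in% cpl$probiotic) {
      row <- cpl[match(pro_ids[k], cpl$probiotic), ]
      rho <- row$rho
      target <- genus_ra[row$genus, ]
      target_z <- stats::qnorm((rank(target, ties.method = "average") - 0.5) / n)
    }
    eps <- stats::rnorm(n)
    z <- if (is.null(target_z)) eps else rho * target_z + sqrt(1 - rho^2) * eps
    out[, k] <- exp(z)
  }
  out
}

#' Write a collection to disk in the package's TSV dialects
#'
#' Emits one OTU table per study, the taxonomy map, the sample metadata,
#' and (for synthetic cohorts) a ground-truth JSON.
#'
#' @param collection a \code{study_collection}.
#' @param dir output directory (created if missing).
#' @param truth optional ground-truth list from
#'   \code{\link{generate_collection}}.
#' @return \code{dir}, invisibly.
#' @export
write_collection <- function(collection, dir, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (t in collection$tables)
    write_count_table(t, file.path(dir, paste0(t$study_id, "_otu_table.tsv")))
  write_taxonomy(collection$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_metadata(collection$metadata, file.path(dir, "metadata.tsv"))
  if (!is.null(collection$probiotics))
    utils::write.table(collection$probiotics, file.path(dir, "probiotics.tsv"),
                       sep = "\t", quote = FALSE)
  if (!is.null(truth))
    jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
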