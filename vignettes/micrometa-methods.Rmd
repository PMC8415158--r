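---
title: "Methods: cross-study microbiome meta-analysis with median-dichotomized odds ratios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-study microbiome meta-analysis with median-dichotomized odds ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micrometa)
```

# The problem

Case/control 16S rRNA gut-microbiome studies of the same disease routinely
disagree: different populations, DNA extraction kits, amplified regions and
sequencing platforms impose study-level batch effects that are often larger
than the disease signal itself. Pooling raw samples across such studies is
therefore misleading — ordinations cluster by study, not by phenotype — and
the appropriate inferential unit is the *study*, combined by meta-analysis.

`micrometa` implements a complete cross-study workflow for this setting:
per-study diversity profiling, a median-dichotomization odds-ratio (OR)
meta-analysis as the core estimator, FDR-controlled differential genera,
random-forest classification with cross-study validation, and a
genus–probiotic correlation network. A synthetic multi-study cohort
generator with planted ground truth makes every stage testable end to end.

# The core estimator: median-dichotomized odds ratios

Any per-sample scalar metric (observed-OTU richness, Shannon entropy,
Pielou evenness, a per-sample beta-diversity dispersion, or the relative
abundance of one taxon) is converted into a per-study 2x2 table:

1. Within each study, the metric's median is computed over **all** samples
   (cases and controls pooled).
2. Samples strictly above the median are "positive"; ties at the median
   count as negative. This strict reading makes the statistic invariant
   under any strictly monotone transform of the metric, and exactly
   antisymmetric under label swap (OR maps to 1/OR).
3. With a = positive controls, b = negative controls, c = positive cases,
   d = negative cases, the study's odds ratio is OR = ad/bc. When any cell
   is zero, 0.5 is added to all four cells (Haldane–Anscombe) before the
   OR, its log, and the Woolf standard error
   sqrt(1/a + 1/b + 1/c + 1/d) are computed.
4. Orientation: OR > 1 means the metric is *higher in controls*.

Per-study log ORs are pooled with the standard inverse-variance machinery:

* **Fixed effects (FE):** weights \(w_i = 1/se_i^2\), pooled
  \(\hat\theta = \sum w_i \theta_i / \sum w_i\).
* **Heterogeneity:** Cochran's \(Q = \sum w_i(\theta_i - \hat\theta)^2\)
  on \(k-1\) df; \(I^2 = \max(0, (Q - df)/Q)\times 100\).
* **Random effects (DerSimonian–Laird):**
  \(\tau^2 = \max\!\big(0, (Q - df)/(\sum w_i - \sum w_i^2/\sum w_i)\big)\),
  weights \(1/(se_i^2 + \tau^2)\).

Both models are always computed (`or_meta()` keeps the second fit in
`$alternate`); "significant" means the 95% CI excludes OR = 1. The pooling
arithmetic is authored in the package and is verified in the test suite
against an independent step-by-step evaluation of the DL formulas and
against `metafor::rma(method = "DL")`.

Design choices worth stating explicitly:

* The median is pooled over both arms, not computed per arm, and ties
  count negative — the strict reading of "above the median".
* The per-sample beta-diversity scalar is the **median** Bray-Curtis
  distance of a sample to all other samples of the same study
  (`per_sample_dispersion()`); a mean option is provided. A distance
  matrix has no canonical per-sample reduction, so this choice is
  configurable and documented rather than hidden.
* z = 1.959964 (normal quantile) throughout; no small-sample t correction,
  matching standard forest-plot practice.

# Diversity, ordination, testing

Alpha diversity: richness = observed features, Shannon in natural log,
Pielou evenness J = H/ln(richness) (0 and flagged when richness < 2).
Comparing alpha metrics across samples requires equal depth, so
`alpha_diversity()` warns on unrarefied input.

Beta diversity: Bray-Curtis via `vegan::vegdist`, PCoA by classical metric
scaling (`stats::cmdscale`; negative eigenvalues are reported, not
corrected — only 2-D visualization is targeted), PERMANOVA via
`vegan::adonis2` with free label permutation and
p = (1 + #{F_perm >= F_obs})/(1 + n_perm), and taxon vector fitting via
`vegan::envfit`. These are standard steps, so the package wraps the field's
standard implementations behind its own stable interfaces and seeds them
explicitly; tests verify the pseudo-F against a hand-computed
within/between decomposition on a toy design.

Per-taxon inference uses the two-sided Wilcoxon rank-sum test on pooled
samples (exact enumeration when both arms are small and untied) with
Benjamini–Hochberg FDR control across the common taxa of the analyzed
rank. Abundances are reported as percent mean ± sd per arm.

# Preprocessing conventions

* Samples with depth below 10000 reads are removed *first*; each study is
  then rarefied (without replacement, hypergeometric, seeded) to its own
  post-filter minimum depth. Rarefying after filtering avoids throwing
  away depth in studies whose minimum was set by a sample that is going to
  be discarded anyway.
* Taxonomic collapse sums counts within the rank name and preserves
  per-sample depth exactly; features unmapped at the rank fall into one
  `"unassigned"` bucket that is retained for depth conservation but
  excluded from genus-level inference and rankings.
* "Common" features are those detected (nonzero) in strictly more than a
  per-study prevalence fraction (default 0, i.e. at least one sample) of
  every study, ranked by descending overall mean relative abundance with
  ties broken by id. This minimal literal definition is a configurable
  threshold, not a fixed rule.

# Random-forest stages

All forests use 500 trees (the remaining hyperparameters stay at the
`randomForest` defaults: mtry = sqrt(p), unlimited depth) and every fit is
seeded, so each procedure is bit-reproducible.

* **Forward feature selection** (`stepwise_select()`): a single forward
  pass over the abundance-ranked common features; a candidate is kept iff
  it improves stratified 10-fold CV AUC by at least epsilon (default
  0.001). "Stepwise selection driven by 10-fold CV" admits several
  procedures; the forward-only single pass is the simplest one consistent
  with selecting predictive features and eliminating uninformative ones,
  and the threshold is exposed as a parameter. If nothing beats the 0.5
  baseline the single most abundant feature is kept so downstream models
  always have a design matrix.
* **Within-study evaluation** (`evaluate_loo()`): per-sample leave-one-out
  probabilities; AUC by the rank (Mann–Whitney) formulation;
  sensitivity/specificity at the Youden-optimal threshold on the same
  out-of-fold probabilities; 95% CIs by a 2000-replicate bootstrap over
  samples. Beyond 500 samples the per-sample LOO is replaced by stratified
  10-fold out-of-fold probabilities (logged), which bounds cost with no
  practical loss. Note that LOO AUC under label permutation is
  pessimistically biased at small n (the held-out sample's class is always
  under-represented in training), a bias of order 1/n that the test suite
  accounts for by using a realistically sized study.
* **Transfer matrix** (`transfer_matrix()`): diagonal = within-study CV
  AUC on that study's selected features; off-diagonal (i, j) = the model
  trained on study i applied to study j. Cross-study scoring uses the
  intersection feature space.
* **LOOS validation** (`loos_validate()`): for each held-out study, selection
  and training on all remaining studies pooled, scored on the hold-out.
* **Disease specificity** (`specificity_assess()`): case samples of other
  collections are scored by the reference model (missing features
  zero-filled and reported); reference-case probabilities are taken
  out-of-bag to avoid resubstitution bias; Welch t-tests compare each
  collection's case probabilities with the reference's.

# The genus–probiotic network

Every genus x probiotic pair is tested by Spearman correlation on pooled
samples (per-study use is possible by subsetting); an edge is retained iff
**both** p < 0.05 and |rho| > 0.1 hold, with raw p-values as the filter by
default (a BH mode is available but off, since the edge filter is a screen,
not an inferential claim). Edges carry a sign; nodes carry enrichment
labels and degree. Exports: edge-list TSV and GraphML.

# The synthetic cohort generator

`generate_collection()` draws, for each study and sample,

    eta = base + delta_study + 1[case] * log(2) * log2FC + noise
    counts ~ Multinomial(depth, softmax(eta))

with `delta_study ~ N(0, study_effect_sd)` per feature (the batch effect),
`noise ~ N(0, sample_noise_sd)` per sample and feature, and depth uniform
over the study's depth range. The logistic-normal/multinomial form makes
batch effects and planted fold-changes additive on the log scale, so the
planted truth has simple algebra. The generator emulates the seven-study
case/control design in `paperlike_design()` (arm sizes 20–281, 1143
samples in total), study-specific depth windows crossing the 10000-read
filter, and batch effects strong enough to dominate ordination.

Two design points deserve emphasis:

* **Mass balancing.** Under compositional closure, planting fold-changes
  on some taxa changes the *total* expected mass, which would shift every
  null taxon's relative abundance in the case arm and corrupt FDR
  calibration. When both enriched and depleted taxa are planted, the
  depleted taxa's baseline log-abundances are therefore shifted by the
  constant that makes the expected planted mass identical in the two arms;
  null taxa then stay null. With one-directional planting no balance is
  possible and none is attempted (sign-recovery tests do not need it).
* **Probiotic stand-ins** are species-level features that 16S genus
  profiles cannot deliver, so they are generated as a separate
  samples x probiotics table (not appended to the OTU table, which would
  distort composition): a Gaussian copula couples each probiotic's ranks
  to its target genus's pooled relative-abundance ranks at the specified
  rho, then an arbitrary monotone map produces abundances — Spearman
  statistics are invariant to that map.

Default generator settings (chosen once, as what a practitioner would call
realistic for 16S cohorts of this kind): 300 OTUs in 60 genera, baseline
log-abundances N(0, 1.3), sample noise sd 0.6, batch sd 1.0, five
case-enriched and five case-depleted planted genera at |log2FC| = 1.5,
per-study depth windows of width 15000 starting between 9000 and 16000.

What the generator does **not** emulate: phylogenetic correlation between
taxa, over-dispersion beyond the logistic-normal, study-by-disease
interaction in the effect itself (each study manifests the same planted
effect, shifted by its batch), longitudinal structure, or realistic depth
distributions. Passing tests therefore demonstrate that the machinery
recovers truth under a clean compositional model — not that any particular
real dataset will behave as well. In particular, transfer degradation in
the generator arises purely from covariate shift (batch-shifted feature
distributions), which is one, but not the only, mechanism in real data.

# Problem sizes and numerical choices

The test-suite simulations run at deliberately scaled-down sizes chosen to
keep the full suite comfortably reproducible on a laptop: coverage and
calibration at 500 replicates with 7 small studies or 16-sample designs
and 999 permutations; classifier checks on one 200-sample study; the
cross-study ordering experiment at 5 studies x 60 samples with ~20 genera.
The same quantities recomputed at larger sizes only tighten, never change,
the qualitative conclusions.

Ties in AUC contribute 1/2 by the average-rank formulation; the Youden
threshold is searched over observed probability cut points with "positive"
meaning strictly above; rarefaction below a sample's depth is an error,
not a silent skip; degenerate studies (all metric values tied at the
median) are dropped from a meta-analysis with a warning and the degrees of
freedom adjusted; Spearman p-values use the t approximation on n - 2 df,
with |rho| = 1 mapped to p = 0.

The pipeline (`run_pipeline()`) executes stages in a single pass and
writes every artifact plus a JSON manifest (package version, seed,
config); intermediate caching was considered and rejected — at these
problem sizes a full rerun is cheaper than correct cache invalidation.

# Known limitations

* The OR machinery treats studies as independent and the Woolf SE as
  exact; with very small arms the dichotomized cells are hypergeometric-
  like and the normal CI is approximate (the coverage simulation in the
  test suite quantifies this at the sizes used).
* Table-2-style Wilcoxon p-values pool samples across studies and thus
  ignore study as a stratum; per-study forest data are emitted alongside
  for transparency.
* PERMANOVA permutes labels freely; no strata/blocking by study within a
  single call (condition on study by running per study).
* Random-forest probabilities are uncalibrated vote fractions.
* No UniFrac (no tree), no compositional differential methods
  (ANCOM/ALDEx2), no meta-regression or publication-bias diagnostics.
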