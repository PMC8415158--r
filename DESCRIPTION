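Package: micrometa
Title: Cross-Study Gut Microbiome Meta-Analysis with Median-Dichotomized Odds Ratios
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for meta-analysis of case/control 16S rRNA gut microbiome
    studies. Reads classic OTU tables with taxonomy and sample metadata,
    performs depth filtering, per-study rarefaction and taxonomic collapse,
    computes alpha diversity (richness, Shannon, Pielou evenness),
    Bray-Curtis ordination and PERMANOVA, and pools per-study
    median-dichotomized odds ratios under fixed- and random-effects
    (DerSimonian-Laird) models with heterogeneity statistics. Includes
    FDR-controlled Wilcoxon differential-abundance summaries, random-forest
    classifiers with forward cross-validated feature selection,
    study-to-study transfer and leave-one-study-out validation, a
    genus-probiotic Spearman correlation network, and a multi-study
    synthetic cohort generator with planted ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    vegan,
    randomForest,
    igraph,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    metafor,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
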