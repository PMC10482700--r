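Package: egrnkit
Title: Enhancer-Driven Gene Regulatory Network Inference from Single-Cell Multiome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers enhancer-driven gene regulatory networks (eRegulons:
    transcription factor to enhancer regions to target genes) from paired or
    computationally paired single-cell chromatin accessibility and gene
    expression matrices. Covers consensus peak construction from scored peak
    calls, per-barcode quality control, fragment counting, collapsed-Gibbs
    latent Dirichlet allocation topic modelling of accessibility with topic
    binarization and dropout imputation, differential accessibility, motif
    cluster scoring and ranking databases, recovery-curve (NES / leading edge)
    and differential (Wilcoxon) motif enrichment, gradient-boosting importance
    networks with GSEA-based eRegulon assembly, AUCell signature scoring,
    regulon specificity scores, triplet ranking, in-silico transcription
    factor knockout simulation, and GRN-velocity differentiation forces along
    pseudotime. A synthetic multiome generator with a planted ground-truth
    network supports verification at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    methods,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    digest,
    xgboost,
    mgcv,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    fgsea,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
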