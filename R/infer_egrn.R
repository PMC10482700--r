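#' End-to-end eRegulon inference from a multiome dataset
#'
#' Runs the canonical workflow on paired matrices: topic modelling of the
#' binarized accessibility and dropout imputation; per-cell-type
#' differentially accessible regions; motif-cluster score and ranking
#' databases over the region sequences; recovery-curve motif enrichment on
#' each DAR set, merged into TF cistromes; gene search spaces; TF-to-gene and
#' region-to-gene gradient-boosting importances; binarized region-gene links;
#' GSEA-based eRegulon assembly; and (optionally) the TF-expression vs
#' region-AUC quality filter.
#'
#' For desk-scale databases (hundreds to a few thousand regions rather than
#' the genome-wide 10^5-10^6) the recovery-curve windows are widened so that
#' the AUC window and the RankAtMax search cover at least a regulon-sized
#' stretch of the ranking: `auc_fraction = 0.05` and
#' `rank_at_max_fraction = 0.25` by default here, against the genome-scale
#' defaults of 0.005 and 0.02 in [cistarget()].
#'
#' @param counts_atac Cells x regions count matrix.
#' @param counts_rna Cells x genes count matrix (same cells).
#' @param labels Cell-type labels (named vector or tibble).
#' @param sequences Named region sequences.
#' @param motif_clusters Named list of `MotifCluster` objects.
#' @param motif_annotation Tibble (`cluster_id`, `tf`, `evidence`).
#' @param annotation Gene annotation tibble.
#' @param tf_list TFs to model (default: annotated TFs present in the
#'   expression matrix).
#' @param n_topics Topics for the LDA (default: number of cell types).
#' @param seed Global seed; stage seeds are derived from it.
#' @param auc_fraction,rank_at_max_fraction Recovery-window fractions for
#'   [cistarget()] (desk-scale defaults, see above).
#' @param nes_threshold NES cut-off (default 3).
#' @param quality Apply [quality_filter()] (default TRUE).
#' @param n_iter Gibbs sweeps for the topic model (default 150).
#' @return List with `eregulons`, `cistromes`, `enrichment`, `dars`,
#'   `topic_model`, `imputed`, `search_space`, `tf_gene`, `region_gene`,
#'   `binarized`, `rankingdb`, `region_auc`.
#' @export
infer_egrn <- function(counts_atac, counts_rna, labels, sequences,
                       motif_clusters, motif_annotation, annotation,
                       tf_list = NULL, n_topics = NULL, seed = 1,
                       auc_fraction = 0.05, rank_at_max_fraction = 0.25,
                       nes_threshold = 3.0, quality = TRUE, n_iter = 150) {
  lab <- labels_to_vector(labels, rownames(counts_atac))
  if (is.null(n_topics)) n_topics <- length(unique(lab))
  if (is.null(tf_list)) {
    tf_list <- intersect(unique(motif_annotation$tf), colnames(counts_rna))
  }

  model <- fit_lda_gibbs(counts_atac, K = max(n_topics, 2), n_iter = n_iter,
                         seed = derive_seed(seed, 1))
  imputed <- impute_accessibility(model)

  dars <- find_dars(imputed, lab)
  dar_sets <- lapply(split(dars[dars$passes, ], dars$group[dars$passes]),
                     function(d) unique(d$region))
  dar_sets <- dar_sets[lengths(dar_sets) > 0]
  if (length(dar_sets) == 0) stop("no differentially accessible regions")

  scoredb <- build_score_db(motif_clusters, sequences)
  rankingdb <- build_ranking_db(scoredb, seed = derive_seed(seed, 2))
  enrichment <- purrr::map_dfr(names(dar_sets), function(g) {
    res <- cistarget(dar_sets[[g]], rankingdb, auc_fraction = auc_fraction,
                     nes_threshold = nes_threshold,
                     rank_at_max_fraction = rank_at_max_fraction)
    if (nrow(res)) res$contrast <- g
    res
  })
  cistromes <- merge_cistromes(enrichment, motif_annotation)
  if (nrow(cistromes) == 0) stop("no TF cistromes recovered")

  space <- define_search_space(annotation, parse_region_names(
    colnames(counts_atac)))
  mc <- make_metacells(as.matrix(counts_rna), imputed, lab,
                       mode = "identity")
  tf_gene <- tf_gene_importance(mc$expression, tf_list,
                                seed = derive_seed(seed, 3))
  region_gene <- region_gene_importance(mc$accessibility, mc$expression,
                                        space,
                                        seed = derive_seed(seed, 4))
  binarized <- binarize_region_gene(region_gene)
  eregulons <- build_eregulons(cistromes, binarized, tf_gene)

  region_auc <- NULL
  if (nrow(eregulons) > 0) {
    sigs <- eregulon_signatures(eregulons, "region")
    region_auc <- aucell(imputed, sigs, seed = derive_seed(seed, 5))
    if (quality) {
      eregulons <- quality_filter(eregulons, as.matrix(counts_rna),
                                  region_auc, lab,
                                  seed = derive_seed(seed, 6))
    }
  }
  list(eregulons = eregulons, cistromes = cistromes,
       enrichment = enrichment, dars = dars, topic_model = model,
       imputed = imputed, search_space = space, tf_gene = tf_gene,
       region_gene = region_gene, binarized = binarized,
       rankingdb = rankingdb, region_auc = region_auc)
}
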