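#' Weighted GSEA running sum
#'
#' Standard weighted Kolmogorov-Smirnov running sum (weight exponent 1):
#' genes are walked in ranking order, hits add their weight (normalized by
#' the total hit weight) and misses subtract `1 / (N - n_hits)`. The
#' enrichment score is the maximum positive deviation; the leading edge
#' contains the hits at or before that maximum.
#'
#' @param ranked_genes Character vector of all genes, best first.
#' @param weights Nonnegative weights aligned to `ranked_genes` (e.g.
#'   TF-to-gene importances).
#' @param gene_set Candidate gene set.
#' @return List with `es`, `leading_edge` (character), `rank_at_max`.
#' @export
gsea_running_sum <- function(ranked_genes, weights, gene_set) {
  stopifnot(length(ranked_genes) == length(weights))
  hit <- ranked_genes %in% gene_set
  n <- length(ranked_genes)
  n_hit <- sum(hit)
  if (n_hit == 0 || n_hit == n) {
    return(list(es = 0, leading_edge = character(), rank_at_max = 0L))
  }
  w <- abs(weights)
  denom_hit <- sum(w[hit])
  if (denom_hit == 0) {
    w[hit] <- 1
    denom_hit <- n_hit
  }
  step <- ifelse(hit, w / denom_hit, -1 / (n - n_hit))
  running <- cumsum(step)
  es <- max(running)
  if (es <= 0) {
    return(list(es = max(running), leading_edge = character(),
                rank_at_max = 0L))
  }
  at <- which.max(running)
  list(es = es,
       leading_edge = ranked_genes[seq_len(at)][hit[seq_len(at)]],
       rank_at_max = as.integer(at))
}

#' Assemble eRegulons from cistromes and binarized links
#'
#' For each TF with a cistrome and each TF-to-gene sign stratum (`+`
#' activating, `-` repressing; region-to-gene links are positive-sign only),
#' the candidate target genes are those connected to cistrome regions through
#' the binarized region-to-gene links. All genes are ranked by their
#' TF-to-gene importance and a weighted GSEA running sum is computed per
#' binarization variant; the eRegulon's target genes are the union of the
#' leading edges across variants (with per-gene variant provenance).
#' eRegulons with fewer than `min_genes` target genes are discarded, and
#' repressor (`-`) eRegulons are flagged experimental via `tf_sign`.
#'
#' @param cistromes Tibble from [merge_cistromes()].
#' @param binarized_links Tibble from [binarize_region_gene()].
#' @param tf_gene_table Tibble from [tf_gene_importance()].
#' @param min_genes Minimum target genes per eRegulon (default 10).
#' @return An `eregulon_df`: tibble with one row per (TF, region, gene) edge
#'   and columns `tf`, `tf_sign`, `gene`, `region`, `tf2g_importance`,
#'   `rho_tf2g`, `r2g_importance`, `rho_r2g`, `variants`, `gsea_es`.
#' @export
build_eregulons <- function(cistromes, binarized_links, tf_gene_table,
                            min_genes = 10) {
  out <- purrr::map_dfr(seq_len(nrow(cistromes)), function(i) {
    tf <- cistromes$tf[i]
    regions <- cistromes$regions[[i]]
    links <- binarized_links[binarized_links$region %in% regions, ]
    if (nrow(links) == 0) return(NULL)
    tg <- tf_gene_table[tf_gene_table$tf == tf &
                          tf_gene_table$target != tf, ]
    if (nrow(tg) == 0) return(NULL)
    ord <- order(-tg$importance, tg$target)
    ranked <- tg$target[ord]
    wts <- tg$importance[ord]
    purrr::map_dfr(c("+", "-"), function(s) {
      stratum_genes <- tg$target[tg$sign == s]
      candidates <- intersect(unique(links$target), stratum_genes)
      if (length(candidates) == 0) return(NULL)
      per_variant <- lapply(split(links, links$variant), function(lv) {
        cand_v <- intersect(unique(lv$target), stratum_genes)
        if (length(cand_v) == 0) return(NULL)
        g <- gsea_running_sum(ranked, wts, cand_v)
        if (length(g$leading_edge) == 0) return(NULL)
        list(genes = g$leading_edge, es = g$es)
      })
      per_variant <- per_variant[!vapply(per_variant, is.null, TRUE)]
      if (length(per_variant) == 0) return(NULL)
      gene_variants <- purrr::map_dfr(names(per_variant), function(v) {
        tibble(gene = per_variant[[v]]$genes, variant = v)
      })
      target_genes <- unique(gene_variants$gene)
      if (length(target_genes) < min_genes) return(NULL)
      prov <- dplyr::summarise(dplyr::group_by(gene_variants, .data$gene),
                               variants = paste(sort(unique(.data$variant)),
                                                collapse = ","),
                               .groups = "drop")
      edges <- dplyr::distinct(
        links[links$target %in% target_genes,
              c("region", "target", "importance", "rho")])
      edges <- dplyr::rename(edges, gene = "target",
                             r2g_importance = "importance",
                             rho_r2g = "rho")
      edges <- dplyr::summarise(
        dplyr::group_by(edges, .data$region, .data$gene),
        r2g_importance = max(.data$r2g_importance),
        rho_r2g = .data$rho_r2g[1], .groups = "drop")
      edges <- dplyr::inner_join(edges, prov, by = "gene")
      edges <- dplyr::inner_join(
        edges,
        dplyr::select(tg, gene = "target", tf2g_importance = "importance",
                      rho_tf2g = "rho"),
        by = "gene")
      es <- max(vapply(per_variant, function(p) p$es, 0))
      tibble(tf = tf, tf_sign = s, gene = edges$gene, region = edges$region,
             tf2g_importance = edges$tf2g_importance,
             rho_tf2g = edges$rho_tf2g,
             r2g_importance = edges$r2g_importance,
             rho_r2g = edges$rho_r2g,
             variants = edges$variants, gsea_es = es)
    })
  })
  class(out) <- c("eregulon_df", class(out))
  validate_eregulons(out, cistromes, min_genes)
  out
}

# Invariants asserted on every run: >= min_genes target genes per eRegulon
# and cistrome containment of every target region.
validate_eregulons <- function(eregulons, cistromes = NULL, min_genes = 10) {
  if (nrow(eregulons) == 0) return(invisible(TRUE))
  sizes <- dplyr::summarise(
    dplyr::group_by(eregulons, .data$tf, .data$tf_sign),
    n_genes = dplyr::n_distinct(.data$gene), .groups = "drop")
  stopifnot(all(sizes$n_genes >= min_genes))
  if (!is.null(cistromes)) {
    for (tf in unique(eregulons$tf)) {
      regs <- unique(eregulons$region[eregulons$tf == tf])
      allowed <- unlist(cistromes$regions[cistromes$tf == tf])
      stopifnot(all(regs %in% allowed))
    }
  }
  invisible(TRUE)
}

#' Summarize an eRegulon edge table per regulon
#'
#' @param eregulons An `eregulon_df`.
#' @return Tibble with one row per (tf, tf_sign): gene and region counts and
#'   the GSEA enrichment score.
#' @export
summarize_eregulons <- function(eregulons) {
  dplyr::summarise(
    dplyr::group_by(eregulons, .data$tf, .data$tf_sign),
    n_genes = dplyr::n_distinct(.data$gene),
    n_regions = dplyr::n_distinct(.data$region),
    gsea_es = .data$gsea_es[1],
    .groups = "drop")
}

#' Extract per-regulon signatures from an eRegulon table
#'
#' @param eregulons An `eregulon_df`.
#' @param what `"gene"` or `"region"` signatures.
#' @return Named list of feature sets, names `TF_sign` (e.g. `"TF1_+"`).
#' @export
eregulon_signatures <- function(eregulons, what = c("gene", "region")) {
  what <- match.arg(what)
  key <- paste0(eregulons$tf, "_", eregulons$tf_sign)
  split(eregulons[[what]], key) |> lapply(unique)
}

#' TF-expression vs region-AUC quality filter
#'
#' Per eRegulon, cells are semi-pseudobulked (`n_pseudobulk` metacells per
#' cell type, `k` cells each) and the Pearson correlation between pseudobulk
#' TF expression and the eRegulon's target-region AUCell score is computed.
#' Activator (`+`) eRegulons are kept when the correlation exceeds
#' `pos_rho_min`; repressor (`-`) eRegulons when it is below `neg_rho_max`.
#'
#' @param eregulons An `eregulon_df`.
#' @param expression Cells x genes matrix.
#' @param region_auc Cells x signatures AUCell matrix on region signatures
#'   (columns named `TF_sign`).
#' @param labels Cell-type labels (named vector or tibble).
#' @param pos_rho_min,neg_rho_max Keep thresholds (defaults 0.7, -0.8).
#' @param n_pseudobulk Metacells per cell type (default 100).
#' @param k Cells per metacell (default 5).
#' @param seed Integer seed.
#' @return The filtered `eregulon_df`, with a `quality_rho` column.
#' @export
quality_filter <- function(eregulons, expression, region_auc, labels,
                           pos_rho_min = 0.7, neg_rho_max = -0.8,
                           n_pseudobulk = 100, k = 5, seed = 1) {
  labels <- labels_to_vector(labels, rownames(expression))
  types <- unique(labels)
  set.seed(seed)
  groups <- list()
  for (ty in types) {
    idx <- which(labels == ty)
    if (length(idx) < k) {
      warning("cell type with fewer than k cells skipped in pseudobulking: ",
              ty)
      next
    }
    groups[[ty]] <- replicate(n_pseudobulk, sample(idx, k), simplify = FALSE)
  }
  draws <- unlist(groups, recursive = FALSE)
  regs <- dplyr::distinct(as_tibble(eregulons[, c("tf", "tf_sign")]))
  regs$key <- paste0(regs$tf, "_", regs$tf_sign)
  rho <- vapply(seq_len(nrow(regs)), function(i) {
    key <- regs$key[i]
    if (!key %in% colnames(region_auc)) return(NA_real_)
    tf_e <- vapply(draws, function(d) mean(expression[d, regs$tf[i]]), 0)
    auc_e <- vapply(draws, function(d) mean(region_auc[d, key]), 0)
    suppressWarnings(cor(tf_e, auc_e))
  }, 0)
  regs$quality_rho <- rho
  keep <- regs[!is.na(regs$quality_rho) &
                 ((regs$tf_sign == "+" & regs$quality_rho > pos_rho_min) |
                    (regs$tf_sign == "-" & regs$quality_rho < neg_rho_max)), ]
  out <- dplyr::inner_join(eregulons, keep[, c("tf", "tf_sign",
                                               "quality_rho")],
                           by = c("tf", "tf_sign"))
  class(out) <- c("eregulon_df", class(out))
  out
}
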