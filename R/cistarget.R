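#' Recovery-curve motif enrichment (cisTarget)
#'
#' For each motif cluster, the recovery curve `rcc(i)` counts how many
#' members of `region_set` appear within the top `i` positions of the
#' cluster's region ranking. The AUC is the area under `rcc` over the top
#' `auc_fraction` of the ranking, normalized by the maximum achievable area
#' at that cut-off (so AUC is in `[0, 1]`), and standardized across clusters
#' into `NES = (AUC - mean(AUC)) / sd(AUC)`. Clusters with
#' `NES > nes_threshold` are reported. The leading-edge cistrome contains the
#' region-set members ranked at or below `RankAtMax`, the position maximizing
#' `rcc_motif(i) - (mean(rcc_all)(i) + 2 sd(rcc_all)(i))` over a window of
#' `max(auc_fraction, rank_at_max_fraction)` of the ranking (positionwise
#' mean/sd across clusters; the wider window stabilizes the maximum on small
#' databases).
#'
#' @param region_set Character vector of region names (subset of the
#'   database regions).
#' @param rankingdb A `RankingDB` from [build_ranking_db()].
#' @param auc_fraction Top fraction of the ranking for the AUC (default
#'   0.005).
#' @param nes_threshold Keep clusters with NES above this (default 3).
#' @param rank_at_max_fraction Window fraction for the RankAtMax search
#'   (default 0.02).
#' @return Tibble with columns `motif_cluster`, `auc`, `nes`, `rank_at_max`,
#'   `n_cistrome`, `cistrome` (list-column of leading-edge regions),
#'   `method`; one row per cluster passing the NES threshold, sorted by
#'   decreasing NES. The full per-cluster AUC/NES table is attached as
#'   attribute `all_clusters`.
#' @export
cistarget <- function(region_set, rankingdb, auc_fraction = 0.005,
                      nes_threshold = 3.0, rank_at_max_fraction = 0.02) {
  ranks <- rankingdb$ranks
  if (length(region_set) == 0) stop("empty region set")
  missing <- setdiff(region_set, rownames(ranks))
  if (length(missing)) {
    stop("region(s) not in ranking database: ",
         paste(head(missing, 3), collapse = ", "))
  }
  n <- nrow(ranks)
  m <- length(region_set)
  n_top <- ceiling(auc_fraction * n)
  window <- max(n_top, ceiling(rank_at_max_fraction * n))

  set_ranks <- ranks[region_set, , drop = FALSE]
  rcc <- apply(set_ranks, 2, function(r) {
    cumsum(tabulate(r[r <= window], nbins = window))
  })
  if (is.null(dim(rcc))) rcc <- matrix(rcc, nrow = window)
  max_area <- sum(pmin(seq_len(n_top), m))
  auc <- colSums(rcc[seq_len(n_top), , drop = FALSE]) / max_area
  nes <- (auc - mean(auc)) / sd(auc)

  mu <- rowMeans(rcc)
  sdv <- apply(rcc, 1, sd)
  ram <- apply(rcc, 2, function(r) which.max(r - (mu + 2 * sdv)))

  all_tbl <- tibble(
    motif_cluster = colnames(ranks),
    auc = as.numeric(auc),
    nes = as.numeric(nes),
    rank_at_max = as.integer(ram)
  )
  res <- all_tbl[all_tbl$nes > nes_threshold, ]
  res$cistrome <- purrr::map2(res$motif_cluster, res$rank_at_max, function(cl, rm) {
    region_set[set_ranks[, cl] <= rm]
  })
  res$n_cistrome <- lengths(res$cistrome)
  res$method <- "cistarget"
  res <- res[order(-res$nes), ]
  attr(res, "all_clusters") <- all_tbl
  res
}

#' Differential motif enrichment (DEM)
#'
#' Per contrast and motif cluster, a two-sided Wilcoxon rank-sum test
#' compares the CRM score distribution of the foreground region set against
#' the background set; `logFC = log2((mean_fg + eps) / (mean_bg + eps))`.
#' P-values are Bonferroni-adjusted across the clusters tested within a
#' contrast, and clusters with adjusted p < `adj_p_max` and
#' `logFC > logfc_min` are kept. The cistrome of a kept cluster contains the
#' foreground regions with CRM score above `crm_min`.
#'
#' @param foreground Named list of region-name vectors (one per contrast), or
#'   a single character vector.
#' @param background Matching list/vector of background regions, or `NULL`
#'   for one-versus-all (background = union of the other foreground sets).
#' @param scoredb Regions x clusters score matrix.
#' @param adj_p_max,logfc_min Keep thresholds (defaults 0.05, 0.5).
#' @param crm_min CRM score cut-off for cistrome membership (default 3).
#' @param epsilon Guard in the logFC (default 1e-9).
#' @return Tibble with `contrast`, `motif_cluster`, `log_fc`, `p_value`,
#'   `adj_p_value`, `cistrome` (list-column), `n_cistrome`, `method`, one row
#'   per kept (contrast, cluster).
#' @export
dem <- function(foreground, background = NULL, scoredb,
                adj_p_max = 0.05, logfc_min = 0.5, crm_min = 3.0,
                epsilon = 1e-9) {
  if (!is.list(foreground)) foreground <- list(set = foreground)
  if (is.null(background)) {
    if (length(foreground) < 2) {
      stop("one-versus-all background needs >= 2 foreground sets")
    }
    background <- lapply(seq_along(foreground), function(i) {
      setdiff(unique(unlist(foreground[-i])), foreground[[i]])
    })
    names(background) <- names(foreground)
  } else if (!is.list(background)) {
    background <- rep(list(background), length(foreground))
    names(background) <- names(foreground)
  }
  purrr::map_dfr(names(foreground), function(cn) {
    fg <- foreground[[cn]]; bg <- background[[cn]]
    if (length(fg) == 0 || length(bg) == 0) {
      stop("empty foreground or background in contrast ", cn)
    }
    if (length(intersect(fg, bg))) {
      stop("foreground and background overlap in contrast ", cn)
    }
    miss <- setdiff(c(fg, bg), rownames(scoredb))
    if (length(miss)) stop("region(s) not in score database: ",
                           paste(head(miss, 3), collapse = ", "))
    stats_tbl <- purrr::map_dfr(colnames(scoredb), function(cl) {
      x <- scoredb[fg, cl]; y <- scoredb[bg, cl]
      p <- if (all(c(x, y) == c(x, y)[1])) 1 else
        suppressWarnings(wilcox.test(x, y)$p.value)
      tibble(
        contrast = cn, motif_cluster = cl,
        log_fc = log2((mean(x) + epsilon) / (mean(y) + epsilon)),
        p_value = p
      )
    })
    stats_tbl$adj_p_value <- pmin(stats_tbl$p_value * nrow(stats_tbl), 1)
    keep <- stats_tbl[stats_tbl$adj_p_value < adj_p_max &
                        stats_tbl$log_fc > logfc_min, ]
    keep$cistrome <- purrr::map(keep$motif_cluster, function(cl) {
      fg[scoredb[fg, cl] > crm_min]
    })
    keep$n_cistrome <- lengths(keep$cistrome)
    keep$method <- "dem"
    keep
  })
}

#' Merge enriched motif clusters into TF cistromes
#'
#' Per TF, the cistrome is the union of the cistromes of all enriched
#' clusters annotated to that TF; the evidence class is the strongest
#' present (`direct` > `orthology`). Clusters annotated to no TF contribute
#' nothing.
#'
#' @param results Enrichment tibble(s) from [cistarget()] and/or [dem()]
#'   (needs columns `motif_cluster`, `cistrome`).
#' @param annotations Tibble with `cluster_id`, `tf`, `evidence`.
#' @return Tibble with `tf`, `evidence`, `regions` (list-column),
#'   `n_regions`, `clusters` (list-column); TFs with empty cistromes are
#'   dropped.
#' @export
merge_cistromes <- function(results, annotations) {
  if (is.data.frame(results)) results <- list(results)
  res <- dplyr::bind_rows(lapply(results, function(r) {
    r[, c("motif_cluster", "cistrome")]
  }))
  ann <- dplyr::distinct(annotations, .data$cluster_id, .data$tf,
                         .data$evidence)
  ann <- ann[!is.na(ann$tf) & nzchar(ann$tf), ]
  joined <- dplyr::inner_join(res, ann,
                              by = c(motif_cluster = "cluster_id"),
                              relationship = "many-to-many")
  if (nrow(joined) == 0) {
    return(tibble(tf = character(), evidence = character(),
                  regions = list(), n_regions = integer(), clusters = list()))
  }
  out <- dplyr::summarise(
    dplyr::group_by(joined, .data$tf),
    evidence = if (any(.data$evidence == "direct")) "direct" else "orthology",
    regions = list(sort(unique(unlist(.data$cistrome)))),
    clusters = list(sort(unique(.data$motif_cluster))),
    .groups = "drop"
  )
  out$n_regions <- lengths(out$regions)
  out[out$n_regions > 0, c("tf", "evidence", "regions", "n_regions",
                           "clusters")]
}

#' Drop promoter regions from a region set
#'
#' Promoters are TSS +/- `flank` bp. Useful for running motif enrichment
#' excluding promoters.
#'
#' @param regions Character vector of canonical region names.
#' @param annotation Gene annotation tibble (`chrom`, `tss`).
#' @param flank Promoter half-width in bp (default 500).
#' @return The region names not overlapping any promoter.
#' @export
exclude_promoters <- function(regions, annotation, flank = 500) {
  reg <- parse_region_names(regions)
  prom <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(pmax(annotation$tss - flank, 0L) + 1L,
                     annotation$tss + flank + 1L)
  )
  hits <- GenomicRanges::findOverlaps(regions_to_granges(reg), prom)
  drop <- unique(S4Vectors::queryHits(hits))
  if (length(drop)) regions[-drop] else regions
}
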