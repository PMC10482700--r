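#' Order-statistics probability for sorted normalized ranks
#'
#' For `k` i.i.d. uniforms, the probability that the `i`-th order statistic
#' is at most `s[i]` for every `i` (s ascending). Used to aggregate the three
#' component ranks of a TF-region-gene triplet; smaller is better. Closed
#' form for `k = 3`, recursive integration otherwise.
#'
#' @param s Numeric vector of sorted (ascending) values in `[0, 1]`.
#' @return The joint order-statistics probability.
#' @export
order_statistic_q <- function(s) {
  s <- pmin(pmax(sort(s), 0), 1)
  k <- length(s)
  # P = k! * h_1(0) with h_k(u) = s_k - u and
  # h_j(u) = integral_u^{s_j} h_{j+1}(t) dt, computed on polynomial
  # coefficients (constant term first).
  h <- c(s[k], -1)
  if (k > 1) {
    for (j in (k - 1):1) {
      anti <- c(0, h / seq_along(h))
      at_sj <- sum(anti * s[j]^(seq_along(anti) - 1))
      h <- c(at_sj, -anti[-1])
    }
  }
  factorial(k) * h[1]
}

#' Rank TF-region-gene triplets
#'
#' Each triplet from the eRegulon table receives three component ranks: its
#' TF-to-gene importance rank, its region-to-gene importance rank (both
#' descending, so rank 1 is the strongest), and the rank of the region's best
#' position across all motif clusters annotated to the TF in the ranking
#' database. The three normalized ranks are aggregated with the
#' order-statistics probability ([order_statistic_q()]); `final_rank` orders
#' triplets by ascending aggregate (1 = best). Triplets of TFs with no
#' annotated clusters are excluded with a message.
#'
#' @param eregulons An `eregulon_df` (needs `tf`, `region`, `gene`,
#'   `tf2g_importance`, `r2g_importance`).
#' @param rankingdb A `RankingDB`.
#' @param annotations Tibble with `cluster_id`, `tf`.
#' @return Tibble with the triplet, the three component ranks,
#'   `aggregate_score` and `final_rank` (a permutation of `1..n`).
#' @export
triplet_ranking <- function(eregulons, rankingdb, annotations) {
  tri <- dplyr::distinct(as_tibble(
    eregulons[, c("tf", "region", "gene", "tf2g_importance",
                  "r2g_importance")]))
  ann <- split(annotations$cluster_id, annotations$tf)
  has_ann <- tri$tf %in% names(ann)
  if (any(!has_ann)) {
    message(sum(!has_ann),
            " triplet(s) excluded: TF with no annotated motif clusters")
    tri <- tri[has_ann, ]
  }
  if (nrow(tri) == 0) stop("no triplets to rank")
  miss <- setdiff(tri$region, rownames(rankingdb$ranks))
  if (length(miss)) stop("region(s) not in ranking database: ",
                         paste(head(miss, 3), collapse = ", "))
  tri$best_motif_rank <- vapply(seq_len(nrow(tri)), function(i) {
    cls <- intersect(ann[[tri$tf[i]]], colnames(rankingdb$ranks))
    if (length(cls) == 0) return(NA_real_)
    min(rankingdb$ranks[tri$region[i], cls])
  }, 0)
  n <- nrow(tri)
  tri$rank_tf_gene <- rank(-tri$tf2g_importance, ties.method = "average")
  tri$rank_region_gene <- rank(-tri$r2g_importance, ties.method = "average")
  tri$rank_tf_region <- rank(tri$best_motif_rank, ties.method = "average")
  tri$aggregate_score <- vapply(seq_len(n), function(i) {
    order_statistic_q(c(tri$rank_tf_gene[i], tri$rank_region_gene[i],
                        tri$rank_tf_region[i]) / n)
  }, 0)
  tri$final_rank <- as.integer(rank(tri$aggregate_score,
                                    ties.method = "first"))
  tri[order(tri$final_rank), ]
}
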