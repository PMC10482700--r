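#' Iterative consensus peak filtering
#'
#' Each peak's summit is extended by `half_width` on each side (clipped at 0)
#' and, among overlapping extended peaks, only the most significant one is
#' retained; the filtering is repeated until no retained peaks overlap. Equal
#' scores are broken deterministically in favour of the leftmost
#' (chrom, start) peak.
#'
#' @param peaks Tibble with columns `chrom`, `summit`, `score` (and any
#'   others, which are carried through).
#' @param half_width Extension in bp on each side of the summit (default 250).
#' @return A tibble of the retained peaks with `start`, `end` recomputed as
#'   `summit +/- half_width` (start clipped at 0) and a canonical `region`
#'   name. Width is `2 * half_width` except where clipped at the chromosome
#'   start.
#' @export
iterative_consensus_peaks <- function(peaks, half_width = 250) {
  stopifnot(half_width > 0)
  if (nrow(peaks) == 0) {
    return(dplyr::mutate(peaks, start = integer(), end = integer(),
                         region = character()))
  }
  if (any(!is.finite(peaks$score))) stop("peaks must carry finite scores")
  ext <- dplyr::mutate(
    peaks,
    start = pmax(as.integer(.data$summit) - as.integer(half_width), 0L),
    end = as.integer(.data$summit) + as.integer(half_width)
  )
  # Greedy selection by descending score (ties: leftmost first) is the fixed
  # point of repeatedly removing any peak overlapped by a higher-priority one.
  ord <- order(-ext$score, ext$chrom, ext$start)
  ext <- ext[ord, ]
  keep <- logical(nrow(ext))
  for (i in seq_len(nrow(ext))) {
    kept <- which(keep)
    same <- kept[ext$chrom[kept] == ext$chrom[i]]
    if (!length(same) ||
        all(ext$end[same] <= ext$start[i] | ext$start[same] >= ext$end[i])) {
      keep[i] <- TRUE
    }
  }
  out <- ext[keep, ]
  out <- out[order(out$chrom, out$start), ]
  out$region <- region_name(out$chrom, out$start, out$end)
  as_tibble(out)
}

#' Two-round consensus peak construction across cell types
#'
#' Round one applies [iterative_consensus_peaks()] within each group (cell
#' type); peak scores are then normalized within each group (score divided by
#' the group's score total, times 1e6, a CPM-like scale-free transform) and a
#' second round runs on the union across groups.
#'
#' @param peaks Tibble with columns `chrom`, `summit`, `score`, `group`.
#' @param half_width Summit extension in bp (default 250).
#' @return Tibble of consensus regions as in [iterative_consensus_peaks()].
#' @export
two_round_consensus <- function(peaks, half_width = 250) {
  groups <- unique(peaks$group)
  if (length(groups) < 1) stop("need at least one group")
  round1 <- purrr::map(groups, function(g) {
    pk <- peaks[peaks$group == g, ]
    if (nrow(pk) == 0) {
      warning("group with no peaks skipped: ", g)
      return(NULL)
    }
    kept <- iterative_consensus_peaks(pk, half_width)
    kept$score <- kept$score / sum(kept$score) * 1e6
    kept
  })
  pooled <- dplyr::bind_rows(round1)
  if (nrow(pooled) == 0) stop("no peaks in any group")
  iterative_consensus_peaks(pooled, half_width)
}
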