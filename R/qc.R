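#' Per-barcode quality-control statistics
#'
#' Computes, per cell barcode: the number of unique fragments (each record
#' counted once, regardless of its duplicate-count field), the fraction of
#' fragments in peaks (FRiP), and a TSS enrichment score. TSS enrichment is
#' the ENCODE-style estimator: mean per-bp fragment coverage in TSS +/- 50 bp
#' windows divided by mean per-bp coverage in the distal flanks
#' (1,900-2,000 bp away on both sides), with the flank coverage floored at
#' 0.1 to avoid division by zero.
#'
#' @param fragments Fragments tibble (see [read_fragments()]).
#' @param regions Consensus regions: tibble with `chrom`, `start`, `end`, or
#'   a character vector of canonical names.
#' @param annotation Gene annotation tibble (needs `chrom`, `tss`).
#' @return Tibble with columns `barcode`, `unique_fragments`, `frip`,
#'   `tss_enrichment`; barcodes without fragments are absent.
#' @export
compute_barcode_qc <- function(fragments, regions, annotation) {
  if (nrow(annotation) == 0) stop("nonempty annotation required")
  if (nrow(fragments) == 0) {
    return(tibble(barcode = character(), unique_fragments = integer(),
                  frip = double(), tss_enrichment = double()))
  }
  frag <- dplyr::distinct(fragments, .data$chrom, .data$start, .data$end,
                          .data$barcode)
  fr_gr <- fragments_to_granges(frag)

  totals <- dplyr::count(frag, .data$barcode, name = "unique_fragments")

  if (is.character(regions)) regions <- parse_region_names(regions)
  in_peak <- rep(FALSE, nrow(frag))
  if (nrow(regions) > 0) {
    hits <- GenomicRanges::findOverlaps(fr_gr, regions_to_granges(regions))
    in_peak[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  frip_tbl <- dplyr::summarise(
    dplyr::group_by(tibble(barcode = frag$barcode, in_peak = in_peak),
                    .data$barcode),
    frip = mean(.data$in_peak), .groups = "drop"
  )

  cov_per_bp <- function(windows) {
    total_bp <- sum(GenomicRanges::width(windows))
    hits <- GenomicRanges::findOverlaps(fr_gr, windows)
    if (length(hits) == 0) {
      return(setNames(numeric(length(totals$barcode)), totals$barcode))
    }
    ov <- GenomicRanges::pintersect(
      fr_gr[S4Vectors::queryHits(hits)],
      windows[S4Vectors::subjectHits(hits)]
    )
    bp <- tapply(GenomicRanges::width(ov),
                 frag$barcode[S4Vectors::queryHits(hits)], sum)
    out <- setNames(numeric(nrow(totals)), totals$barcode)
    out[names(bp)] <- bp
    out / total_bp
  }

  tss1 <- pmax(annotation$tss - 50L, 0L)
  tss_win <- GenomicRanges::reduce(GenomicRanges::GRanges(
    annotation$chrom, IRanges::IRanges(tss1 + 1L, annotation$tss + 50L + 1L)
  ))
  fl_left <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(pmax(annotation$tss - 2000L, 0L) + 1L,
                     pmax(annotation$tss - 1900L, 1L))
  )
  fl_right <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(annotation$tss + 1900L + 1L, annotation$tss + 2000L + 1L)
  )
  flank_win <- GenomicRanges::reduce(c(fl_left, fl_right))

  tss_cov <- cov_per_bp(tss_win)
  flank_cov <- pmax(cov_per_bp(flank_win), 0.1)

  out <- dplyr::left_join(totals, frip_tbl, by = "barcode")
  out$tss_enrichment <- as.numeric(tss_cov[out$barcode] /
                                     flank_cov[out$barcode])
  out
}
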