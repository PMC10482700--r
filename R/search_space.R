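#' Define per-gene search spaces
#'
#' A gene's search space is the window `[start - upstream_max,
#' end + downstream_max]`, clipped on each side at the promoter of the
#' nearest neighboring gene (TSS +/- `promoter_pad`) when that promoter is
#' closer, but never clipped below `min_extension` from the gene body.
#' Regions are assigned to every gene whose window they overlap; the signed
#' distance is from the region midpoint to the TSS, negative upstream
#' relative to the gene's strand.
#'
#' @param annotation Gene annotation tibble (`gene`, `chrom`, `strand`,
#'   `tss`, `start`, `end`).
#' @param regions Tibble with `chrom`, `start`, `end` or canonical names.
#' @param upstream_max,downstream_max Window half-extents in bp (default
#'   150000).
#' @param min_extension Minimal extension beyond the gene body in bp
#'   (default 1000).
#' @param promoter_pad Promoter half-width around the neighbor TSS (default
#'   10).
#' @return Tibble with columns `gene`, `region`, `distance`.
#' @export
define_search_space <- function(annotation, regions,
                                upstream_max = 150000,
                                downstream_max = 150000,
                                min_extension = 1000,
                                promoter_pad = 10) {
  if (is.character(regions)) regions <- parse_region_names(regions)
  if (!"region" %in% names(regions)) {
    regions$region <- region_name(regions$chrom, regions$start, regions$end)
  }
  ann <- annotation[order(annotation$chrom, annotation$tss), ]
  windows <- purrr::map_dfr(seq_len(nrow(ann)), function(i) {
    g <- ann[i, ]
    same <- ann[ann$chrom == g$chrom & ann$gene != g$gene, ]
    left <- g$start - upstream_max
    lefts <- same$tss[same$tss < g$start]
    if (length(lefts)) {
      left <- max(left, max(lefts) - promoter_pad)
    }
    left <- min(left, g$start - min_extension)
    left <- max(left, 0)
    right <- g$end + downstream_max
    rights <- same$tss[same$tss > g$end]
    if (length(rights)) {
      right <- min(right, min(rights) + promoter_pad)
    }
    right <- max(right, g$end + min_extension)
    tibble(gene = g$gene, chrom = g$chrom, win_start = left,
           win_end = right, tss = g$tss, strand = g$strand)
  })
  known <- regions$chrom %in% unique(ann$chrom)
  if (any(!known)) {
    message(sum(!known),
            " region(s) on chromosomes absent from the annotation left unassigned")
    regions <- regions[known, , drop = FALSE]
  }
  if (nrow(regions) == 0) {
    return(tibble(gene = character(), region = character(),
                  distance = double()))
  }
  win_gr <- GenomicRanges::GRanges(
    windows$chrom,
    IRanges::IRanges(windows$win_start + 1L, windows$win_end))
  hits <- GenomicRanges::findOverlaps(regions_to_granges(regions), win_gr)
  ri <- S4Vectors::queryHits(hits); gi <- S4Vectors::subjectHits(hits)
  mid <- (regions$start[ri] + regions$end[ri]) / 2
  dist <- (mid - windows$tss[gi]) * ifelse(windows$strand[gi] == "-", -1, 1)
  tibble(gene = windows$gene[gi], region = regions$region[ri],
         distance = dist)
}
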