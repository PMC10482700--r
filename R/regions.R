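#' Canonical region names
#'
#' Regions use the BED convention throughout: 0-based, half-open
#' `[start, end)`. The canonical name `"chrom:start-end"` renders the same
#' numbers and round-trips through [parse_region_names()].
#'
#' @param chrom Chromosome names.
#' @param start 0-based inclusive start positions.
#' @param end Exclusive end positions (`end > start`).
#' @return Character vector of canonical names.
#' @export
region_name <- function(chrom, start, end) {
  stopifnot(all(start >= 0), all(end > start))
  sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))
}

#' Parse canonical region names into a tibble
#'
#' @param names Character vector of `"chrom:start-end"` names.
#' @return A tibble with columns `region`, `chrom`, `start`, `end`.
#' @export
parse_region_names <- function(names) {
  m <- regmatches(names, regexec("^(.+):([0-9]+)-([0-9]+)$", names))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("malformed region name(s): ", paste(names[bad][1], collapse = ", "))
  }
  out <- tibble(
    region = names,
    chrom = vapply(m, `[`, "", 2L),
    start = as.integer(vapply(m, `[`, "", 3L)),
    end = as.integer(vapply(m, `[`, "", 4L))
  )
  if (any(out$end <= out$start)) stop("region with end <= start")
  out
}

# Tibble (chrom, start, end) -> GRanges. BED half-open to 1-based closed.
regions_to_granges <- function(x) {
  if (is.character(x)) x <- parse_region_names(x)
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

#' Read a BED3+ file of regions
#'
#' @param path Path to a tab-separated BED file (no header).
#' @return A tibble with columns `chrom`, `start`, `end`, `region` (canonical
#'   name) and, when present, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("BED file needs at least 3 columns: ", path)
  extras <- c("name", "score", "strand")
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) > 3) {
    names(df)[4:min(6, ncol(df))] <- extras[seq_len(min(3, ncol(df) - 3))]
  }
  out <- as_tibble(df[, names(df) %in% c("chrom", "start", "end", extras)])
  out$region <- region_name(out$chrom, out$start, out$end)
  out
}

#' Write regions as BED6
#'
#' Emits BED6 with the canonical region name, score 0 and strand `"."`.
#'
#' @param regions Tibble with `chrom`, `start`, `end` (or a character vector
#'   of canonical names).
#' @param path Output path.
#' @export
write_bed <- function(regions, path) {
  if (is.character(regions)) regions <- parse_region_names(regions)
  df <- data.frame(
    chrom = regions$chrom,
    start = as.integer(regions$start),
    end = as.integer(regions$end),
    name = region_name(regions$chrom, regions$start, regions$end),
    score = 0L,
    strand = "."
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Expects a TSV with header columns `gene`, `chrom`, `strand`, `tss`,
#' `start`, `end` (TSS and gene body in 0-based coordinates).
#'
#' @param path Path to the TSV.
#' @return A tibble, one row per gene.
#' @export
read_gene_annotation <- function(path) {
  df <- as_tibble(read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE))
  need <- c("gene", "chrom", "strand", "tss", "start", "end")
  if (!all(need %in% names(df))) {
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$gene)) stop("duplicate gene symbols in annotation")
  if (any(df$start >= df$end)) stop("gene with start >= end")
  df
}
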