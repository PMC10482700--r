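#' Read an ATAC fragments file
#'
#' Fragments are the standard 5-column TSV (chrom, start, end, barcode,
#' count), 0-based half-open as in BED. Lines starting with `#` are comments.
#' Plain or gzip/bgzip-compressed files are accepted.
#'
#' @param path Path to the fragments TSV (optionally `.gz`).
#' @return A tibble with columns `chrom`, `start`, `end`, `barcode`, `count`,
#'   in file order.
#' @export
read_fragments <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con)
  close(con)
  is_comment <- startsWith(lines, "#")
  keep <- which(!is_comment & nzchar(lines))
  if (length(keep) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  barcode = character(), count = integer()))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 5)) {
    stop("malformed fragments line ", keep[which(nf < 5)[1]],
         ": expected >= 5 tab-separated fields")
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  count <- suppressWarnings(as.integer(vapply(fields, `[`, "", 5L)))
  bad <- which(is.na(start) | is.na(end) | is.na(count))
  if (length(bad)) {
    stop("malformed fragments line ", keep[bad[1]],
         ": non-numeric coordinate or count")
  }
  bad <- which(end <= start)
  if (length(bad)) {
    stop("invalid fragment at line ", keep[bad[1]], ": end <= start")
  }
  if (any(count < 1)) {
    stop("invalid fragment at line ", keep[which(count < 1)[1]], ": count < 1")
  }
  tibble(
    chrom = vapply(fields, `[`, "", 1L),
    start = start, end = end,
    barcode = vapply(fields, `[`, "", 4L),
    count = count
  )
}

#' Write a fragments tibble as TSV
#'
#' @param fragments Tibble as returned by [read_fragments()].
#' @param path Output path.
#' @export
write_fragments <- function(fragments, path) {
  write.table(
    fragments[, c("chrom", "start", "end", "barcode", "count")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

fragments_to_granges <- function(fragments) {
  GenomicRanges::GRanges(
    seqnames = fragments$chrom,
    ranges = IRanges::IRanges(start = fragments$start + 1L,
                              end = fragments$end)
  )
}
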