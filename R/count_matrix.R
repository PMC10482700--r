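#' Fragment-to-region count matrix
#'
#' Entry (cell, region) is the number of fragments of that barcode that
#' overlap the region by any amount. A fragment spanning two regions is
#' counted once in each; the duplicate-count field of the fragments file is
#' ignored (unique-fragment semantics). Fragments from barcodes outside
#' `barcodes` are dropped; barcodes without fragments keep an all-zero row.
#'
#' @param fragments Fragments tibble.
#' @param regions Tibble with `chrom`, `start`, `end` (or canonical names);
#'   assumed non-overlapping (consensus output).
#' @param barcodes Character vector of allowed cell barcodes (row order of
#'   the result).
#' @return A sparse [Matrix::dgCMatrix-class] (cells x regions) with dimnames.
#' @export
make_count_matrix <- function(fragments, regions, barcodes) {
  if (is.character(regions)) regions <- parse_region_names(regions)
  region_names <- region_name(regions$chrom, regions$start, regions$end)
  frag <- fragments[fragments$barcode %in% barcodes, ]
  counts <- Matrix::sparseMatrix(
    i = integer(), j = integer(), x = numeric(),
    dims = c(length(barcodes), nrow(regions)),
    dimnames = list(barcodes, region_names)
  )
  if (nrow(frag) > 0 && nrow(regions) > 0) {
    hits <- GenomicRanges::findOverlaps(fragments_to_granges(frag),
                                        regions_to_granges(regions))
    if (length(hits) > 0) {
      i <- match(frag$barcode[S4Vectors::queryHits(hits)], barcodes)
      j <- S4Vectors::subjectHits(hits)
      counts <- Matrix::sparseMatrix(
        i = i, j = j, x = 1,
        dims = c(length(barcodes), nrow(regions)),
        dimnames = list(barcodes, region_names)
      )
    }
  }
  methods::as(counts, "CsparseMatrix")
}

#' Write a count matrix as MatrixMarket with name sidecars
#'
#' Writes `matrix.mtx`, `barcodes.txt` (rows) and `regions.txt` (columns)
#' into `dir`.
#'
#' @param counts Sparse or dense matrix with dimnames.
#' @param dir Output directory (created if needed).
#' @export
write_count_matrix <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "barcodes.txt"))
  writeLines(colnames(counts), file.path(dir, "regions.txt"))
  invisible(dir)
}

#' Read a count matrix written by [write_count_matrix()]
#'
#' @param dir Directory holding `matrix.mtx`, `barcodes.txt`, `regions.txt`.
#' @return Sparse matrix (cells x features) with dimnames.
#' @export
read_count_matrix <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  dimnames(m) <- list(readLines(file.path(dir, "barcodes.txt")),
                      readLines(file.path(dir, "regions.txt")))
  methods::as(methods::as(m, "dMatrix"), "CsparseMatrix")
}
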