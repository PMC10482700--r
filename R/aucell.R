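#' AUCell signature enrichment per cell
#'
#' Per cell, features are ranked by decreasing value (ties broken by a seeded
#' shuffle) and the enrichment of a signature is the area under its recovery
#' curve within the top `top_fraction` of the ranking, normalized by the
#' maximum achievable area at that cut-off, so scores lie in `[0, 1]`. Being
#' rank-based, the score is invariant to monotone transforms of the feature
#' values.
#'
#' @param mat Cells x features matrix (raw values).
#' @param signatures Named list of feature sets.
#' @param top_fraction Ranking cut-off (default 0.05).
#' @param seed Integer seed for tie-breaking.
#' @return An `AUCMatrix`: cells x signatures matrix in `[0, 1]` with
#'   attribute `top_fraction`.
#' @export
aucell <- function(mat, signatures, top_fraction = 0.05, seed = 1) {
  mat <- as.matrix(mat)
  if (length(signatures) == 0) stop("no signatures supplied")
  if (is.null(names(signatures))) {
    names(signatures) <- paste0("signature_", seq_along(signatures))
  }
  sig_idx <- lapply(signatures, function(s) {
    if (length(s) == 0) stop("empty signature")
    idx <- match(unique(s), colnames(mat))
    idx[!is.na(idx)]
  })
  if (any(lengths(sig_idx) == 0)) {
    stop("signature(s) with no features in the matrix: ",
         paste(names(signatures)[lengths(sig_idx) == 0], collapse = ", "))
  }
  n <- ncol(mat)
  n_top <- ceiling(top_fraction * n)
  set.seed(seed)
  key <- matrix(runif(length(mat)), nrow = nrow(mat))
  out <- matrix(0, nrow(mat), length(signatures),
                dimnames = list(rownames(mat), names(signatures)))
  for (ci in seq_len(nrow(mat))) {
    ord <- order(-mat[ci, ], key[ci, ])
    rank_of <- integer(n)
    rank_of[ord] <- seq_len(n)
    for (si in seq_along(sig_idx)) {
      r <- rank_of[sig_idx[[si]]]
      m <- length(r)
      rcc <- cumsum(tabulate(r[r <= n_top], nbins = n_top))
      out[ci, si] <- sum(rcc) / sum(pmin(seq_len(n_top), m))
    }
  }
  structure(out, top_fraction = top_fraction, seed = as.integer(seed),
            class = c("AUCMatrix", class(out)))
}

#' Regulon specificity scores (RSS)
#'
#' Per signature and cell type: the per-cell enrichment vector is normalized
#' to a probability distribution `p`, compared by Jensen-Shannon divergence
#' (base 2, bounded by 1) to the normalized cell-type indicator distribution
#' `q`, and scored as `RSS = 1 - sqrt(JSD(p, q))`. The score is invariant to
#' positive rescaling of the enrichment vector. All-zero enrichment vectors
#' yield 0 with a warning.
#'
#' @param auc Cells x signatures matrix (e.g. from [aucell()]).
#' @param labels Cell-type labels (named vector or tibble).
#' @return An `RSSMatrix`: signatures x cell types matrix in `[0, 1]`.
#' @export
rss <- function(auc, labels) {
  auc <- as.matrix(auc)
  labels <- labels_to_vector(labels, rownames(auc))
  types <- sort(unique(labels))
  if (length(types) < 2) stop("need at least 2 cell types")
  out <- matrix(0, ncol(auc), length(types),
                dimnames = list(colnames(auc), types))
  for (si in seq_len(ncol(auc))) {
    a <- auc[, si]
    if (sum(a) == 0) {
      warning("all-zero enrichment vector for signature ", colnames(auc)[si],
              "; RSS set to 0")
      next
    }
    p <- a / sum(a)
    for (ti in seq_along(types)) {
      q <- as.numeric(labels == types[ti])
      q <- q / sum(q)
      out[si, ti] <- 1 - sqrt(js_divergence(p, q))
    }
  }
  structure(out, class = c("RSSMatrix", class(out)))
}
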