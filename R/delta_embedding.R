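#' Embedding shift from a perturbation simulation
#'
#' Estimates, per cell, a 2-D shift on a supplied embedding (transition-
#' probability style): each cell's simulated profile change is compared with
#' the baseline profile differences to its `k_neighbors` nearest embedding
#' neighbors; the similarity-weighted (softmax over Pearson correlations)
#' average of the unit direction vectors to those neighbors, minus their
#' unweighted average, is the cell's shift. Cells whose simulated profile
#' equals the baseline get a zero shift. Shifts are equivariant under
#' rotation of the embedding.
#'
#' @param baseline Cells x features baseline matrix (expression or AUC).
#' @param simulated Cells x features simulated matrix (same shape).
#' @param embedding Cells x 2 matrix aligned to the rows.
#' @param k_neighbors Number of embedding neighbors (default 15).
#' @param temperature Softmax temperature on the correlations (default 0.05).
#' @return A `DeltaEmbedding` tibble: `cell`, `x`, `y`, `dx`, `dy`.
#' @export
delta_embedding <- function(baseline, simulated, embedding,
                            k_neighbors = 15, temperature = 0.05) {
  baseline <- as.matrix(baseline); simulated <- as.matrix(simulated)
  embedding <- as.matrix(embedding)
  n <- nrow(baseline)
  stopifnot(nrow(simulated) == n, nrow(embedding) == n, ncol(embedding) == 2)
  if (k_neighbors >= n) stop("k_neighbors must be smaller than the number of cells")
  d2 <- as.matrix(stats::dist(embedding))
  shifts <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    delta <- simulated[i, ] - baseline[i, ]
    if (all(abs(delta) < 1e-12)) next
    nb <- order(d2[i, ])[-1][seq_len(k_neighbors)]
    dirs <- embedding[nb, , drop = FALSE] -
      matrix(embedding[i, ], k_neighbors, 2, byrow = TRUE)
    lens <- sqrt(rowSums(dirs^2))
    lens[lens == 0] <- 1
    dirs <- dirs / lens
    sims <- vapply(nb, function(j) {
      suppressWarnings(cor(delta, baseline[j, ] - baseline[i, ]))
    }, 0)
    sims[is.na(sims)] <- 0
    w <- exp(sims / temperature)
    w <- w / sum(w)
    shifts[i, ] <- colSums(dirs * w) - colMeans(dirs)
  }
  structure(
    tibble(cell = rownames(baseline) %||% as.character(seq_len(n)),
           x = embedding[, 1], y = embedding[, 2],
           dx = shifts[, 1], dy = shifts[, 2]),
    class = c("DeltaEmbedding", class(tibble())))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
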