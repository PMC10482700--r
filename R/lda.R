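#' Fit an LDA topic model on binarized accessibility with collapsed Gibbs
#'
#' Cells are documents and accessible regions are tokens. Counts are
#' binarized by default (any nonzero entry contributes one token, the
#' cisTopic convention); set `binarize = FALSE` to use counts as token
#' multiplicities. Priors follow the standard heuristic defaults
#' `alpha = 50 / K` and `beta = 0.1`. Point estimates are averaged over
#' post-burn-in Gibbs samples taken every `sample_lag` sweeps. Runs are
#' reproducible given `seed`.
#'
#' @param counts Cells x regions matrix (sparse or dense, with dimnames).
#' @param K Number of topics (>= 2).
#' @param n_iter Total Gibbs sweeps.
#' @param seed Integer seed.
#' @param alpha,beta Dirichlet priors on cell-topic and topic-region.
#' @param burn_in Sweeps discarded before averaging (default `n_iter / 2`).
#' @param sample_lag Spacing between retained samples (default 10).
#' @param binarize Binarize counts into presence/absence tokens.
#' @return A `TopicModel` object: list with `cell_topic` (cells x K,
#'   row-stochastic), `topic_region` (K x regions, row-stochastic),
#'   `loglik_trace` (length `n_iter`), priors, seed and the token matrix
#'   used (for model-selection metrics).
#' @export
fit_lda_gibbs <- function(counts, K, n_iter = 150, seed = 1,
                          alpha = 50 / K, beta = 0.1,
                          burn_in = floor(n_iter / 2), sample_lag = 10,
                          binarize = TRUE) {
  if (K < 2) stop("K must be >= 2")
  if (n_iter <= burn_in) stop("n_iter must exceed burn_in")
  m <- Matrix::Matrix(counts, sparse = TRUE)
  m <- methods::as(methods::as(m, "dMatrix"), "CsparseMatrix")
  if (length(m@x) == 0) stop("empty count matrix")
  if (binarize) m@x <- rep(1, length(m@x))
  sm <- Matrix::summary(m)
  sm <- sm[sm$x > 0, , drop = FALSE]
  n_signal <- length(unique(sm$j))
  if (K > n_signal) stop("K exceeds the number of regions with signal")
  doc <- rep.int(sm$i, sm$x) - 1L
  word <- rep.int(sm$j, sm$x) - 1L

  set.seed(seed)
  fit <- lda_gibbs_cpp(doc, word, nrow(m), ncol(m), as.integer(K),
                       as.integer(n_iter), alpha, beta,
                       as.integer(burn_in), as.integer(sample_lag))
  cell_topic <- fit$cell_topic
  topic_region <- fit$topic_region
  cell_topic <- cell_topic / rowSums(cell_topic)
  topic_region <- topic_region / rowSums(topic_region)
  dimnames(cell_topic) <- list(rownames(m), paste0("topic_", seq_len(K)))
  dimnames(topic_region) <- list(paste0("topic_", seq_len(K)), colnames(m))

  structure(
    list(K = as.integer(K), alpha = alpha, beta = beta,
         cell_topic = cell_topic, topic_region = topic_region,
         loglik_trace = fit$loglik, seed = as.integer(seed),
         n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
         sample_lag = as.integer(sample_lag), n_samples = fit$n_samples,
         tokens = m, matrix_hash = digest::digest(m)),
    class = "TopicModel"
  )
}

#' @export
print.TopicModel <- function(x, ...) {
  cat(sprintf(
    "TopicModel: K=%d, alpha=%.4g, beta=%.4g, %d cells x %d regions, %d sweeps (seed %d)\n",
    x$K, x$alpha, x$beta, nrow(x$cell_topic), ncol(x$topic_region),
    x$n_iter, x$seed))
  invisible(x)
}

#' Model selection table for a set of topic models
#'
#' Reports, per model: the final log joint likelihood of the Gibbs trace,
#' UMass co-document coherence averaged over topics (top 20 regions each),
#' and the mean pairwise Jensen-Shannon distance between topic-region rows.
#' No automatic selection is made; choose K by inspecting the table.
#'
#' @param models List of `TopicModel` objects fit on the same matrix.
#' @param top_n Regions per topic entering the coherence sum (default 20).
#' @return Tibble with columns `K`, `log_likelihood`, `coherence`,
#'   `topic_divergence`.
#' @export
model_selection_metrics <- function(models, top_n = 20) {
  if (length(models) < 2) stop("need at least 2 models")
  hashes <- vapply(models, function(m) m$matrix_hash, "")
  if (length(unique(hashes)) != 1) {
    stop("models were fit on different matrices")
  }
  purrr::map_dfr(models, function(m) {
    tibble(
      K = m$K,
      log_likelihood = m$loglik_trace[length(m$loglik_trace)],
      coherence = mean(vapply(seq_len(m$K), function(k) {
        umass_coherence(m$topic_region[k, ], m$tokens, top_n)
      }, 0)),
      topic_divergence = mean_pairwise_jsd(m$topic_region)
    )
  })
}

# UMass coherence of one topic over its top_n regions.
umass_coherence <- function(probs, tokens, top_n) {
  top <- head(order(probs, decreasing = TRUE), top_n)
  bin <- tokens[, top, drop = FALSE]
  bin@x <- rep(1, length(bin@x))
  co <- Matrix::crossprod(bin)  # co-document counts
  d <- Matrix::diag(co)
  s <- 0
  n <- length(top)
  for (m2 in 2:n) {
    for (l in 1:(m2 - 1)) {
      s <- s + log((co[m2, l] + 1) / max(d[l], 1))
    }
  }
  s
}

mean_pairwise_jsd <- function(phi) {
  K <- nrow(phi)
  if (K < 2) return(0)
  pairs <- utils::combn(K, 2)
  mean(apply(pairs, 2, function(ij) {
    js_divergence(phi[ij[1], ], phi[ij[2], ])
  }))
}

# Jensen-Shannon divergence in bits (base 2), bounded by 1.
js_divergence <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

#' Binarize topic-region distributions
#'
#' `otsu` thresholds each topic's region-probability vector by maximizing
#' between-class variance on a 256-bin histogram; `ntop` takes the `n`
#' highest-probability regions, ties broken by region name.
#'
#' @param model A `TopicModel`.
#' @param method `"otsu"` or `"ntop"`.
#' @param n Regions per topic for `ntop` (default 3000).
#' @return A `BinarizedTopics` object: named list of region-name vectors,
#'   with `method` and `parameter` attributes.
#' @export
binarize_topics <- function(model, method = c("otsu", "ntop"), n = 3000) {
  method <- match.arg(method)
  phi <- model$topic_region
  sets <- lapply(seq_len(nrow(phi)), function(k) {
    p <- phi[k, ]
    if (method == "otsu") {
      if (max(p) - min(p) < .Machine$double.eps * 10) {
        warning("constant probability vector in topic ", k,
                "; empty region set")
        return(character())
      }
      thr <- otsu_threshold(p)
      names(p)[p > thr]
    } else {
      ord <- order(-p, names(p))
      names(p)[ord[seq_len(min(n, length(p)))]]
    }
  })
  names(sets) <- rownames(phi)
  structure(sets, method = method, parameter = if (method == "ntop") n else NA,
            class = c("BinarizedTopics", "list"))
}

#' Otsu threshold of a numeric vector
#'
#' Exhaustively maximizes between-class variance over the boundaries of a
#' 256-bin histogram spanning the data range.
#'
#' @param x Numeric vector.
#' @param n_bins Histogram bins (default 256).
#' @return The threshold value; elements strictly above it form the
#'   foreground class.
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  breaks <- seq(min(x), max(x), length.out = n_bins + 1)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                nbins = n_bins)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w <- cumsum(h)
  total <- w[n_bins]
  mu <- cumsum(h * mids)
  mu_t <- mu[n_bins]
  w0 <- w[-n_bins]; w1 <- total - w0
  valid <- w0 > 0 & w1 > 0
  between <- rep(-Inf, n_bins - 1)
  between[valid] <- (mu_t * w0[valid] / total - mu[-n_bins][valid])^2 *
    total / (w0[valid] * w1[valid])
  breaks[which.max(between) + 1]
}

#' Impute accessibility dropouts from a topic model
#'
#' The imputed matrix is `scale_factor * cell_topic %*% topic_region`; since
#' both factors are row-stochastic, every cell's row sums to `scale_factor`.
#'
#' @param model A `TopicModel`.
#' @param scale_factor Multiplier (default 1e6).
#' @return Dense cells x regions matrix with attribute `scale_factor`.
#' @export
impute_accessibility <- function(model, scale_factor = 1e6) {
  imp <- (model$cell_topic %*% model$topic_region) * scale_factor
  attr(imp, "scale_factor") <- scale_factor
  imp
}

#' Write binarized topics as one BED file per topic
#'
#' @param binarized A `BinarizedTopics`.
#' @param dir Output directory.
#' @export
write_binarized_topics <- function(binarized, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(binarized)) {
    if (length(binarized[[nm]]) == 0) next
    write_bed(parse_region_names(binarized[[nm]]),
              file.path(dir, paste0(nm, ".bed")))
  }
  invisible(dir)
}
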