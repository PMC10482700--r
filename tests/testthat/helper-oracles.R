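# Independent brute-force / literal-transcription oracles used across the
# suite. These deliberately avoid the package's own code paths.

# Literal recursive filtering: among the overlapping extended peaks the one
# with the highest score is kept, the peaks it overlaps are removed, and the
# process repeats on the remainder until no overlapping peaks are left.
oracle_consensus <- function(peaks, half_width) {
  p <- peaks
  p$start <- pmax(p$summit - half_width, 0)
  p$end <- p$summit + half_width
  overlaps <- function(i, j) {
    p$chrom[i] == p$chrom[j] && p$start[i] < p$end[j] && p$start[j] < p$end[i]
  }
  remaining <- seq_len(nrow(p))
  kept <- integer()
  while (length(remaining)) {
    ord <- remaining[order(-p$score[remaining], p$chrom[remaining],
                           p$start[remaining])]
    best <- ord[1]
    kept <- c(kept, best)
    remaining <- setdiff(remaining, best)
    drop <- remaining[vapply(remaining, overlaps, TRUE, j = best)]
    remaining <- setdiff(remaining, drop)
  }
  out <- p[kept, ]
  out[order(out$chrom, out$start), c("chrom", "start", "end")]
}

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of group
# assignments (tie-free data only).
oracle_wilcox_exact <- function(x, y) {
  all_v <- c(x, y)
  stopifnot(!anyDuplicated(all_v))
  n <- length(x)
  r <- rank(all_v)
  w_obs <- sum(r[seq_len(n)])
  combos <- utils::combn(length(all_v), n)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- n * (length(all_v) + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Literal transcription of the recovery-curve statistics for one cluster
# ranking matrix (regions x clusters, rank 1 best).
oracle_cistarget <- function(region_set, ranks, auc_fraction, window_frac) {
  n <- nrow(ranks)
  m <- length(region_set)
  n_top <- ceiling(auc_fraction * n)
  window <- max(n_top, ceiling(window_frac * n))
  rcc <- sapply(colnames(ranks), function(cl) {
    sapply(seq_len(window), function(i) {
      sum(ranks[region_set, cl] <= i)
    })
  })
  max_area <- sum(pmin(seq_len(n_top), m))
  auc <- colSums(rcc[seq_len(n_top), , drop = FALSE]) / max_area
  nes <- (auc - mean(auc)) / sd(auc)
  mu <- rowMeans(rcc)
  sdv <- apply(rcc, 1, sd)
  ram <- sapply(colnames(ranks), function(cl) {
    which.max(rcc[, cl] - (mu + 2 * sdv))
  })
  leading <- lapply(colnames(ranks), function(cl) {
    region_set[ranks[region_set, cl] <= ram[[cl]]]
  })
  names(leading) <- colnames(ranks)
  list(auc = auc, nes = nes, rank_at_max = ram, leading = leading)
}

# Literal weighted running-sum GSEA (weight exponent 1).
oracle_gsea <- function(ranked, weights, set) {
  hit <- ranked %in% set
  p_hit <- cumsum(ifelse(hit, abs(weights), 0)) / sum(abs(weights[hit]))
  p_miss <- cumsum(ifelse(hit, 0, 1)) / sum(!hit)
  running <- p_hit - p_miss
  es <- max(running)
  at <- which.max(running)
  list(es = es, leading_edge = intersect(ranked[seq_len(at)], set))
}

# Step-function recovery AUC at a cut-off, normalized by the maximum area.
oracle_recovery_auc <- function(ranks_of_set, n_features, top_fraction) {
  n_top <- ceiling(top_fraction * n_features)
  rcc <- sapply(seq_len(n_top), function(i) sum(ranks_of_set <= i))
  sum(rcc) / sum(pmin(seq_len(n_top), length(ranks_of_set)))
}

# Direct-formula RSS.
oracle_rss <- function(auc_vec, indicator) {
  p <- auc_vec / sum(auc_vec)
  q <- indicator / sum(indicator)
  m <- (p + q) / 2
  kl <- function(a, b) sum(ifelse(a > 0, a * log2(a / b), 0))
  1 - sqrt(0.5 * kl(p, m) + 0.5 * kl(q, m))
}

# Monte-Carlo joint order-statistics probability.
oracle_order_stat_mc <- function(s, n_draws = 1e6, seed = 42) {
  set.seed(seed)
  k <- length(s)
  u <- matrix(runif(n_draws * k), ncol = k)
  u <- t(apply(u, 1, sort))
  mean(colSums(t(u) <= sort(s)) == k)
}

# Pure-R collapsed Gibbs LDA (independent of the compiled sampler),
# averaging post-burn-in samples.
oracle_lda_gibbs <- function(mat, K, n_iter, alpha, beta, seed,
                             burn_in = floor(n_iter / 2), lag = 10) {
  set.seed(seed)
  idx <- which(mat > 0, arr.ind = TRUE)
  doc <- idx[, 1]; word <- idx[, 2]
  D <- nrow(mat); V <- ncol(mat); n_tok <- length(doc)
  z <- sample.int(K, n_tok, replace = TRUE)
  ndk <- matrix(0, D, K); nkw <- matrix(0, K, V); nk <- numeric(K)
  for (t in seq_len(n_tok)) {
    ndk[doc[t], z[t]] <- ndk[doc[t], z[t]] + 1
    nkw[z[t], word[t]] <- nkw[z[t], word[t]] + 1
    nk[z[t]] <- nk[z[t]] + 1
  }
  theta_acc <- matrix(0, D, K); n_s <- 0
  for (it in seq_len(n_iter)) {
    for (t in seq_len(n_tok)) {
      d <- doc[t]; w <- word[t]; k <- z[t]
      ndk[d, k] <- ndk[d, k] - 1; nkw[k, w] <- nkw[k, w] - 1
      nk[k] <- nk[k] - 1
      p <- (ndk[d, ] + alpha) * (nkw[, w] + beta) / (nk + V * beta)
      k <- sample.int(K, 1, prob = p)
      z[t] <- k
      ndk[d, k] <- ndk[d, k] + 1; nkw[k, w] <- nkw[k, w] + 1
      nk[k] <- nk[k] + 1
    }
    if (it > burn_in && ((it - burn_in - 1) %% lag == 0)) {
      theta_acc <- theta_acc + (ndk + alpha) / (rowSums(ndk) + K * alpha)
      n_s <- n_s + 1
    }
  }
  theta_acc / n_s
}

# Brute-force best-hit log-odds PWM scan in plain R.
oracle_pwm_scan <- function(seq_str, pfms, background = rep(0.25, 4)) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  revcomp <- function(s) {
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  score_one <- function(s, lo) {
    v <- strsplit(s, "")[[1]]
    L <- ncol(lo)
    if (L > length(v)) return(-Inf)
    best <- -Inf
    for (off in 0:(length(v) - L)) {
      sc <- 0
      for (j in seq_len(L)) {
        b <- v[off + j]
        if (b %in% c("A", "C", "G", "T")) sc <- sc + lo[b, j]
      }
      best <- max(best, sc)
    }
    best
  }
  best <- -Inf
  for (pfm in pfms) {
    lo <- log2((pfm + 1e-4) / (1 + 4e-4)) - log2(background)
    rownames(lo) <- c("A", "C", "G", "T")
    best <- max(best, score_one(seq_str, lo),
                score_one(revcomp(seq_str), lo))
  }
  max(best, 0)
}

# Exhaustive two-level step-fit breakpoint (minimal SSE; ties -> largest
# step), on a decreasing vector.
oracle_basc <- function(v) {
  n <- length(v)
  best <- NULL; best_sse <- Inf
  for (b in 1:(n - 1)) {
    sse <- sum((v[1:b] - mean(v[1:b]))^2) +
      sum((v[(b + 1):n] - mean(v[(b + 1):n]))^2)
    if (sse < best_sse - 1e-12) {
      best_sse <- sse; best <- b
    } else if (abs(sse - best_sse) <= 1e-12) {
      if ((v[b] - v[b + 1]) > (v[best] - v[best + 1])) best <- b
    }
  }
  best
}

random_peaks <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    summit = sample(0:3000, n),
    score = round(runif(n, 0, 10), 2)
  )
}

# High-information PFM fixture around a random consensus.
random_pfm_for_tests <- function(length, major = 0.94) {
  cons <- sample(4, length, replace = TRUE)
  m <- matrix((1 - major) / 3, 4, length)
  m[cbind(cons, seq_len(length))] <- major
  rownames(m) <- c("A", "C", "G", "T")
  m
}
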