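# Standardized smooth curve along pseudotime: z-score the series, then a
# penalized-spline additive fit (mgcv, automatic smoothness selection);
# falls back to lowess on degenerate inputs.
fit_smooth_curve <- function(t, y) {
  z <- as.numeric(scale(y))
  if (all(!is.finite(z))) z <- rep(0, length(y))
  kk <- min(10, length(unique(t)) - 1)
  if (kk < 3) return(rep(mean(z), length(t)))
  fit <- tryCatch(
    mgcv::gam(z ~ s(t, k = kk)),
    error = function(e) NULL)
  if (is.null(fit)) {
    lw <- lowess(t, z)
    return(stats::approx(lw$x, lw$y, xout = t, rule = 2)$y)
  }
  as.numeric(predict(fit, newdata = data.frame(t = t)))
}

quantile_bin <- function(v, n_quantiles) {
  br <- unique(quantile(v, probs = seq(0, 1, length.out = n_quantiles + 1)))
  if (length(br) < 2) return(rep(1L, length(v)))
  findInterval(v, br, rightmost.closed = TRUE, all.inside = TRUE)
}

#' GRN-velocity differentiation forces
#'
#' For each eRegulon and differentiation path, standardized smooth curves are
#' fitted along pseudotime for the TF's expression and for the eRegulon's
#' target enrichment (AUC). Fitted TF-curve values and target-curve values
#' are binned into `n_quantiles` quantile bins, and each cell is mapped to
#' the nearest later cell whose target-curve value falls in the same quantile
#' bin (a cell with no later match maps to itself). The differentiation force
#' is the pseudotime distance to the matched cell; forces are zero for
#' self-matched cells and for cells at or below the `expr_quantile` of raw TF
#' expression. With multiple paths, per-path forces and embedding deltas are
#' averaged across the paths containing the cell, and a path's contribution
#' is suppressed at cells where the path-standardized TF curve deviates from
#' the globally standardized one by at least `t_p` (branch penalization).
#' Only positive (activator) eRegulons should be supplied.
#'
#' @param pseudotime Named numeric vector (per cell).
#' @param tf_expression Cells x eRegulons matrix of raw TF expression (one
#'   column per eRegulon, named like the AUC columns).
#' @param regulon_auc Cells x eRegulons enrichment matrix (same columns).
#' @param paths Named list of cell-name vectors, each ordered by
#'   nondecreasing pseudotime; default: one path containing all cells.
#' @param n_quantiles Quantile bins for curve matching (default 10).
#' @param t_p Branch-penalization threshold on standardized curves (default
#'   0.03; applied when there are >= 2 paths).
#' @param expr_quantile TF-expression quantile below which no arrow is drawn
#'   (default 0.70).
#' @param embedding Optional cells x 2 matrix for delta-embedding arrows.
#' @return A `VelocityResult`: list with `force` (cells x eRegulons matrix,
#'   >= 0), `matches` tibble (`path`, `regulon`, `cell`, `future_cell`,
#'   `force`), `delta` (cells x 2 matrix or NULL), `arrows` tibble (or NULL),
#'   `paths`.
#' @export
grn_velocity <- function(pseudotime, tf_expression, regulon_auc,
                         paths = NULL, n_quantiles = 10, t_p = 0.03,
                         expr_quantile = 0.70, embedding = NULL) {
  tf_expression <- as.matrix(tf_expression)
  regulon_auc <- as.matrix(regulon_auc)
  stopifnot(identical(colnames(tf_expression), colnames(regulon_auc)))
  cells <- names(pseudotime)
  if (is.null(cells)) stop("pseudotime must be named by cell")
  if (any(!is.finite(pseudotime))) stop("pseudotime must be finite")
  if (is.null(paths)) paths <- list(path1 = cells[order(pseudotime[cells])])
  if (is.null(names(paths))) names(paths) <- paste0("path", seq_along(paths))
  for (pn in names(paths)) {
    pc <- paths[[pn]]
    if (length(pc) < 10) stop("path with fewer than 10 cells: ", pn)
    if (is.unsorted(pseudotime[pc])) {
      stop("path not ordered by pseudotime: ", pn)
    }
  }
  regs <- colnames(tf_expression)
  force <- matrix(0, length(cells), length(regs),
                  dimnames = list(cells, regs))
  contrib <- matrix(0, length(cells), length(regs),
                    dimnames = list(cells, regs))
  delta <- if (!is.null(embedding)) {
    matrix(0, length(cells), 2, dimnames = list(cells, c("dx", "dy")))
  }
  matches <- list()
  multi <- length(paths) >= 2

  for (r in regs) {
    # arrows only for cells above the dataset-level TF-expression quantile
    expr_thr <- quantile(tf_expression[cells, r], expr_quantile)
    g_global <- if (multi) {
      ordc <- cells[order(pseudotime[cells])]
      setNames(fit_smooth_curve(pseudotime[ordc], tf_expression[ordc, r]),
               ordc)
    }
    for (pn in names(paths)) {
      pc <- paths[[pn]]
      t <- pseudotime[pc]
      g_tf <- fit_smooth_curve(t, tf_expression[pc, r])
      g_tg <- fit_smooth_curve(t, regulon_auc[pc, r])
      # Quantile bins on the pooled fitted values so the two standardized
      # curves are compared on a common value scale; identical curves then
      # self-match everywhere (zero force).
      br <- unique(quantile(c(g_tf, g_tg),
                            probs = seq(0, 1, length.out = n_quantiles + 1)))
      bin_of <- function(v) {
        if (length(br) < 2) rep(1L, length(v)) else
          findInterval(v, br, rightmost.closed = TRUE, all.inside = TRUE)
      }
      bin_tf <- bin_of(g_tf)
      bin_tg <- bin_of(g_tg)
      pen_ok <- if (multi) {
        abs(g_tf - g_global[pc]) < t_p
      } else rep(TRUE, length(pc))
      for (ci in seq_along(pc)) {
        cell <- pc[ci]
        contrib[cell, r] <- contrib[cell, r] + 1
        if (tf_expression[cell, r] <= expr_thr || !pen_ok[ci]) next
        # the cell itself is a candidate: posterior-or-self in the same bin
        later <- which(t >= t[ci] & bin_tg == bin_tf[ci])
        if (length(later) == 0) next  # no match: maps to itself, force 0
        fut <- later[which.min(t[later] - t[ci])]
        f <- t[fut] - t[ci]
        if (f <= 0) next
        force[cell, r] <- force[cell, r] + f
        if (!is.null(delta)) {
          delta[cell, ] <- delta[cell, ] +
            (embedding[pc[fut], ] - embedding[cell, ])
        }
        matches[[length(matches) + 1]] <- tibble(
          path = pn, regulon = r, cell = cell, future_cell = pc[fut],
          force = f)
      }
    }
  }
  contrib[contrib == 0] <- 1
  force <- force / contrib
  if (!is.null(delta)) delta <- delta / rowMeans(contrib)
  arrows <- if (!is.null(delta)) {
    tibble(cell = cells, x = embedding[cells, 1], y = embedding[cells, 2],
           dx = delta[, 1], dy = delta[, 2])
  }
  structure(
    list(force = force,
         matches = if (length(matches)) dplyr::bind_rows(matches) else
           tibble(path = character(), regulon = character(),
                  cell = character(), future_cell = character(),
                  force = double()),
         delta = delta, arrows = arrows, paths = paths,
         n_quantiles = n_quantiles, t_p = t_p,
         expr_quantile = expr_quantile),
    class = "VelocityResult")
}

#' @export
print.VelocityResult <- function(x, ...) {
  cat(sprintf(
    "VelocityResult: %d cells x %d eRegulons, %d path(s), %d matches\n",
    nrow(x$force), ncol(x$force), length(x$paths), nrow(x$matches)))
  invisible(x)
}

#' Prioritize differentiation forces per cell group
#'
#' Applies the regulon specificity score ([rss()]) to the cell x eRegulon
#' force matrix (arrow lengths), per group label.
#'
#' @param velocity A `VelocityResult`.
#' @param labels Cell group labels (named vector or tibble).
#' @return Tibble with `regulon`, `group`, `score`.
#' @export
prioritize_forces <- function(velocity, labels) {
  f <- velocity$force
  if (all(f == 0)) {
    warning("all forces are zero; scores are 0")
    labels <- labels_to_vector(labels, rownames(f))
    return(tidyr::expand_grid(regulon = colnames(f),
                              group = sort(unique(labels))) |>
             dplyr::mutate(score = 0))
  }
  m <- rss(f, labels)
  as_tibble(as.table(unclass(m)), .name_repair = ~c("regulon", "group",
                                                    "score"))
}
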