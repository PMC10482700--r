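#' Differentially accessible regions (Wilcoxon rank-sum)
#'
#' One-vs-rest contrasts per group by default. For each region and contrast a
#' two-sided Wilcoxon rank-sum test is computed (exact for small tie-free
#' samples via [stats::wilcox.test()], otherwise the normal approximation
#' with tie and continuity correction). The effect is
#' `logFC = log2((mean_in + eps) / (mean_out + eps))`; p-values are
#' Benjamini-Hochberg adjusted across regions within each contrast, and a
#' region passes when `logFC > logfc_min` and the adjusted p-value is below
#' `adj_p_max`.
#'
#' @param imputed Cells x regions matrix (imputed accessibility; any cells x
#'   features matrix works).
#' @param labels Group label per cell: named vector or tibble with columns
#'   `barcode`, `cell_type`.
#' @param contrasts Currently only `"one_vs_rest"`.
#' @param logfc_min,adj_p_max Pass thresholds (defaults 0.5 and 0.05).
#' @param epsilon Guard added to both means; defaults to
#'   `1e-12 * scale_factor` of the imputed matrix (or `1e-12`).
#' @return Tibble with columns `region`, `group`, `log_fc`, `p_value`,
#'   `adj_p_value`, `passes`.
#' @export
find_dars <- function(imputed, labels, contrasts = "one_vs_rest",
                      logfc_min = 0.5, adj_p_max = 0.05, epsilon = NULL) {
  stopifnot(identical(contrasts, "one_vs_rest"))
  labels <- labels_to_vector(labels, rownames(imputed))
  groups <- unique(labels)
  if (length(groups) < 2) stop("need at least 2 groups")
  if (is.null(epsilon)) {
    sf <- attr(imputed, "scale_factor")
    epsilon <- if (is.null(sf)) 1e-12 else 1e-12 * sf
  }
  imputed <- as.matrix(imputed)
  out <- purrr::map_dfr(groups, function(g) {
    idx <- labels == g
    if (sum(idx) < 2) {
      warning("group with fewer than 2 cells skipped: ", g)
      return(NULL)
    }
    mean_in <- colMeans(imputed[idx, , drop = FALSE])
    mean_out <- colMeans(imputed[!idx, , drop = FALSE])
    p <- vapply(seq_len(ncol(imputed)), function(j) {
      x <- imputed[idx, j]; y <- imputed[!idx, j]
      if (all(x == x[1]) && all(y == y[1]) && x[1] == y[1]) return(1)
      suppressWarnings(wilcox.test(x, y)$p.value)
    }, 0)
    tibble(
      region = colnames(imputed),
      group = g,
      log_fc = log2((mean_in + epsilon) / (mean_out + epsilon)),
      p_value = p,
      adj_p_value = p.adjust(p, method = "BH")
    )
  })
  out$passes <- out$log_fc > logfc_min & out$adj_p_value < adj_p_max
  out
}

# Accept labels as a named vector or a (barcode, cell_type) tibble, aligned
# to `cells`.
labels_to_vector <- function(labels, cells) {
  if (is.data.frame(labels)) {
    lab_col <- intersect(c("cell_type", "group", "label"), names(labels))[1]
    if (is.na(lab_col) || !"barcode" %in% names(labels)) {
      stop("label tibble needs columns barcode and cell_type")
    }
    labels <- setNames(labels[[lab_col]], labels$barcode)
  }
  if (!is.null(names(labels)) && !is.null(cells)) {
    if (!all(cells %in% names(labels))) stop("labels missing for some cells")
    labels <- labels[cells]
  }
  as.character(labels)
}
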