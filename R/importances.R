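# Gradient-boosted regression fit with GRNBoost2-like defaults.
boosted_fit <- function(X, y, seed, n_trees = 500, eta = 0.01,
                        max_depth = 3, subsample = 0.9) {
  xgboost::xgb.train(
    params = list(objective = "reg:squarederror", eta = eta,
                  max_depth = max_depth, subsample = subsample,
                  nthread = 1, seed = seed),
    data = xgboost::xgb.DMatrix(as.matrix(X), label = y, nthread = 1),
    nrounds = n_trees, verbose = 0)
}

boosted_predict <- function(fit, X) {
  predict(fit, xgboost::xgb.DMatrix(as.matrix(X), nthread = 1))
}

# Gradient-boosted feature importances: total split gain per feature from
# the tree dump, normalized to sum to 1; features never used get 0.
boosted_importance <- function(X, y, seed, n_trees = 500, eta = 0.01,
                               max_depth = 3, subsample = 0.9) {
  X <- as.matrix(X)
  out <- setNames(numeric(ncol(X)), colnames(X))
  if (var(y) == 0 || ncol(X) == 0) return(out)
  fit <- boosted_fit(X, y, seed, n_trees, eta, max_depth, subsample)
  if (ncol(X) >= 2) {
    imp <- xgboost::xgb.importance(model = fit)
    if (!is.null(imp) && nrow(imp) > 0) out[imp$Feature] <- imp$Gain
  } else {
    # gain-share from the tree dump (the importance accessor does not
    # support single-feature boosters)
    dump <- xgboost::xgb.model.dt.tree(model = fit)
    splits <- dump$Feature != "Leaf"
    if (any(splits)) out[1] <- 1
  }
  out
}

sign_from_rho <- function(rho, threshold = 0.03) {
  dplyr::case_when(
    is.na(rho) ~ "none",
    rho > threshold ~ "+",
    rho < -threshold ~ "-",
    TRUE ~ "none"
  )
}

#' TF-to-gene importances (gradient boosting)
#'
#' Per target gene, a gradient-boosted ensemble regresses the gene's
#' expression on all TF expressions (excluding the gene itself when it is a
#' TF); the per-feature importance is the TF-to-gene score. Pearson
#' correlation signs the interaction: `+` above `rho_threshold`, `-` below
#' `-rho_threshold`, otherwise `none`. A TF's self-importance is the maximum
#' importance over all its targets plus 1e-5.
#'
#' @param expression Cells (or metacells) x genes matrix.
#' @param tf_list Character vector of TF gene names (subset of columns).
#' @param seed Integer seed.
#' @param rho_threshold Correlation sign threshold (default 0.03).
#' @param n_trees,eta,max_depth,subsample Gradient-boosting hyperparameters
#'   (defaults 500, 0.01, 3, 0.9).
#' @return Tibble with `tf`, `target`, `importance`, `rho`, `sign`, plus the
#'   hyperparameters as attributes.
#' @export
tf_gene_importance <- function(expression, tf_list, seed = 1,
                               rho_threshold = 0.03, n_trees = 500,
                               eta = 0.01, max_depth = 3, subsample = 0.9) {
  expression <- as.matrix(expression)
  genes <- colnames(expression)
  if (!all(tf_list %in% genes)) {
    stop("tf_list contains genes absent from the expression matrix")
  }
  targets <- genes
  rows <- purrr::map_dfr(targets, function(g) {
    feats <- setdiff(tf_list, g)
    if (length(feats) == 0) return(NULL)
    y <- expression[, g]
    imp <- boosted_importance(expression[, feats, drop = FALSE], y,
                              seed = seed, n_trees = n_trees, eta = eta,
                              max_depth = max_depth, subsample = subsample)
    rho <- suppressWarnings(
      as.numeric(cor(expression[, feats, drop = FALSE], y)))
    tibble(tf = feats, target = g, importance = as.numeric(imp),
           rho = ifelse(is.na(rho), 0, rho))
  })
  rows$sign <- sign_from_rho(rows$rho, rho_threshold)
  self <- purrr::map_dfr(tf_list, function(tf) {
    own <- rows$importance[rows$tf == tf]
    tibble(tf = tf, target = tf,
           importance = (if (length(own)) max(own) else 0) + 1e-5,
           rho = 1, sign = "+")
  })
  out <- dplyr::bind_rows(rows[rows$tf != rows$target, ], self)
  attr(out, "hyperparameters") <- list(n_trees = n_trees, eta = eta,
                                       max_depth = max_depth,
                                       subsample = subsample, seed = seed)
  out
}

#' Region-to-gene importances (gradient boosting)
#'
#' Per gene, a gradient-boosted ensemble regresses the gene's expression on
#' the (imputed) accessibility of the regions in its search space; the
#' per-feature importance is the region-to-gene score. Spearman rank
#' correlation signs the link at +/- `rho_threshold`. Genes without regions
#' in their search space are skipped.
#'
#' @param accessibility Cells (or metacells) x regions matrix.
#' @param expression Cells x genes matrix (same rows).
#' @param search_space Tibble from [define_search_space()].
#' @param seed Integer seed.
#' @param rho_threshold Correlation sign threshold (default 0.03).
#' @param n_trees,eta,max_depth,subsample Gradient-boosting hyperparameters.
#' @return Tibble with `region`, `target`, `importance`, `rho`, `sign`.
#' @export
region_gene_importance <- function(accessibility, expression, search_space,
                                   seed = 1, rho_threshold = 0.03,
                                   n_trees = 500, eta = 0.01, max_depth = 3,
                                   subsample = 0.9) {
  accessibility <- as.matrix(accessibility)
  expression <- as.matrix(expression)
  stopifnot(nrow(accessibility) == nrow(expression))
  space <- search_space[search_space$region %in% colnames(accessibility) &
                          search_space$gene %in% colnames(expression), ]
  genes <- unique(space$gene)
  skipped <- setdiff(intersect(unique(search_space$gene),
                               colnames(expression)), genes)
  if (length(skipped)) {
    message(length(skipped), " gene(s) without usable regions skipped")
  }
  out <- purrr::map_dfr(genes, function(g) {
    regs <- unique(space$region[space$gene == g])
    y <- expression[, g]
    X <- accessibility[, regs, drop = FALSE]
    imp <- boosted_importance(X, y, seed = seed, n_trees = n_trees,
                              eta = eta, max_depth = max_depth,
                              subsample = subsample)
    rho <- suppressWarnings(as.numeric(cor(X, y, method = "spearman")))
    tibble(region = regs, target = g, importance = as.numeric(imp),
           rho = ifelse(is.na(rho), 0, rho))
  })
  out$sign <- sign_from_rho(out$rho, rho_threshold)
  attr(out, "hyperparameters") <- list(n_trees = n_trees, eta = eta,
                                       max_depth = max_depth,
                                       subsample = subsample, seed = seed)
  out
}
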