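#' Pseudo-multiome metacells
#'
#' Pairs separate expression and accessibility experiments by sampling, per
#' metacell, `k_cells` cells without replacement from each modality within
#' the same cell-type label and averaging the raw expression and imputed
#' accessibility. With true multiome data use `mode = "identity"` to pass
#' both matrices through unchanged (cells are their own metacells).
#'
#' @param expression Cells x genes matrix (raw counts).
#' @param accessibility Cells x regions matrix (imputed accessibility).
#' @param labels Cell-type labels: for `"sample"` mode a list with elements
#'   `expression` and `accessibility` (named vectors/tibbles per modality) or
#'   a single labels object valid for both; for `"identity"` a single labels
#'   object.
#' @param n_metacells_per_type Metacells drawn per cell type (default 50).
#' @param k_cells Cells averaged per metacell (default 10).
#' @param seed Integer seed.
#' @param mode `"sample"` or `"identity"`.
#' @return A `MetacellPair`: list with `expression`, `accessibility`
#'   (metacells x features), `labels` tibble (`metacell`, `cell_type`) and
#'   `k_cells`.
#' @export
make_metacells <- function(expression, accessibility, labels,
                           n_metacells_per_type = 50, k_cells = 10,
                           seed = 1, mode = c("sample", "identity")) {
  mode <- match.arg(mode)
  if (mode == "identity") {
    if (!identical(rownames(expression), rownames(accessibility))) {
      stop("identity mode requires the same cells in both modalities")
    }
    lab <- labels_to_vector(labels, rownames(expression))
    return(structure(
      list(expression = as.matrix(expression),
           accessibility = as.matrix(accessibility),
           labels = tibble(metacell = rownames(expression), cell_type = lab),
           k_cells = 1L),
      class = "MetacellPair"))
  }
  lab_e <- labels_to_vector(if (is.list(labels) && !is.data.frame(labels))
    labels$expression else labels, rownames(expression))
  lab_a <- labels_to_vector(if (is.list(labels) && !is.data.frame(labels))
    labels$accessibility else labels, rownames(accessibility))
  types <- sort(unique(lab_e))
  if (!setequal(types, unique(lab_a))) {
    stop("modalities carry different label vocabularies")
  }
  set.seed(seed)
  expr_rows <- list(); acc_rows <- list(); meta <- list()
  for (ty in types) {
    ie <- which(lab_e == ty); ia <- which(lab_a == ty)
    if (length(ie) < k_cells || length(ia) < k_cells) {
      stop("cell type with fewer than k_cells cells: ", ty)
    }
    for (j in seq_len(n_metacells_per_type)) {
      se <- sample(ie, k_cells)
      sa <- sample(ia, k_cells)
      id <- paste0(ty, "_mc", j)
      expr_rows[[id]] <- colMeans(as.matrix(expression[se, , drop = FALSE]))
      acc_rows[[id]] <- colMeans(as.matrix(accessibility[sa, , drop = FALSE]))
      meta[[id]] <- ty
    }
  }
  structure(
    list(expression = do.call(rbind, expr_rows),
         accessibility = do.call(rbind, acc_rows),
         labels = tibble(metacell = names(meta),
                         cell_type = unlist(meta, use.names = FALSE)),
         k_cells = as.integer(k_cells)),
    class = "MetacellPair")
}

#' @export
print.MetacellPair <- function(x, ...) {
  cat(sprintf("MetacellPair: %d metacells (%d genes, %d regions), k_cells=%d\n",
              nrow(x$expression), ncol(x$expression), ncol(x$accessibility),
              x$k_cells))
  invisible(x)
}
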