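#' Binarize region-to-gene links
#'
#' Produces the seven standard variants: global importance quantile (0.85,
#' 0.90, 0.95), per-gene top-n (5, 10, 15) and a BASC-style step-function
#' binarization of each gene's sorted importance vector (the breakpoint
#' minimizing the two-level step-fit squared error; genes with fewer than two
#' positive links keep all of them). Only positive-sign links enter;
#' negative-sign links are recorded separately in the `negatives` attribute.
#'
#' @param table Region-to-gene importance tibble
#'   (see [region_gene_importance()]).
#' @param variants Character vector naming the variants to compute; default
#'   all seven.
#' @return Tibble with columns `variant`, `region`, `target`, `importance`,
#'   `rho`; attribute `negatives` holds the excluded negative-sign links.
#' @export
binarize_region_gene <- function(table,
                                 variants = c("quantile_0.85", "quantile_0.9",
                                              "quantile_0.95", "top_5",
                                              "top_10", "top_15", "basc")) {
  pos <- table[table$sign == "+", ]
  neg <- table[table$sign == "-", ]
  pieces <- lapply(variants, function(v) {
    kept <- if (grepl("^quantile_", v)) {
      q <- as.numeric(sub("^quantile_", "", v))
      thr <- quantile(pos$importance, q, names = FALSE)
      pos[pos$importance > thr, ]
    } else if (grepl("^top_", v)) {
      n <- as.integer(sub("^top_", "", v))
      dplyr::slice_max(dplyr::group_by(pos, .data$target),
                       order_by = .data$importance, n = n,
                       with_ties = FALSE) |> dplyr::ungroup()
    } else if (v == "basc") {
      dplyr::bind_rows(lapply(split(pos, pos$target), function(tb) {
        if (nrow(tb) < 2) return(tb)
        keep_n <- basc_breakpoint(sort(tb$importance, decreasing = TRUE))
        dplyr::slice_max(tb, order_by = .data$importance, n = keep_n,
                         with_ties = FALSE)
      }))
    } else {
      stop("unknown variant: ", v)
    }
    kept$variant <- v
    kept
  })
  out <- dplyr::bind_rows(pieces)[, c("variant", "region", "target",
                                      "importance", "rho")]
  attr(out, "negatives") <- neg
  out
}

#' BASC-style step-function breakpoint
#'
#' Given a vector sorted in decreasing order, returns the number of leading
#' elements kept by the optimal two-level step fit (the breakpoint minimizing
#' the within-level squared error; ties go to the breakpoint at the largest
#' step).
#'
#' @param v Numeric vector sorted decreasing, length >= 2.
#' @return Integer in `1..(length(v) - 1)`.
#' @export
basc_breakpoint <- function(v) {
  n <- length(v)
  stopifnot(n >= 2)
  sse <- vapply(seq_len(n - 1), function(b) {
    hi <- v[1:b]; lo <- v[(b + 1):n]
    sum((hi - mean(hi))^2) + sum((lo - mean(lo))^2)
  }, 0)
  cand <- which(sse == min(sse))
  if (length(cand) > 1) {
    steps <- v[cand] - v[cand + 1]
    cand <- cand[which.max(steps)]
  }
  cand[1]
}
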