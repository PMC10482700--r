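#' @export
autoplot.TopicModel <- function(object, ...) {
  df <- tibble(iteration = seq_along(object$loglik_trace),
               log_likelihood = object$loglik_trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$log_likelihood)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "Gibbs sweep", y = "log P(w, z)",
                  title = sprintf("LDA trace (K = %d)", object$K)) +
    ggplot2::theme_minimal()
}

#' Plot topic-model selection metrics against K
#'
#' @param metrics Tibble from [model_selection_metrics()].
#' @return A ggplot.
#' @export
plot_model_selection <- function(metrics) {
  long <- tidyr::pivot_longer(metrics, -"K", names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(.data$K, .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme_minimal()
}

#' Barcode QC scatter (unique fragments vs TSS enrichment, FRiP colour)
#'
#' @param qc Tibble from [compute_barcode_qc()].
#' @return A ggplot.
#' @export
plot_barcode_qc <- function(qc) {
  ggplot2::ggplot(qc, ggplot2::aes(.data$unique_fragments,
                                   .data$tss_enrichment,
                                   colour = .data$frip)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "unique fragments", y = "TSS enrichment",
                  colour = "FRiP") +
    ggplot2::theme_minimal()
}

#' Recovery curves of a region set across motif clusters
#'
#' @param region_set Region names.
#' @param rankingdb A `RankingDB`.
#' @param clusters Cluster names to draw (default all).
#' @param window Positions shown (default 10% of the database).
#' @return A ggplot.
#' @export
plot_recovery_curves <- function(region_set, rankingdb, clusters = NULL,
                                 window = NULL) {
  ranks <- rankingdb$ranks
  if (is.null(clusters)) clusters <- colnames(ranks)
  if (is.null(window)) window <- ceiling(0.1 * nrow(ranks))
  df <- purrr::map_dfr(clusters, function(cl) {
    r <- ranks[region_set, cl]
    tibble(cluster = cl, position = seq_len(window),
           recovered = cumsum(tabulate(r[r <= window], nbins = window)))
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$recovered,
                                   colour = .data$cluster)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "ranking position", y = "regions recovered") +
    ggplot2::theme_minimal()
}

#' Heatmap of regulon specificity scores
#'
#' @param rss_matrix Matrix from [rss()].
#' @return A ggplot.
#' @export
plot_rss <- function(rss_matrix) {
  df <- as_tibble(as.table(unclass(rss_matrix)),
                  .name_repair = ~c("signature", "cell_type", "rss"))
  ggplot2::ggplot(df, ggplot2::aes(.data$cell_type, .data$signature,
                                   fill = .data$rss)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @export
autoplot.SimulationResult <- function(object, n_genes = 20, ...) {
  top <- names(sort(abs(object$final_logfc), decreasing = TRUE))[
    seq_len(min(n_genes, length(object$final_logfc)))]
  df <- object$logfc[object$logfc$gene %in% top, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$log_fc,
                                   group = .data$gene)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(y = "log2 fold change vs baseline",
                  title = paste("knockout:",
                                paste(object$knocked_out, collapse = "+"))) +
    ggplot2::theme_minimal()
}

#' Arrow plot of embedding shifts
#'
#' Works for both [delta_embedding()] tibbles and the `arrows` element of a
#' `VelocityResult`.
#'
#' @param arrows Tibble with `x`, `y`, `dx`, `dy`.
#' @param scale Arrow scale multiplier (default 1).
#' @return A ggplot.
#' @export
plot_arrows <- function(arrows, scale = 1) {
  ggplot2::ggplot(arrows, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(size = 0.5, colour = "grey70") +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$x + scale * .data$dx,
                   yend = .data$y + scale * .data$dy),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.1, "cm")),
      data = arrows[abs(arrows$dx) + abs(arrows$dy) > 0, ]) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' @export
autoplot.VelocityResult <- function(object, ...) {
  if (is.null(object$arrows)) {
    stop("velocity was computed without an embedding; no arrows to draw")
  }
  plot_arrows(object$arrows, ...)
}
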