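#' Tidy a topic model
#'
#' @param x A `TopicModel`.
#' @param matrix `"topic_region"` (default) or `"cell_topic"`.
#' @param ... Unused.
#' @return Long tibble: (`topic`, `region`, `probability`) or (`cell`,
#'   `topic`, `probability`).
#' @export
tidy.TopicModel <- function(x, matrix = c("topic_region", "cell_topic"),
                            ...) {
  matrix <- match.arg(matrix)
  if (matrix == "topic_region") {
    as_tibble(as.table(x$topic_region),
              .name_repair = ~c("topic", "region", "probability"))
  } else {
    as_tibble(as.table(x$cell_topic),
              .name_repair = ~c("cell", "topic", "probability"))
  }
}

#' @export
glance.TopicModel <- function(x, ...) {
  tibble(K = x$K, alpha = x$alpha, beta = x$beta, n_iter = x$n_iter,
         seed = x$seed,
         log_likelihood = x$loglik_trace[length(x$loglik_trace)])
}

#' @export
tidy.SimulationResult <- function(x, ...) x$logfc

#' @export
glance.SimulationResult <- function(x, ...) {
  tibble(knocked_out = paste(x$knocked_out, collapse = "+"),
         n_iterations = x$n_iterations,
         n_genes = length(x$final_logfc),
         n_down = sum(x$final_logfc < 0),
         n_up = sum(x$final_logfc > 0))
}

#' @export
tidy.VelocityResult <- function(x, ...) {
  as_tibble(as.table(unclass(x$force)),
            .name_repair = ~c("cell", "regulon", "force"))
}

#' @export
glance.VelocityResult <- function(x, ...) {
  tibble(n_cells = nrow(x$force), n_regulons = ncol(x$force),
         n_paths = length(x$paths), n_matches = nrow(x$matches),
         mean_force = mean(x$matches$force))
}

#' @export
tidy.AUCMatrix <- function(x, ...) {
  as_tibble(as.table(unclass(x)),
            .name_repair = ~c("cell", "signature", "auc"))
}

#' @export
tidy.RSSMatrix <- function(x, ...) {
  as_tibble(as.table(unclass(x)),
            .name_repair = ~c("signature", "cell_type", "rss"))
}

#' @export
glance.eregulon_df <- function(x, ...) {
  s <- summarize_eregulons(x)
  tibble(n_eregulons = nrow(s),
         n_activators = sum(s$tf_sign == "+"),
         n_repressors = sum(s$tf_sign == "-"),
         median_genes = median(s$n_genes),
         median_regions = median(s$n_regions))
}
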