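#' Run the staged pipeline from a configuration
#'
#' Executes the workflow stages in order on files under `config$io$input_dir`
#' (the layout written by [write_scenario()]), writing versioned outputs and
#' a machine-readable manifest (stage parameters, derived seeds, input
#' checksums) under `config$io$out_dir`. A stage whose parameter/input
#' checksum matches the manifest and whose outputs exist is skipped, so a
#' rerun with an unchanged configuration re-executes nothing and a changed
#' parameter invalidates only its stage and everything downstream.
#'
#' Stages (a valid prefix may be selected via `config$stages`): `topics`,
#' `impute`, `dars`, `motif_db`, `enrich`, `grn`, `aucell`, `rss`.
#'
#' @param config A named list or path to a YAML file with sections `io`
#'   (`input_dir`, `out_dir`), `seed`, optional `stages`, and one optional
#'   parameter block per stage (`topics: {k: 5, n_iter: 150}`,
#'   `enrich: {nes_threshold: 3}`, ...).
#' @return The manifest (invisibly), a list with one entry per executed or
#'   skipped stage.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  io <- config$io
  stopifnot(!is.null(io$input_dir), !is.null(io$out_dir))
  seed <- config$seed %||% 1L
  dir.create(io$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(io$out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  } else list()

  all_stages <- c("topics", "impute", "dars", "motif_db", "enrich", "grn",
                  "aucell", "rss")
  stages <- config$stages %||% all_stages
  if (!identical(stages, all_stages[seq_along(stages)])) {
    stop("stages must form a valid prefix of: ",
         paste(all_stages, collapse = " -> "))
  }

  env <- new.env()
  env$counts_atac <- read_count_matrix(file.path(io$input_dir,
                                                 "counts_atac"))
  env$counts_rna <- read_count_matrix(file.path(io$input_dir, "counts_rna"))
  cells <- as_tibble(read.table(file.path(io$input_dir, "cells.tsv"),
                                header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE))
  env$labels <- setNames(cells$cell_type, cells$barcode)
  env$annotation <- read_gene_annotation(file.path(io$input_dir,
                                                   "genes.tsv"))
  fa <- Biostrings::readDNAStringSet(file.path(io$input_dir, "regions.fa"))
  env$sequences <- setNames(as.character(fa), names(fa))
  env$motif_annotation <- read_motif_annotation(
    file.path(io$input_dir, "motif_annotation.tsv"))
  mfiles <- list.files(file.path(io$input_dir, "motifs"),
                       full.names = TRUE)
  pfms <- do.call(c, lapply(mfiles, read_jaspar))
  env$motif_clusters <- make_motif_clusters(pfms, env$motif_annotation)

  input_hash <- digest::digest(list(
    dim(env$counts_atac), sum(env$counts_atac), dim(env$counts_rna),
    sum(env$counts_rna), env$labels, env$sequences))

  upstream_hash <- input_hash
  executed <- list()
  for (si in seq_along(stages)) {
    st <- stages[si]
    params <- config[[st]] %||% list()
    stage_seed <- derive_seed(seed, si)
    hash <- digest::digest(list(st, params, stage_seed, upstream_hash))
    out_dir <- file.path(io$out_dir, st)
    done <- !is.null(manifest[[st]]) &&
      identical(manifest[[st]]$checksum, hash) && dir.exists(out_dir)
    if (!done) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      run_stage(st, params, stage_seed, env, out_dir)
      manifest[[st]] <- list(checksum = hash, params = params,
                             seed = stage_seed,
                             completed = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    } else {
      load_stage(st, env, out_dir)
    }
    executed[[st]] <- list(executed = !done, checksum = hash)
    upstream_hash <- hash
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  }
  message("pipeline complete: ",
          sum(vapply(executed, function(e) e$executed, TRUE)),
          " stage(s) executed, ",
          sum(!vapply(executed, function(e) e$executed, TRUE)),
          " skipped")
  invisible(executed)
}

write_tsv_prov <- function(df, path, params) {
  con <- file(path, "w")
  writeLines(paste0("# egrnkit ", basename(path), " | params: ",
                    jsonlite::toJSON(params, auto_unbox = TRUE)), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  close(con)
}

run_stage <- function(st, params, stage_seed, env, out_dir) {
  switch(
    st,
    topics = {
      k <- params$k %||% length(unique(env$labels))
      env$model <- fit_lda_gibbs(env$counts_atac, K = max(k, 2),
                                 n_iter = params$n_iter %||% 150,
                                 seed = stage_seed)
      write_topic_model(env$model, out_dir)
    },
    impute = {
      env$imputed <- impute_accessibility(env$model,
                                          params$scale_factor %||% 1e6)
      write_count_matrix(Matrix::Matrix(env$imputed, sparse = TRUE),
                         file.path(out_dir, "imputed"))
    },
    dars = {
      env$dars <- find_dars(env$imputed, env$labels,
                            logfc_min = params$logfc_min %||% 0.5,
                            adj_p_max = params$adj_p_max %||% 0.05)
      write_tsv_prov(env$dars, file.path(out_dir, "dars.tsv"), params)
    },
    motif_db = {
      env$scoredb <- build_score_db(env$motif_clusters, env$sequences)
      env$rankingdb <- build_ranking_db(env$scoredb, seed = stage_seed)
      write_tsv_prov(data.frame(region = rownames(env$scoredb),
                                unclass(env$scoredb),
                                check.names = FALSE),
                     file.path(out_dir, "scores.tsv"), params)
      write_tsv_prov(data.frame(region = rownames(env$rankingdb$ranks),
                                env$rankingdb$ranks, check.names = FALSE),
                     file.path(out_dir, "rankings.tsv"),
                     list(seed = stage_seed))
    },
    enrich = {
      sets <- split(env$dars$region[env$dars$passes],
                    env$dars$group[env$dars$passes])
      sets <- sets[lengths(sets) > 0]
      env$enrichment <- purrr::map_dfr(names(sets), function(g) {
        res <- cistarget(
          unique(sets[[g]]), env$rankingdb,
          auc_fraction = params$auc_fraction %||% 0.05,
          nes_threshold = params$nes_threshold %||% 3.0,
          rank_at_max_fraction = params$rank_at_max_fraction %||% 0.25)
        if (nrow(res)) res$contrast <- g
        res
      })
      env$cistromes <- merge_cistromes(env$enrichment, env$motif_annotation)
      flat <- dplyr::mutate(env$enrichment,
                            cistrome = vapply(.data$cistrome, paste,
                                              "", collapse = ","))
      write_tsv_prov(flat, file.path(out_dir, "enrichment.tsv"), params)
    },
    grn = {
      space <- define_search_space(
        env$annotation, parse_region_names(colnames(env$counts_atac)))
      tfs <- intersect(unique(env$motif_annotation$tf),
                       colnames(env$counts_rna))
      mc <- make_metacells(as.matrix(env$counts_rna), env$imputed,
                           env$labels, mode = "identity")
      env$tf_gene <- tf_gene_importance(mc$expression, tfs,
                                        seed = stage_seed)
      env$region_gene <- region_gene_importance(mc$accessibility,
                                                mc$expression, space,
                                                seed = stage_seed)
      env$eregulons <- build_eregulons(
        env$cistromes, binarize_region_gene(env$region_gene), env$tf_gene,
        min_genes = params$min_genes %||% 10)
      write_tsv_prov(env$eregulons, file.path(out_dir, "eregulons.tsv"),
                     params)
    },
    aucell = {
      sigs <- c(eregulon_signatures(env$eregulons, "gene"))
      env$auc <- aucell(as.matrix(env$counts_rna), sigs,
                        top_fraction = params$top_fraction %||% 0.05,
                        seed = stage_seed)
      write_tsv_prov(as.data.frame(unclass(env$auc)),
                     file.path(out_dir, "auc.tsv"), params)
    },
    rss = {
      env$rss <- rss(env$auc, env$labels)
      write_tsv_prov(as.data.frame(unclass(env$rss)),
                     file.path(out_dir, "rss.tsv"), params)
    },
    stop("unknown stage: ", st)
  )
}

# Reload the outputs a skipped stage's downstream neighbours need.
load_stage <- function(st, env, out_dir) {
  switch(
    st,
    topics = env$model <- read_topic_model(out_dir),
    impute = {
      env$imputed <- as.matrix(read_count_matrix(file.path(out_dir,
                                                           "imputed")))
      attr(env$imputed, "scale_factor") <- 1e6
    },
    dars = env$dars <- as_tibble(read.table(
      file.path(out_dir, "dars.tsv"), header = TRUE, sep = "\t",
      comment.char = "#", stringsAsFactors = FALSE)),
    motif_db = {
      sc <- read.table(file.path(out_dir, "scores.tsv"), header = TRUE,
                       sep = "\t", comment.char = "#", check.names = FALSE,
                       row.names = 1)
      env$scoredb <- as.matrix(sc)
      rk <- read.table(file.path(out_dir, "rankings.tsv"), header = TRUE,
                       sep = "\t", comment.char = "#", check.names = FALSE,
                       row.names = 1)
      env$rankingdb <- structure(list(ranks = as.matrix(rk),
                                      seed = NA_integer_),
                                 class = "RankingDB")
    },
    enrich = {
      flat <- as_tibble(read.table(file.path(out_dir, "enrichment.tsv"),
                                   header = TRUE, sep = "\t",
                                   comment.char = "#",
                                   stringsAsFactors = FALSE))
      flat$cistrome <- strsplit(flat$cistrome, ",", fixed = TRUE)
      env$enrichment <- flat
      env$cistromes <- merge_cistromes(flat, env$motif_annotation)
    },
    grn = {
      env$eregulons <- as_tibble(read.table(
        file.path(out_dir, "eregulons.tsv"), header = TRUE, sep = "\t",
        comment.char = "#", stringsAsFactors = FALSE))
      class(env$eregulons) <- c("eregulon_df", class(env$eregulons))
    },
    aucell = env$auc <- as.matrix(read.table(
      file.path(out_dir, "auc.tsv"), header = TRUE, sep = "\t",
      comment.char = "#", check.names = FALSE)),
    rss = invisible(NULL)
  )
}

#' Serialize a topic model to a directory
#'
#' Writes `cell_topic.tsv`, `topic_region.tsv` and `meta.json` (K, alpha,
#' beta, seed, n_iter).
#'
#' @param model A `TopicModel`.
#' @param dir Output directory.
#' @export
write_topic_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(model$cell_topic, file.path(dir, "cell_topic.tsv"),
              sep = "\t", quote = FALSE)
  write.table(model$topic_region, file.path(dir, "topic_region.tsv"),
              sep = "\t", quote = FALSE)
  jsonlite::write_json(
    list(K = model$K, alpha = model$alpha, beta = model$beta,
         seed = model$seed, n_iter = model$n_iter,
         loglik_trace = model$loglik_trace),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a topic model serialized by [write_topic_model()]
#'
#' @param dir Directory with `cell_topic.tsv`, `topic_region.tsv`,
#'   `meta.json`.
#' @return A `TopicModel` (without the token matrix).
#' @export
read_topic_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  ct <- as.matrix(read.table(file.path(dir, "cell_topic.tsv"), sep = "\t",
                             header = TRUE, check.names = FALSE))
  tr <- as.matrix(read.table(file.path(dir, "topic_region.tsv"), sep = "\t",
                             header = TRUE, check.names = FALSE))
  structure(list(K = meta$K, alpha = meta$alpha, beta = meta$beta,
                 cell_topic = ct, topic_region = tr,
                 loglik_trace = meta$loglik_trace, seed = meta$seed,
                 n_iter = meta$n_iter, tokens = NULL,
                 matrix_hash = NA_character_),
            class = "TopicModel")
}
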