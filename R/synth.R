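#' Synthetic multiome scenario parameters
#'
#' Defines a fully self-contained synthetic multiome dataset with a planted
#' TF -> region -> gene network. Each TF drives one cell type: its regions
#' are accessible and its motif occurrences are planted in their sequences,
#' and its target genes respond to the TF's activity through a saturating
#' (Hill-like) link, with the planted sign. Genes sit every 200 kb on one
#' synthetic chromosome with their regions within 50 kb upstream, so planted
#' regions fall inside their genes' search spaces under default settings;
#' target genes of different TFs alternate along the chromosome. Decoy motif
#' clusters (no planted sites) make enrichment statistics well-defined.
#'
#' @param n_cell_types Number of cell types (default 5, one per TF).
#' @param n_cells_per_type Cells per type (default 100).
#' @param n_tfs Number of TFs (default 5).
#' @param regions_per_tf Planted enhancer regions per TF (default 40).
#' @param genes_per_tf Target genes per TF (default 29; plus the TF gene
#'   itself, the default totals 150 genes).
#' @param n_background_regions Unbound background regions (default 100).
#' @param frac_negative Fraction of TF->gene edges with repressive sign
#'   (default 0.2).
#' @param dispersion Negative-binomial dispersion of expression (default
#'   0.3; 0 gives noise-free means).
#' @param dropout Per-entry probability that an accessible region yields no
#'   fragment (default 0.3).
#' @param bg_accessibility Accessibility rate of closed regions (default
#'   0.05).
#' @param region_width Region width in bp (default 500).
#' @param motif_length Planted motif length in bp (default 8).
#' @param n_decoy_motifs Decoy motif clusters (default 15).
#' @param trajectory Optional list `(n_paths, lag)`: replaces the discrete
#'   cell types with a differentiation trajectory; `lag` is the pseudotime
#'   delay of target activation after TF expression (one value or one per
#'   TF).
#' @param seed Integer seed.
#' @return A `SyntheticScenario` parameter list.
#' @export
synthetic_scenario <- function(n_cell_types = 5, n_cells_per_type = 100,
                               n_tfs = 5, regions_per_tf = 40,
                               genes_per_tf = 29,
                               n_background_regions = 100,
                               frac_negative = 0.2, dispersion = 0.3,
                               dropout = 0.3, bg_accessibility = 0.05,
                               region_width = 500, motif_length = 8,
                               n_decoy_motifs = 15, trajectory = NULL,
                               seed = 1) {
  stopifnot(n_cell_types >= 1, n_cells_per_type >= 1, n_tfs >= 1,
            regions_per_tf >= 1, genes_per_tf >= 1,
            dropout >= 0, dropout < 1, frac_negative >= 0,
            frac_negative <= 1)
  if (!is.null(trajectory)) {
    stopifnot(all(trajectory$lag >= 0))
  }
  structure(as.list(environment()), class = "SyntheticScenario")
}

# A high-information-content PFM around a random consensus.
random_pfm <- function(length, major = 0.94) {
  cons <- sample(4, length, replace = TRUE)
  m <- matrix((1 - major) / 3, 4, length)
  m[cbind(cons, seq_len(length))] <- major
  rownames(m) <- c("A", "C", "G", "T")
  m
}

sample_motif_site <- function(pfm) {
  paste(vapply(seq_len(ncol(pfm)), function(j) {
    sample(rownames(pfm), 1, prob = pfm[, j])
  }, ""), collapse = "")
}

hill <- function(a, k = 0.5, h = 2) a^h / (a^h + k^h)

#' Generate a synthetic multiome dataset with planted ground truth
#'
#' Emits, deterministically given the scenario seed: region sequences with
#' planted motif occurrences, a cells x regions accessibility count matrix,
#' a cells x genes expression count matrix (negative binomial around
#' TF-activity-driven means), cell metadata (labels and, in trajectory mode,
#' pseudotime/path/embedding), motif clusters with a TF annotation table, a
#' gene annotation, and the planted ground truth.
#'
#' @param params A [synthetic_scenario()].
#' @return A list with elements `counts_atac`, `counts_rna`, `cells`
#'   (tibble), `regions` (tibble), `genes` (annotation tibble), `sequences`
#'   (named character), `motif_clusters`, `motif_annotation`, `truth` (list
#'   with `tf_region`, `region_gene`, `tf_gene` tibbles, `motif_positions`,
#'   `cell_type_of_tf`), and `params`.
#' @export
generate_scenario <- function(params) {
  stopifnot(inherits(params, "SyntheticScenario"))
  p <- params
  if (p$genes_per_tf == 0 && p$regions_per_tf > 0) {
    stop("inconsistent params: regions planted but genes_per_tf = 0")
  }
  set.seed(p$seed)
  tfs <- paste0("TF", seq_len(p$n_tfs))
  n_targets <- p$n_tfs * p$genes_per_tf
  targets <- paste0("G", seq_len(n_targets))
  # round-robin TF assignment so neighboring genes belong to different TFs
  tf_of_target <- tfs[(seq_len(n_targets) - 1) %% p$n_tfs + 1]
  genes <- c(tfs, targets)

  # chromosome layout: one gene every 200 kb, 2 kb bodies, strand +
  gene_tbl <- tibble(
    gene = genes, chrom = "chrS", strand = "+",
    start = 100000L + (seq_along(genes) - 1L) * 200000L
  )
  gene_tbl$end <- gene_tbl$start + 2000L
  gene_tbl$tss <- gene_tbl$start

  # distribute each TF's regions over its targets (some genes get several)
  region_rows <- list()
  for (ti in seq_len(p$n_tfs)) {
    idx <- which(tf_of_target == tfs[ti])
    gene_of_region <- targets[idx][((seq_len(p$regions_per_tf) - 1) %%
                                      length(idx)) + 1]
    for (ri in seq_len(p$regions_per_tf)) {
      g <- gene_of_region[ri]
      gs <- gene_tbl$start[gene_tbl$gene == g]
      copy <- sum(vapply(region_rows, function(r) r$gene == g, TRUE))
      start <- gs - 5000L * (copy + 1L) - 2000L
      region_rows[[length(region_rows) + 1]] <- tibble(
        tf = tfs[ti], gene = g, chrom = "chrS",
        start = start, end = start + as.integer(p$region_width))
    }
  }
  planted <- dplyr::bind_rows(region_rows)
  planted$region <- region_name(planted$chrom, planted$start, planted$end)

  # background regions beyond the gene array
  bg_start <- max(gene_tbl$end) + 500000L +
    (seq_len(p$n_background_regions) - 1L) * 5000L
  background <- tibble(
    tf = NA_character_, gene = NA_character_, chrom = "chrS",
    start = bg_start, end = bg_start + as.integer(p$region_width))
  background$region <- region_name(background$chrom, background$start,
                                   background$end)
  regions <- dplyr::bind_rows(planted, background)

  # motifs: one informative cluster per TF plus decoys
  pfms <- list()
  for (ti in seq_len(p$n_tfs)) {
    pfms[[paste0("motif_", tfs[ti])]] <- random_pfm(p$motif_length)
  }
  for (d in seq_len(p$n_decoy_motifs)) {
    pfms[[paste0("motif_decoy", d)]] <- random_pfm(p$motif_length)
  }
  motif_annotation <- tibble(
    cluster_id = paste0("cluster_", c(tfs, paste0("decoy",
                                                  seq_len(p$n_decoy_motifs)))),
    motif_id = names(pfms),
    tf = c(tfs, rep(NA_character_, p$n_decoy_motifs)),
    evidence = c(rep("direct", p$n_tfs),
                 rep(NA_character_, p$n_decoy_motifs)))
  clusters <- make_motif_clusters(pfms, motif_annotation)

  # sequences: i.i.d. background with motif sites planted in bound regions
  seqs <- vapply(seq_len(nrow(regions)), function(i) {
    paste(sample(c("A", "C", "G", "T"), p$region_width, replace = TRUE),
          collapse = "")
  }, "")
  names(seqs) <- regions$region
  motif_positions <- list()
  for (i in which(!is.na(regions$tf))) {
    pfm <- pfms[[paste0("motif_", regions$tf[i])]]
    n_occ <- sample(1:2, 1)
    pos <- sort(sample(seq_len(p$region_width - p$motif_length - 1),
                       n_occ))
    # keep occurrences non-overlapping
    if (n_occ == 2 && diff(pos) < p$motif_length) pos <- pos[1]
    s <- seqs[[i]]
    for (po in pos) {
      site <- sample_motif_site(pfm)
      substr(s, po, po + p$motif_length - 1) <- site
    }
    seqs[[i]] <- s
    motif_positions[[regions$region[i]]] <- pos
  }

  # cells: discrete types or a trajectory
  n_cells <- p$n_cell_types * p$n_cells_per_type
  barcodes <- sprintf("cell%04d", seq_len(n_cells))
  if (is.null(p$trajectory)) {
    cell_type <- rep(paste0("type", seq_len(p$n_cell_types)),
                     each = p$n_cells_per_type)
    cells <- tibble(barcode = barcodes, cell_type = cell_type)
    # TF ti is active in type ti (recycled if more types than TFs)
    type_of_tf <- paste0("type", ((seq_len(p$n_tfs) - 1) %%
                                    p$n_cell_types) + 1)
    act <- vapply(seq_len(p$n_tfs), function(ti) {
      ifelse(cell_type == type_of_tf[ti], 0.9, 0.05)
    }, numeric(n_cells))
    pseudotime <- path <- NULL
  } else {
    n_paths <- p$trajectory$n_paths %||% 1
    lag <- rep(p$trajectory$lag, length.out = p$n_tfs)
    pseudotime <- sort(runif(n_cells))
    path <- paste0("path", rep_len(seq_len(n_paths), n_cells))
    cell_type <- paste0("stage", pmin(floor(pseudotime * 3) + 1, 3))
    cells <- tibble(barcode = barcodes, cell_type = cell_type,
                    pseudotime = pseudotime, path = path,
                    x = pseudotime,
                    y = as.numeric(factor(path)) / 2 + rnorm(n_cells, 0, 0.05))
    type_of_tf <- rep(NA_character_, p$n_tfs)
    # TF activity is a transient sinusoidal pulse along pseudotime (its
    # moments are invariant to the lag shift, so standardized curves of TF
    # and lagged targets are exact time-shifted copies); targets follow
    # after the planted lag
    act <- vapply(seq_len(p$n_tfs), function(ti) {
      0.5 + 0.5 * sin(2 * pi * (pseudotime - 0.25))
    }, numeric(n_cells))
    attr(act, "lag") <- lag
  }
  colnames(act) <- tfs

  # accessibility: bound regions open with the TF's activity, minus dropout
  open_prob <- matrix(p$bg_accessibility, n_cells, nrow(regions))
  for (i in which(!is.na(regions$tf))) {
    a <- act[, regions$tf[i]]
    open_prob[, i] <- pmax(p$bg_accessibility, a * (1 - p$dropout))
  }
  if (p$dropout == 0 && p$dispersion == 0) {
    counts_atac <- matrix(as.integer(open_prob >= 0.5), n_cells,
                          nrow(regions))
  } else {
    counts_atac <- matrix(rbinom(length(open_prob), 1, open_prob),
                          n_cells, nrow(regions))
  }
  dimnames(counts_atac) <- list(barcodes, regions$region)

  # expression: NB around activity-driven means with the planted sign
  sign_of <- setNames(rep("+", n_targets), targets)
  n_neg <- round(p$frac_negative * n_targets)
  if (n_neg > 0) {
    neg_targets <- unlist(lapply(tfs, function(tf) {
      own <- targets[tf_of_target == tf]
      sample(own, round(p$frac_negative * length(own)))
    }))
    sign_of[neg_targets] <- "-"
  }
  lagged_act <- function(tf_i) {
    if (is.null(p$trajectory)) return(act[, tf_i])
    lag <- attr(act, "lag")[match(tf_i, tfs)]
    0.5 + 0.5 * sin(2 * pi * (pseudotime - lag - 0.25))
  }
  mu <- matrix(0, n_cells, length(genes),
               dimnames = list(barcodes, genes))
  for (tf in tfs) mu[, tf] <- 1 + 60 * act[, tf]
  for (g in targets) {
    tf <- tf_of_target[match(g, targets)]
    h <- hill(lagged_act(tf))
    mu[, g] <- if (sign_of[g] == "+") 2 + 60 * h else 2 + 60 * (1 - h)
  }
  counts_rna <- if (p$dispersion == 0) {
    round(mu)
  } else {
    matrix(rnbinom(length(mu), mu = mu, size = 1 / p$dispersion),
           n_cells, length(genes), dimnames = dimnames(mu))
  }

  truth <- list(
    tf_region = planted[, c("tf", "region")],
    region_gene = planted[, c("region", "gene")],
    tf_gene = tibble(tf = tf_of_target, gene = targets,
                     sign = unname(sign_of[targets])),
    motif_positions = motif_positions,
    cell_type_of_tf = setNames(type_of_tf, tfs))

  list(counts_atac = counts_atac, counts_rna = counts_rna, cells = cells,
       regions = regions[, c("chrom", "start", "end", "region", "tf")],
       genes = gene_tbl[, c("gene", "chrom", "strand", "tss", "start",
                            "end")],
       sequences = seqs, motif_clusters = clusters,
       motif_annotation = motif_annotation, truth = truth, params = p)
}

#' Write a generated scenario to disk
#'
#' Emits `regions.fa`, `counts_atac/` and `counts_rna/` (MatrixMarket +
#' sidecars), `cells.tsv`, `genes.tsv`, `regions.bed`, `motifs/` (one
#' JASPAR-style file per cluster), `motif_annotation.tsv` and `truth.json`.
#'
#' @param scenario Output of [generate_scenario()].
#' @param dir Output directory.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- Biostrings::DNAStringSet(scenario$sequences)
  Biostrings::writeXStringSet(seqs, file.path(dir, "regions.fa"))
  write_count_matrix(scenario$counts_atac, file.path(dir, "counts_atac"))
  write_count_matrix(scenario$counts_rna, file.path(dir, "counts_rna"))
  write.table(scenario$cells, file.path(dir, "cells.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(scenario$genes, file.path(dir, "genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_bed(scenario$regions, file.path(dir, "regions.bed"))
  mdir <- file.path(dir, "motifs")
  dir.create(mdir, showWarnings = FALSE)
  for (cl in scenario$motif_clusters) {
    lines <- unlist(lapply(names(cl$members), function(id) {
      m <- cl$members[[id]]
      c(paste0(">", id),
        vapply(1:4, function(b) {
          paste0(rownames(m)[b], " [ ",
                 paste(sprintf("%.4f", m[b, ]), collapse = " "), " ]")
        }, ""))
    }))
    writeLines(lines, file.path(mdir, paste0(cl$id, ".jaspar")))
  }
  write.table(scenario$motif_annotation,
              file.path(dir, "motif_annotation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- scenario$truth
  jsonlite::write_json(
    list(tf_region = truth$tf_region, region_gene = truth$region_gene,
         tf_gene = truth$tf_gene, motif_positions = truth$motif_positions,
         cell_type_of_tf = as.list(truth$cell_type_of_tf)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Score inferred eRegulons against the planted ground truth
#'
#' Set-overlap precision/recall/F1 of the inferred activator TF -> gene and
#' TF -> region edge sets against the planted positive edges, pooled and per
#' TF.
#'
#' @param eregulons An `eregulon_df` (or tibble with `tf`, `gene`, `region`,
#'   `tf_sign`).
#' @param truth Ground-truth list from [generate_scenario()].
#' @return Tibble with `level` (`tf_gene`/`tf_region`), `tf` (`"pooled"` or
#'   a TF), `precision`, `recall`, `f1`, `n_inferred`, `n_true`.
#' @export
score_recovery <- function(eregulons, truth) {
  act <- eregulons[eregulons$tf_sign == "+", ]
  inferred_tg <- unique(paste(act$tf, act$gene))
  inferred_tr <- unique(paste(act$tf, act$region))
  true_tg <- with(truth$tf_gene[truth$tf_gene$sign == "+", ],
                  paste(tf, gene))
  true_tr <- with(dplyr::inner_join(truth$tf_region, truth$region_gene,
                                    by = "region"),
                  unique(paste(tf, region)))
  prf <- function(inf, tru) {
    tp <- length(intersect(inf, tru))
    precision <- if (length(inf)) tp / length(inf) else 0
    recall <- if (length(tru)) tp / length(tru) else 0
    f1 <- if (precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else 0
    tibble(precision = precision, recall = recall, f1 = f1,
           n_inferred = length(inf), n_true = length(tru))
  }
  pooled <- dplyr::bind_rows(
    dplyr::mutate(prf(inferred_tg, true_tg), level = "tf_gene",
                  tf = "pooled"),
    dplyr::mutate(prf(inferred_tr, true_tr), level = "tf_region",
                  tf = "pooled"))
  per_tf <- purrr::map_dfr(unique(truth$tf_region$tf), function(tf) {
    dplyr::bind_rows(
      dplyr::mutate(prf(grep(paste0("^", tf, " "), inferred_tg, value = TRUE),
                        grep(paste0("^", tf, " "), true_tg, value = TRUE)),
                    level = "tf_gene", tf = tf),
      dplyr::mutate(prf(grep(paste0("^", tf, " "), inferred_tr, value = TRUE),
                        grep(paste0("^", tf, " "), true_tr, value = TRUE)),
                    level = "tf_region", tf = tf))
  })
  dplyr::bind_rows(pooled, per_tf)[, c("level", "tf", "precision", "recall",
                                       "f1", "n_inferred", "n_true")]
}
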