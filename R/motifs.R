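#' Construct a motif cluster
#'
#' A motif cluster is a set of position frequency matrices (PFMs, per-position
#' base probabilities) scored jointly: a region's cluster score is the best
#' hit over all members, strands and offsets. TF annotations carry an
#' evidence class (`direct` beats `orthology`).
#'
#' @param id Cluster identifier.
#' @param members List of 4 x L matrices (rows A, C, G, T; columns sum to 1).
#' @param tf_annotations Tibble with columns `tf`, `evidence`
#'   (`"direct"`/`"orthology"`), possibly empty.
#' @return A `MotifCluster` object.
#' @export
motif_cluster <- function(id, members,
                          tf_annotations = tibble(tf = character(),
                                                  evidence = character())) {
  stopifnot(length(members) >= 1)
  members <- lapply(members, function(m) {
    m <- as.matrix(m)
    if (nrow(m) != 4) stop("PFM must have 4 rows (A, C, G, T)")
    rownames(m) <- c("A", "C", "G", "T")
    cs <- colSums(m)
    if (any(abs(cs - 1) > 1e-6)) m <- sweep(m, 2, cs, "/")
    m
  })
  structure(list(id = id, members = members,
                 tf_annotations = as_tibble(tf_annotations)),
            class = "MotifCluster")
}

#' Read position frequency matrices from JASPAR-style text
#'
#' Accepts the JASPAR layout: a `>ID` header followed by four rows
#' `A [ counts ]`, `C [...]`, `G [...]`, `T [...]` (brackets optional), or
#' four bare numeric rows in A/C/G/T order.
#'
#' @param path Path to the motif text file.
#' @return Named list of 4 x L probability matrices.
#' @export
read_jaspar <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  if (length(starts) == 0) stop("no motif headers ('>') found in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  out <- list()
  for (i in seq_along(starts)) {
    id <- sub("^>\\s*", "", lines[starts[i]])
    id <- strsplit(id, "\\s+")[[1]][1]
    body <- lines[(starts[i] + 1L):ends[i]]
    rows <- lapply(body, function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", l)
      l <- gsub("[][]", " ", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    if (length(rows) != 4) stop("motif ", id, " does not have 4 base rows")
    m <- do.call(rbind, rows)
    rownames(m) <- c("A", "C", "G", "T")
    m <- sweep(m, 2, colSums(m), "/")
    out[[id]] <- m
  }
  out
}

#' Read Cluster-Buster (.cb) motif files
#'
#' The .cb layout is a `>ID` header followed by one row per motif position
#' with four counts in A, C, G, T column order.
#'
#' @param path Path to the .cb file.
#' @return Named list of 4 x L probability matrices.
#' @export
read_cb <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  starts <- grep("^>", lines)
  if (length(starts) == 0) stop("no motif headers ('>') found in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  out <- list()
  for (i in seq_along(starts)) {
    id <- strsplit(sub("^>\\s*", "", lines[starts[i]]), "\\s+")[[1]][1]
    body <- lines[(starts[i] + 1L):ends[i]]
    m <- t(vapply(body, function(l) {
      as.numeric(strsplit(l, "\\s+")[[1]][1:4])
    }, numeric(4)))
    m <- t(m)  # 4 x L, rows A C G T
    rownames(m) <- c("A", "C", "G", "T")
    m <- sweep(m, 2, colSums(m), "/")
    out[[id]] <- m
  }
  out
}

#' Read a motif cluster annotation table
#'
#' TSV with header columns `cluster_id`, `motif_id`, `tf`, `evidence`.
#'
#' @param path Path to the TSV.
#' @return Tibble.
#' @export
read_motif_annotation <- function(path) {
  df <- as_tibble(read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE))
  need <- c("cluster_id", "motif_id", "tf", "evidence")
  if (!all(need %in% names(df))) {
    stop("motif annotation needs columns: ", paste(need, collapse = ", "))
  }
  df
}

#' Assemble motif clusters from PFMs and an annotation table
#'
#' @param pfms Named list of PFMs (names are motif ids).
#' @param annotation Tibble with `cluster_id`, `motif_id`, `tf`, `evidence`.
#' @return Named list of [motif_cluster()] objects.
#' @export
make_motif_clusters <- function(pfms, annotation) {
  split_ann <- split(annotation, annotation$cluster_id)
  lapply(split_ann, function(a) {
    ids <- unique(a$motif_id)
    missing <- setdiff(ids, names(pfms))
    if (length(missing)) stop("PFM missing for motif(s): ",
                              paste(missing, collapse = ", "))
    tfs <- dplyr::distinct(a[!is.na(a$tf) & nzchar(a$tf), ],
                           .data$tf, .data$evidence)
    motif_cluster(a$cluster_id[1], pfms[ids], tfs)
  })
}

# log2-odds matrix of a PFM against background, with pseudocount.
pfm_log_odds <- function(pfm, background, pseudocount = 1e-4) {
  p <- (pfm + pseudocount) / (1 + 4 * pseudocount)
  log2(p) - log2(background)
}

revcomp_matrix <- function(m) {
  m[4:1, ncol(m):1, drop = FALSE]
}

encode_seq <- function(s) {
  v <- strsplit(toupper(s), "")[[1]]
  code <- match(v, c("A", "C", "G", "T")) - 1L
  code[is.na(code)] <- 4L
  code
}

#' Score regions with a motif cluster (best-hit log-odds CRM score)
#'
#' Each region's score is the maximum, over cluster members, strands and
#' offsets, of the summed log2 odds of the PFM (with a 1e-4 pseudocount)
#' against the background base composition, floored at 0. `N` positions
#' contribute odds 1 (zero log-odds). This is a self-contained cis-regulatory
#' module score that is monotone in motif match quality.
#'
#' @param cluster A `MotifCluster`.
#' @param sequences Named character vector or
#'   [Biostrings::DNAStringSet-class] of region sequences (names are region
#'   names).
#' @param regions Region names to score (default: all sequences).
#' @param background Base frequencies over A, C, G, T (default uniform).
#' @return Named numeric vector of scores (>= 0), one per region.
#' @export
score_regions <- function(cluster, sequences, regions = NULL,
                          background = rep(0.25, 4)) {
  if (is(sequences, "DNAStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  if (is.null(regions)) regions <- names(sequences)
  missing <- setdiff(regions, names(sequences))
  if (length(missing)) {
    stop("region(s) absent from FASTA: ", paste(head(missing, 3),
                                                collapse = ", "))
  }
  lo <- unlist(lapply(cluster$members, function(m) {
    fwd <- pfm_log_odds(m, background)
    list(fwd, revcomp_matrix(fwd))
  }), recursive = FALSE)
  scores <- vapply(regions, function(r) {
    max(scan_best_hit_cpp(encode_seq(sequences[[r]]), lo), 0)
  }, 0)
  setNames(scores, regions)
}

#' Build a region x cluster CRM score database
#'
#' @param clusters Named list of `MotifCluster` objects.
#' @param sequences Named sequences (see [score_regions()]).
#' @param background Base frequencies (default uniform).
#' @return A `ScoreDB`: regions x clusters numeric matrix with attribute
#'   `background`.
#' @export
build_score_db <- function(clusters, sequences, background = rep(0.25, 4)) {
  if (is(sequences, "DNAStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  ids <- vapply(clusters, function(cl) cl$id, "")
  m <- vapply(clusters, function(cl) {
    score_regions(cl, sequences, background = background)
  }, numeric(length(sequences)))
  dimnames(m) <- list(names(sequences), ids)
  structure(m, background = background, class = c("ScoreDB", class(m)))
}

#' Rank regions per motif cluster
#'
#' Regions are ordered by descending CRM score within each cluster; ties
#' (notably the zero floor) are broken by a seeded shuffle so that every
#' column is a full permutation. Rank 1 is the best-scoring region.
#'
#' @param scoredb Regions x clusters score matrix.
#' @param seed Integer seed for the tie-breaking shuffle.
#' @return A `RankingDB`: list with `ranks` (regions x clusters integer
#'   matrix, each column a permutation of `1..N`) and `seed`.
#' @export
build_ranking_db <- function(scoredb, seed = 1) {
  if (any(!is.finite(scoredb))) stop("scores must be finite")
  set.seed(seed)
  n <- nrow(scoredb)
  ranks <- apply(scoredb, 2, function(s) {
    key <- runif(n)
    ord <- order(-s, key)
    r <- integer(n)
    r[ord] <- seq_len(n)
    r
  })
  rownames(ranks) <- rownames(scoredb)
  structure(list(ranks = ranks, seed = as.integer(seed)), class = "RankingDB")
}
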