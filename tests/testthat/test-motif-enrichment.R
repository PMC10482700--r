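toy_pfm <- function(consensus) {
  idx <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
  m <- matrix(0.02, 4, length(idx))
  m[cbind(idx, seq_along(idx))] <- 0.94
  rownames(m) <- c("A", "C", "G", "T")
  m
}

test_that("CRM score has the closed form on a consensus sequence", {
  pfm <- toy_pfm("ACGTAC")
  cl <- motif_cluster("m1", list(pfm))
  sc <- score_regions(cl, c(r1 = "ACGTAC"))
  want <- 6 * (log2((0.94 + 1e-4) / (1 + 4e-4)) - log2(0.25))
  expect_equal(unname(sc), want, tolerance = 1e-10)

  # all-N sequence scores 0
  expect_equal(unname(score_regions(cl, c(r1 = "NNNNNNNN"))), 0)

  # reverse-complement strand is found
  sc_rc <- score_regions(cl, c(r1 = "GTACGT"))
  expect_equal(unname(sc_rc), want, tolerance = 1e-10)

  expect_error(score_regions(cl, c(r1 = "ACGTAC"), regions = "r9"),
               "absent")
})

test_that("CRM scoring equals the brute-force scan oracle", {
  set.seed(20)
  cl <- motif_cluster("m", list(toy_pfm("ACGTTGCA"), toy_pfm("GGATCC")))
  seqs <- vapply(1:30, function(i) {
    paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
          collapse = "")
  }, "")
  names(seqs) <- paste0("r", 1:30)
  got <- score_regions(cl, seqs)
  want <- vapply(seqs, oracle_pwm_scan, 0, pfms = cl$members)
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("ranking database is a seeded permutation with stable ties", {
  sc <- cbind(m1 = c(5, 4, 3, 2, 1), m2 = rep(0, 5))
  rownames(sc) <- paste0("r", 1:5)
  db <- build_ranking_db(sc, seed = 1)
  expect_equal(unname(db$ranks[, "m1"]), 1:5)
  expect_true(all(apply(db$ranks, 2, sort) == 1:5))

  # all-equal scores: same seed reproduces, different seed permutes
  db2 <- build_ranking_db(sc, seed = 1)
  expect_identical(db$ranks, db2$ranks)
  db3 <- build_ranking_db(sc, seed = 2)
  expect_false(identical(db$ranks[, "m2"], db3$ranks[, "m2"]))

  # mixed ties: top stratum ordered before the tied zero floor
  sc2 <- cbind(m = c(3, 3, 0, 0, 5))
  rownames(sc2) <- paste0("r", 1:5)
  r <- build_ranking_db(sc2, seed = 3)$ranks[, 1]
  expect_equal(unname(r["r5"]), 1)
  expect_setequal(unname(r[c("r1", "r2")]), 2:3)
  expect_setequal(unname(r[c("r3", "r4")]), 4:5)
})

test_that("cistarget matches a literal transcription oracle", {
  set.seed(30)
  n <- 100
  scores <- matrix(runif(n * 20), n, 20,
                   dimnames = list(paste0("r", 1:n), paste0("m", 1:20)))
  # make cluster m1 enrich the region set
  region_set <- paste0("r", 1:10)
  scores[region_set, "m1"] <- scores[region_set, "m1"] + 5
  db <- build_ranking_db(scores, seed = 5)
  res <- cistarget(region_set, db, auc_fraction = 0.1,
                   nes_threshold = 3, rank_at_max_fraction = 0.25)
  orc <- oracle_cistarget(region_set, db$ranks, 0.1, 0.25)
  all_tbl <- attr(res, "all_clusters")
  expect_equal(all_tbl$auc, unname(orc$auc), tolerance = 1e-12)
  expect_equal(all_tbl$nes, unname(orc$nes), tolerance = 1e-12)
  expect_equal(all_tbl$rank_at_max, unname(unlist(orc$rank_at_max)))
  expect_true("m1" %in% res$motif_cluster)
  expect_setequal(res$cistrome[[which(res$motif_cluster == "m1")]],
                  orc$leading$m1)

  # perfect recovery attains the maximal AUC across clusters
  expect_equal(which.max(all_tbl$auc), 1L)
  # leading edge is always a subset of the region set
  expect_true(all(unlist(res$cistrome) %in% region_set))
  # NES standardization across clusters
  expect_equal(mean(all_tbl$nes), 0, tolerance = 1e-12)
  expect_equal(sd(all_tbl$nes), 1, tolerance = 1e-12)

  expect_error(cistarget(character(), db), "empty")
  expect_error(cistarget("not_a_region", db), "not in ranking")
})

test_that("cistarget keeps exactly the clusters above the NES threshold", {
  set.seed(31)
  scores <- matrix(runif(3000), 150, 20,
                   dimnames = list(paste0("r", 1:150), paste0("m", 1:20)))
  scores[paste0("r", 1:12), "m7"] <- scores[paste0("r", 1:12), "m7"] + 9
  db <- build_ranking_db(scores, seed = 2)
  res <- cistarget(paste0("r", 1:12), db, auc_fraction = 0.1)
  all_tbl <- attr(res, "all_clusters")
  expect_setequal(res$motif_cluster,
                  all_tbl$motif_cluster[all_tbl$nes > 3.0])
  # boundary: a cluster at NES 2.9 would be absent, 3.1 present
  expect_true(all(res$nes > 3.0))
  expect_false(any(all_tbl$nes[!all_tbl$motif_cluster %in%
                                 res$motif_cluster] > 3.0))
})

test_that("DEM keeps differential clusters and builds CRM cistromes", {
  set.seed(40)
  n_fg <- 30; n_bg <- 30
  regions <- paste0("r", 1:(n_fg + n_bg))
  fg <- regions[1:n_fg]; bg <- regions[(n_fg + 1):(n_fg + n_bg)]
  sc <- cbind(hit = c(rep(5, n_fg), rep(0, n_bg)),
              flat = runif(n_fg + n_bg))
  rownames(sc) <- regions
  res <- dem(list(c1 = fg), list(c1 = bg), sc)
  expect_equal(res$motif_cluster, "hit")
  expect_setequal(res$cistrome[[1]], fg)  # all fg scores exceed CRM > 3

  # identical score distributions: logFC 0, not kept
  sc2 <- cbind(same = rep(2, 60))
  rownames(sc2) <- regions
  expect_equal(nrow(dem(list(c1 = fg), list(c1 = bg), sc2)), 0)

  # exact-oracle agreement on a tie-free 10 vs 10 toy
  set.seed(41)
  x <- rnorm(10); y <- rnorm(10) + 1.2
  sc3 <- cbind(m = c(x, y) + 10)
  rownames(sc3) <- paste0("q", 1:20)
  res3 <- dem(list(c = paste0("q", 11:20)), list(c = paste0("q", 1:10)),
              sc3, adj_p_max = 1.1, logfc_min = -10)
  expect_lt(abs(res3$p_value - oracle_wilcox_exact(y + 10, x + 10)), 1e-6)

  # Bonferroni: adjusted p = p * number of clusters, capped at 1
  sc4 <- cbind(a = c(rep(4, 30), rep(0, 30)), b = runif(60), d = runif(60))
  rownames(sc4) <- regions
  res4 <- dem(list(c = fg), list(c = bg), sc4, adj_p_max = 1.1,
              logfc_min = -10)
  expect_equal(res4$adj_p_value, pmin(res4$p_value * 3, 1))

  expect_error(dem(list(c = fg), list(c = character()), sc), "empty")
  expect_error(dem(list(c = fg), list(c = fg), sc), "overlap")
})

test_that("cistromes merge per TF with strongest evidence", {
  res <- tibble::tibble(
    motif_cluster = c("c1", "c2", "c3"),
    cistrome = list(c("a", "b"), c("b", "c"), c("z")))
  ann <- tibble::tibble(
    cluster_id = c("c1", "c2", "c3"),
    tf = c("X", "X", NA),
    evidence = c("orthology", "direct", NA))
  out <- merge_cistromes(res, ann)
  expect_equal(nrow(out), 1)
  expect_setequal(out$regions[[1]], c("a", "b", "c"))
  expect_equal(out$evidence, "direct")

  # unannotated cluster contributes nothing
  expect_false("z" %in% unlist(out$regions))
})

test_that("motif files round-trip through the JASPAR and cb readers", {
  pfm <- toy_pfm("ACGT")
  jf <- tempfile(fileext = ".jaspar")
  writeLines(c(">mot1",
               paste0("A [ ", paste(pfm[1, ], collapse = " "), " ]"),
               paste0("C [ ", paste(pfm[2, ], collapse = " "), " ]"),
               paste0("G [ ", paste(pfm[3, ], collapse = " "), " ]"),
               paste0("T [ ", paste(pfm[4, ], collapse = " "), " ]")), jf)
  got <- read_jaspar(jf)
  expect_equal(got$mot1, pfm, ignore_attr = TRUE, tolerance = 1e-9)

  cb <- tempfile(fileext = ".cb")
  writeLines(c(">mot2", apply(t(pfm), 1, paste, collapse = "\t")), cb)
  got2 <- read_cb(cb)
  expect_equal(got2$mot2, pfm, ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("promoter exclusion removes TSS-proximal regions", {
  ann <- tibble::tibble(gene = "g", chrom = "chr1", strand = "+",
                        tss = 1000, start = 1000, end = 3000)
  regs <- c("chr1:900-1100", "chr1:5000-5200")
  expect_equal(exclude_promoters(regs, ann, flank = 500),
               "chr1:5000-5200")
})
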