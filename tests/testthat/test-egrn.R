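test_that("metacells: identity mode, constancy and determinism", {
  set.seed(1)
  expr <- matrix(rpois(300, 5), 30, 10,
                 dimnames = list(paste0("c", 1:30), paste0("g", 1:10)))
  acc <- matrix(runif(150), 30, 5,
                dimnames = list(paste0("c", 1:30), paste0("r", 1:5)))
  lab <- setNames(rep(c("A", "B"), each = 15), rownames(expr))

  id <- make_metacells(expr, acc, lab, mode = "identity")
  expect_equal(id$expression, expr)
  expect_equal(id$accessibility, acc)
  expect_equal(id$k_cells, 1L)

  # constant expression within a type averages to that constant
  expr_const <- expr; expr_const[1:15, ] <- 3
  mc <- make_metacells(expr_const, acc, lab, n_metacells_per_type = 4,
                       k_cells = 5, seed = 2)
  a_rows <- mc$labels$metacell[mc$labels$cell_type == "A"]
  expect_true(all(mc$expression[a_rows, ] == 3))

  # seeded determinism
  mc2 <- make_metacells(expr, acc, lab, n_metacells_per_type = 4,
                        k_cells = 5, seed = 2)
  mc3 <- make_metacells(expr, acc, lab, n_metacells_per_type = 4,
                        k_cells = 5, seed = 2)
  mc4 <- make_metacells(expr, acc, lab, n_metacells_per_type = 4,
                        k_cells = 5, seed = 3)
  expect_identical(mc2$expression, mc3$expression)
  expect_false(identical(mc2$expression, mc4$expression))

  expect_error(make_metacells(expr, acc, lab, k_cells = 20, seed = 1),
               "fewer than k_cells")
})

test_that("search space applies the window, promoter and minimum rules", {
  regions <- tibble::tibble(
    chrom = "chr1",
    start = c(50000, 340000, 399500, 710000),
    end = c(50500, 340500, 400000, 710500))
  # isolated gene: full 150 kb window on both sides
  iso <- tibble::tibble(gene = "iso", chrom = "chr1", strand = "+",
                        tss = 200000, start = 200000, end = 202000)
  sp <- define_search_space(iso, regions)
  expect_setequal(sp$region[sp$gene == "iso"],
                  c("chr1:50000-50500", "chr1:340000-340500"))

  # neighbor promoter 40 kb upstream clips the window at its TSS - 10
  ann <- dplyr::bind_rows(
    iso,
    tibble::tibble(gene = "nb", chrom = "chr1", strand = "+",
                   tss = 160000, start = 160000, end = 162000))
  sp2 <- define_search_space(ann, tibble::tibble(
    chrom = "chr1", start = c(159000, 160500), end = c(159400, 160900)))
  # region left of nb's promoter is outside iso's window; right is inside
  expect_false("chr1:159000-159400" %in% sp2$region[sp2$gene == "iso"])
  expect_true("chr1:160500-160900" %in% sp2$region[sp2$gene == "iso"])

  # neighbor promoter 300 bp upstream: the 1 kb minimum dominates
  ann3 <- dplyr::bind_rows(
    iso,
    tibble::tibble(gene = "close", chrom = "chr1", strand = "+",
                   tss = 199700, start = 199700, end = 199900))
  sp3 <- define_search_space(ann3, tibble::tibble(
    chrom = "chr1", start = 199100, end = 199300))
  expect_true("chr1:199100-199300" %in% sp3$region[sp3$gene == "iso"])

  # regions on unknown chromosomes are left unassigned
  expect_message(
    sp4 <- define_search_space(iso, tibble::tibble(
      chrom = "chrUn", start = 1, end = 100)),
    "unassigned")
  expect_equal(nrow(sp4), 0)
})

test_that("TF-gene importances find a planted dependency and sign it", {
  set.seed(3)
  n <- 300
  tf1 <- rpois(n, 20); tf2 <- rpois(n, 20)
  target <- 2 * tf1 + rnorm(n, 0, 0.01)
  expr <- cbind(TF1 = tf1, TF2 = tf2, G1 = target,
                G2 = rpois(n, 10))
  rownames(expr) <- paste0("c", 1:n)
  tbl <- tf_gene_importance(expr, c("TF1", "TF2"), seed = 1, n_trees = 100)
  g1 <- tbl[tbl$target == "G1", ]
  expect_equal(g1$tf[which.max(g1$importance)], "TF1")
  expect_equal(g1$sign[g1$tf == "TF1"], "+")

  # the self row carries max importance over targets + 1e-5
  self1 <- tbl[tbl$tf == "TF1" & tbl$target == "TF1", ]
  others <- tbl[tbl$tf == "TF1" & tbl$target != "TF1", ]
  expect_equal(self1$importance, max(others$importance) + 1e-5)

  # sign thresholds at +/- 0.03
  expect_true(all(tbl$sign[tbl$rho > 0.03] == "+"))
  expect_true(all(tbl$sign[tbl$rho < -0.03] == "-"))
  expect_true(all(tbl$sign[abs(tbl$rho) <= 0.03] == "none"))

  # zero-variance target gets zero importances and sign none
  expr0 <- cbind(expr, G0 = rep(5, n))
  tbl0 <- tf_gene_importance(expr0, c("TF1", "TF2"), seed = 1, n_trees = 50)
  g0 <- tbl0[tbl0$target == "G0", ]
  expect_true(all(g0$importance == 0))
  expect_true(all(g0$sign == "none"))
})

test_that("region-gene importances recover a planted region; nulls unsigned", {
  set.seed(4)
  n <- 200
  acc <- matrix(runif(n * 6), n, 6,
                dimnames = list(paste0("c", 1:n), paste0("chr1:", 1:6 * 1000,
                                                         "-", 1:6 * 1000 + 500)))
  expr <- cbind(G1 = 3 * acc[, 1] + rnorm(n, 0, 0.01))
  rownames(expr) <- rownames(acc)
  space <- tibble::tibble(gene = "G1", region = colnames(acc), distance = 0)
  tbl <- region_gene_importance(acc, expr, space, seed = 1, n_trees = 100)
  expect_equal(tbl$region[which.max(tbl$importance)], colnames(acc)[1])
  expect_equal(tbl$sign[which.max(tbl$importance)], "+")

  # decoupled accessibility: null correlations stay small, so no region
  # approaches the planted one (the +/-0.03 sign gate admits null noise at
  # this sample size by construction, |rho| ~ 1/sqrt(n))
  expr_null <- cbind(G1 = rnorm(n))
  rownames(expr_null) <- rownames(acc)
  tbl_null <- region_gene_importance(acc, expr_null, space, seed = 1,
                                     n_trees = 50)
  expect_lt(max(abs(tbl_null$rho)), 0.3)
  expect_true(all(tbl_null$sign[abs(tbl_null$rho) <= 0.03] == "none"))
})

test_that("region-gene binarization variants and BASC breakpoints", {
  set.seed(5)
  tbl <- tibble::tibble(
    region = paste0("r", 1:100),
    target = rep(paste0("g", 1:5), each = 20),
    importance = runif(100),
    rho = 0.5, sign = "+")
  b <- binarize_region_gene(tbl)
  q90 <- b[b$variant == "quantile_0.9", ]
  expect_equal(nrow(q90), 10)
  expect_setequal(q90$region,
                  tbl$region[order(-tbl$importance)][1:10])
  top5 <- b[b$variant == "top_5", ]
  expect_equal(as.integer(table(top5$target)), rep(5L, 5))

  # negative links never enter
  tbl$sign[1] <- "-"
  b2 <- binarize_region_gene(tbl)
  expect_false("r1" %in% b2$region)
  expect_equal(attr(b2, "negatives")$region, "r1")

  # BASC on (9,9,8,1,1,1): threshold after the third element
  expect_equal(basc_breakpoint(c(9, 9, 8, 1, 1, 1)), 3)
  for (i in 1:20) {
    v <- sort(round(runif(sample(3:10, 1), 0, 10), 2), decreasing = TRUE)
    expect_equal(basc_breakpoint(v), oracle_basc(v))
  }
})

test_that("GSEA running sum matches the literal oracle", {
  set.seed(6)
  ranked <- paste0("g", 1:20)
  weights <- sort(runif(20, 0.1, 5), decreasing = TRUE)
  cand <- c("g1", "g2", "g4", "g9", "g13", "g18")
  got <- gsea_running_sum(ranked, weights, cand)
  orc <- oracle_gsea(ranked, weights, cand)
  expect_equal(got$es, orc$es, tolerance = 1e-12)
  expect_setequal(got$leading_edge, orc$leading_edge)

  # candidates at the top: leading edge is the whole set, ES maximal
  top <- gsea_running_sum(ranked, weights, paste0("g", 1:6))
  expect_setequal(top$leading_edge, paste0("g", 1:6))
  expect_gt(top$es, got$es)

  # leading edge is a prefix-intersection of the ranking
  le_ranks <- match(got$leading_edge, ranked)
  expect_true(all(le_ranks <= got$rank_at_max))

  # independent cross-check against fgsea's running-sum statistic
  skip_if_not_installed("fgsea")
  fg <- fgsea::calcGseaStat(setNames(weights, ranked),
                            selectedStats = match(cand, ranked),
                            gseaParam = 1, returnLeadingEdge = TRUE)
  expect_equal(got$es, fg$res, tolerance = 1e-8)
  expect_setequal(got$leading_edge, ranked[fg$leadingEdge])
})

test_that("eRegulon assembly respects cistromes, strata and the size floor", {
  set.seed(7)
  genes <- paste0("g", 1:30)
  cistromes <- tibble::tibble(
    tf = "TFX", evidence = "direct",
    regions = list(paste0("r", 1:15)), n_regions = 15,
    clusters = list("c1"))
  links <- tibble::tibble(
    variant = "top_5",
    region = paste0("r", 1:15),
    target = genes[1:15],
    importance = runif(15, 1, 2), rho = 0.6)
  tf_gene <- tibble::tibble(
    tf = "TFX", target = genes,
    importance = c(sort(runif(15, 5, 10), decreasing = TRUE),
                   runif(15, 0, 0.1)),
    rho = c(rep(0.9, 15), rep(0, 15)),
    sign = c(rep("+", 15), rep("none", 15)))
  er <- build_eregulons(cistromes, links, tf_gene, min_genes = 10)
  expect_s3_class(er, "eregulon_df")
  expect_true(all(er$tf_sign == "+"))
  # candidates occupy the top of the ranking: all 15 retained
  expect_equal(dplyr::n_distinct(er$gene), 15)
  expect_true(all(er$region %in% cistromes$regions[[1]]))

  # below the floor: dropped
  er2 <- build_eregulons(cistromes, links[1:5, ], tf_gene, min_genes = 10)
  expect_equal(nrow(er2), 0)

  # interleaved candidates yield a small leading edge, dropped at the floor
  tf_gene_flat <- tf_gene
  tf_gene_flat$importance <- rev(seq_len(30))
  tf_gene_flat$sign <- "+"
  links_spread <- links
  links_spread$target <- genes[seq(2, 30, by = 2)]
  er3 <- build_eregulons(cistromes, links_spread, tf_gene_flat,
                         min_genes = 10)
  expect_lte(if (nrow(er3)) dplyr::n_distinct(er3$gene) else 0, 15)
})

test_that("AUCell is a normalized recovery AUC with rank invariance", {
  set.seed(8)
  n_feat <- 50
  vals <- matrix(runif(2 * n_feat), 2, n_feat,
                 dimnames = list(c("c1", "c2"), paste0("f", 1:n_feat)))
  # signature occupying the top of cell 1's ranking
  top_idx <- order(-vals[1, ])[1:2]
  sig <- list(s = colnames(vals)[top_idx])
  auc <- aucell(vals, sig, top_fraction = 0.1, seed = 1)
  expect_equal(auc["c1", "s"], 1)

  # signature entirely below the cut-off scores 0
  bottom <- list(s = colnames(vals)[order(vals[1, ])[1:3]])
  auc0 <- aucell(vals, bottom, top_fraction = 0.05, seed = 1)
  expect_equal(auc0["c1", "s"], 0)

  # step-function oracle at known ranks
  sig5 <- list(s = colnames(vals)[order(-vals[2, ])[c(1, 3, 7, 20, 40)]])
  auc5 <- aucell(vals, sig5, top_fraction = 0.2, seed = 1)
  expect_equal(auc5["c2", "s"],
               oracle_recovery_auc(c(1, 3, 7, 20, 40), n_feat, 0.2))

  # invariant under monotone transforms of the values
  auc_exp <- aucell(exp(vals * 3), sig5, top_fraction = 0.2, seed = 1)
  expect_equal(auc5, auc_exp)

  expect_error(aucell(vals, list(s = character())), "empty signature")
  expect_true(all(auc5 >= 0 & auc5 <= 1))
})

test_that("RSS follows the 1 - sqrt(JSD) formula and its invariances", {
  labels <- setNames(rep(c("T", "U"), each = 10), paste0("c", 1:20))
  # enrichment confined to type T gives RSS(T) = 1
  a <- matrix(c(rep(1, 10), rep(0, 10)), 20, 1,
              dimnames = list(names(labels), "sig"))
  r <- rss(a, labels)
  expect_equal(r["sig", "T"], 1)

  # uniform AUC over two equal types: direct formula oracle
  u <- matrix(1, 20, 1, dimnames = list(names(labels), "sig"))
  r2 <- rss(u, labels)
  expect_equal(r2["sig", "T"],
               oracle_rss(rep(1, 20), as.numeric(labels == "T")))

  # invariant to positive rescaling; bounded in [0, 1]
  set.seed(9)
  v <- matrix(runif(20), 20, 1, dimnames = list(names(labels), "sig"))
  expect_equal(rss(v, labels), rss(v * 7.3, labels))
  expect_true(all(rss(v, labels) >= 0 & rss(v, labels) <= 1))

  expect_warning(rz <- rss(v * 0, labels), "all-zero")
  expect_true(all(rz == 0))
})

test_that("triplet aggregation matches closed form, MC oracle and symmetry", {
  # closed form for k = 3 equals the generic recursion
  s <- c(0.2, 0.5, 0.9)
  q3 <- 6 * prod(s) - 3 * s[3] * s[1]^2 - 3 * s[1] * s[2]^2 + s[1]^3
  expect_equal(order_statistic_q(s), q3, tolerance = 1e-12)
  expect_equal(order_statistic_q(c(1, 1, 1)), 1)

  # Monte-Carlo oracle within 2%
  mc <- oracle_order_stat_mc(s, n_draws = 2e5)
  expect_equal(order_statistic_q(s), mc, tolerance = 0.02)

  # permutation symmetry of the components
  expect_equal(order_statistic_q(c(0.9, 0.5, 0.2)),
               order_statistic_q(c(0.2, 0.9, 0.5)))

  # ranking: dominance and exclusion rules
  ereg <- tibble::tibble(
    tf = c("A", "A", "B"), region = c("r1", "r2", "r3"),
    gene = c("g1", "g2", "g3"),
    tf2g_importance = c(9, 1, 5), r2g_importance = c(8, 1, 4))
  sc <- matrix(c(9, 5, 1, 1, 5, 9), 3, 2,
               dimnames = list(c("r1", "r2", "r3"), c("cA", "cB")))
  db <- build_ranking_db(sc, seed = 1)
  ann <- tibble::tibble(cluster_id = c("cA", "cB"), tf = c("A", "B"))
  tr <- triplet_ranking(ereg, db, ann)
  expect_equal(sort(tr$final_rank), 1:3)
  # the triplet best in all components ranks first
  expect_equal(tr$gene[tr$final_rank == 1], "g1")

  ann_missing <- ann[1, ]
  expect_message(tr2 <- triplet_ranking(ereg, db, ann_missing), "excluded")
  expect_equal(nrow(tr2), 2)
})

test_that("quality filter keeps correlated activators only", {
  set.seed(10)
  n <- 120
  cells <- paste0("c", 1:n)
  lab <- setNames(rep(c("A", "B", "C"), each = 40), cells)
  tf_expr <- c(rnorm(40, 10), rnorm(40, 2), rnorm(40, 2))
  expr <- cbind(TF1 = tf_expr, TF2 = rnorm(n, 5))
  rownames(expr) <- cells
  auc <- cbind(`TF1_+` = tf_expr / 10 + rnorm(n, 0, 0.01),
               `TF2_+` = runif(n))
  rownames(auc) <- cells
  ereg <- tibble::tibble(
    tf = rep(c("TF1", "TF2"), each = 12), tf_sign = "+",
    gene = paste0("g", 1:24), region = paste0("r", 1:24),
    tf2g_importance = 1, rho_tf2g = 0.5, r2g_importance = 1,
    rho_r2g = 0.5, variants = "top_5", gsea_es = 0.5)
  kept <- quality_filter(ereg, expr, auc, lab, n_pseudobulk = 30, k = 5,
                         seed = 1)
  expect_setequal(unique(kept$tf), "TF1")
  expect_true(all(kept$quality_rho > 0.7))
})
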