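# A planted regulatory chain TF1 -> TF2 -> G1 (all activating) plus an
# edge-less bystander TF3, with expression generated accordingly.
chain_fixture <- function(n = 400, seed = 1) {
  set.seed(seed)
  tf1 <- runif(n, 0, 10)
  tf2 <- 2 * tf1 + rnorm(n, 0, 0.2)
  g1 <- 1.5 * tf2 + rnorm(n, 0, 0.2)
  tf3 <- runif(n, 0, 10)
  expr <- cbind(TF1 = tf1, TF2 = tf2, G1 = g1, TF3 = tf3)
  rownames(expr) <- paste0("c", 1:n)
  ereg <- tibble::tibble(
    tf = c("TF1", "TF2"), gene = c("TF2", "G1"), tf_sign = "+")
  list(expr = expr, ereg = ereg)
}

test_that("gene models fit planted signals and exclude self-regulation", {
  fx <- chain_fixture()
  models <- fit_gene_models(fx$expr, fx$ereg, seed = 1, n_trees = 200)
  expect_gt(models$fit_cor[["TF2"]], 0.95)
  expect_gt(models$fit_cor[["G1"]], 0.95)

  # a self-regulating TF is not its own predictor
  ereg_self <- dplyr::bind_rows(fx$ereg,
                                tibble::tibble(tf = "TF2", gene = "TF2",
                                               tf_sign = "+"))
  m2 <- fit_gene_models(fx$expr, ereg_self, seed = 1, n_trees = 50)
  expect_false("TF2" %in% m2$predictors[["TF2"]])

  # seeded determinism of predictions
  m3 <- fit_gene_models(fx$expr, fx$ereg, seed = 1, n_trees = 50)
  m4 <- fit_gene_models(fx$expr, fx$ereg, seed = 1, n_trees = 50)
  s3 <- simulate_knockout(m3, fx$expr, "TF1", n_iterations = 2)
  s4 <- simulate_knockout(m4, fx$expr, "TF1", n_iterations = 2)
  expect_identical(s3$final_logfc, s4$final_logfc)

  # genes without predictors are excluded
  ereg_none <- tibble::tibble(tf = "TF9", gene = "G1", tf_sign = "+")
  expect_error(fit_gene_models(fx$expr, ereg_none, seed = 1), "no genes")
})

test_that("knockout propagates through the chain with one-iteration delay", {
  fx <- chain_fixture()
  models <- fit_gene_models(fx$expr, fx$ereg, seed = 1, n_trees = 200)
  sim <- simulate_knockout(models, fx$expr, "TF1", n_iterations = 4)

  lf <- sim$logfc
  g1_it1 <- lf$log_fc[lf$gene == "G1" & lf$iteration == 1]
  g1_it2 <- lf$log_fc[lf$gene == "G1" & lf$iteration == 2]
  tf2_it1 <- lf$log_fc[lf$gene == "TF2" & lf$iteration == 1]
  # direct target drops immediately; the downstream gene only from iter 2
  expect_lt(tf2_it1, -0.5)
  expect_equal(unname(g1_it1), 0, tolerance = 1e-9)
  expect_lt(g1_it2, -0.5)

  # knocked-out TF column is clamped in every iteration
  ereg_ko <- dplyr::bind_rows(fx$ereg,
                              tibble::tibble(tf = "TF3", gene = "TF1",
                                             tf_sign = "+"))
  mko <- fit_gene_models(fx$expr, ereg_ko, seed = 1, n_trees = 50)
  sko <- simulate_knockout(mko, fx$expr, "TF1", n_iterations = 3)
  expect_true(all(vapply(sko$iterations,
                         function(it) all(it[, "TF1"] == 0), TRUE)))

  expect_error(simulate_knockout(models, fx$expr, "NOPE"), "unknown")
})

test_that("knockout of an edge-less TF changes nothing", {
  fx <- chain_fixture()
  models <- fit_gene_models(fx$expr, fx$ereg, seed = 1, n_trees = 100)
  sim <- simulate_knockout(models, fx$expr, "TF3", n_iterations = 3)
  expect_true(all(abs(sim$final_logfc) < 1e-9))

  # fixed point when the knocked-out TF is already all-zero: simulated and
  # control trajectories coincide at every iteration
  expr0 <- fx$expr
  expr0[, "TF1"] <- 0
  m0 <- fit_gene_models(expr0, fx$ereg, seed = 1, n_trees = 50)
  s0 <- simulate_knockout(m0, expr0, "TF1", n_iterations = 3)
  expect_true(all(abs(s0$logfc$log_fc) < 1e-9))
})

test_that("delta embedding points toward the attracting cluster", {
  set.seed(2)
  n_a <- 60; n_b <- 60
  emb <- rbind(cbind(rnorm(n_a, -3, 0.4), rnorm(n_a, 0, 0.4)),
               cbind(rnorm(n_b, 3, 0.4), rnorm(n_b, 0, 0.4)))
  n_genes <- 20
  prof_a <- c(rep(5, 8), rep(0, 8), rep(1, 4))
  prof_b <- c(rep(0, 8), rep(5, 8), rep(1, 4))
  base <- rbind(matrix(prof_a, n_a, n_genes, byrow = TRUE) +
                  matrix(rnorm(n_a * n_genes, 0, 0.2), n_a),
                matrix(prof_b, n_b, n_genes, byrow = TRUE) +
                  matrix(rnorm(n_b * n_genes, 0, 0.2), n_b))
  rownames(base) <- paste0("c", 1:(n_a + n_b))
  # simulation moves cluster-A cells' profiles toward B
  sim <- base
  sim[1:n_a, ] <- sim[1:n_a, ] +
    matrix(prof_b - prof_a, n_a, n_genes, byrow = TRUE) * 0.5
  # the neighborhood must reach across clusters for the transition weights
  # to see the attracting profile
  de <- delta_embedding(base, sim, emb, k_neighbors = 80)
  toward_b <- de$dx[1:n_a] > 0
  expect_gte(mean(toward_b), 0.9)

  # unchanged profiles give zero shifts
  de0 <- delta_embedding(base, base, emb, k_neighbors = 80)
  expect_true(all(de0$dx == 0 & de0$dy == 0))

  # equivariance under rotation of the embedding
  th <- pi / 3
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  der <- delta_embedding(base, sim, emb %*% rot, k_neighbors = 80)
  got <- cbind(der$dx, der$dy)
  want <- cbind(de$dx, de$dy) %*% rot
  expect_equal(got, want, tolerance = 1e-8)

  expect_error(delta_embedding(base, sim, emb, k_neighbors = 1000),
               "smaller")
})

# Transient sinusoidal TF activity pulse with the target enrichment delayed
# by `lag` (the pulse's moments are shift-invariant, so the standardized
# curves are exact time-shifted copies).
velocity_fixture <- function(n = 300, lag = 0.2, seed = 3, noise = 0.02) {
  set.seed(seed)
  t <- sort(runif(n))
  names(t) <- paste0("c", 1:n)
  f <- function(x) 0.5 + 0.5 * sin(2 * pi * (x - 0.25))
  tf <- matrix(f(t) + rnorm(n, 0, noise), ncol = 1,
               dimnames = list(names(t), "R1"))
  auc <- matrix(f(t - lag) + rnorm(n, 0, noise), ncol = 1,
                dimnames = list(names(t), "R1"))
  list(t = t, tf = tf, auc = auc)
}

test_that("velocity recovers a planted pseudotime lag", {
  fx <- velocity_fixture(lag = 0.2)
  # quantile bins fine enough that the bin traversal time is small against
  # the planted lag (coarse bins bias the force estimate low by ~half a bin)
  v <- grn_velocity(fx$t, fx$tf, fx$auc, n_quantiles = 20)
  mean_force <- mean(v$matches$force)
  expect_gte(mean_force, 0.15)
  expect_lte(mean_force, 0.25)

  # forces are bounded by the pseudotime range and nonnegative
  expect_true(all(v$force >= 0))
  expect_lte(max(v$force), max(fx$t) - min(fx$t))

  # cells at or below the 70% TF-expression quantile carry no arrows
  thr <- stats::quantile(fx$tf[, 1], 0.70)
  low_cells <- names(fx$t)[fx$tf[, 1] <= thr]
  expect_true(all(v$force[low_cells, 1] == 0))
  expect_false(any(v$matches$cell %in% low_cells))
})

test_that("identical TF and target curves give zero forces", {
  fx <- velocity_fixture(lag = 0, noise = 0)
  v <- grn_velocity(fx$t, fx$tf, fx$tf)
  expect_true(all(v$force == 0))
  expect_equal(nrow(v$matches), 0)
})

test_that("velocity validates paths and applies branch penalization", {
  fx <- velocity_fixture()
  expect_error(grn_velocity(fx$t, fx$tf, fx$auc,
                            paths = list(p = names(fx$t)[1:5])),
               "fewer than 10")
  expect_error(grn_velocity(fx$t, fx$tf, fx$auc,
                            paths = list(p = rev(names(fx$t)))),
               "not ordered")

  # a TF with no dynamics in one branch is suppressed there: its
  # path-standardized curve disagrees with the globally standardized one
  set.seed(4)
  n <- 200
  t <- sort(runif(n)); names(t) <- paste0("c", 1:n)
  branch <- rep(c("p1", "p2"), length.out = n)
  f <- function(x) 0.5 + 0.5 * sin(2 * pi * (x - 0.25))
  tf_val <- ifelse(branch == "p1", f(t), 1.0)
  tf <- matrix(tf_val + rnorm(n, 0, 0.01), ncol = 1,
               dimnames = list(names(t), "R1"))
  auc <- matrix(ifelse(branch == "p1", f(t - 0.15), 0.5) +
                  rnorm(n, 0, 0.05), ncol = 1,
                dimnames = list(names(t), "R1"))
  paths <- split(names(t)[order(t)], branch[order(t)])
  v <- grn_velocity(t, tf, auc, paths = paths, t_p = 0.03)
  p2_cells <- names(t)[branch == "p2"]
  # p2 cells express the TF above the global quantile, yet the penalization
  # suppresses (nearly) all of their arrows; exceptions can only occur where
  # the path and global curves cross within t_p
  expect_gt(mean(tf[p2_cells, 1] > quantile(tf[, 1], 0.7)), 0.2)
  expect_gte(mean(v$force[p2_cells, 1] == 0), 0.9)
})

test_that("force prioritization equals a direct RSS computation", {
  set.seed(5)
  cells <- paste0("c", 1:30)
  lab <- setNames(rep(c("A", "B", "C"), each = 10), cells)
  force <- cbind(R1 = c(runif(10, 0.5, 1), rep(0, 20)),
                 R2 = runif(30, 0, 0.2))
  rownames(force) <- cells
  v <- structure(list(force = force, matches = tibble::tibble(),
                      paths = list()), class = "VelocityResult")
  pr <- prioritize_forces(v, lab)
  top <- pr[pr$regulon == "R1", ]
  expect_equal(top$group[which.max(top$score)], "A")
  expect_equal(top$score[top$group == "A"],
               oracle_rss(force[, "R1"], as.numeric(lab == "A")))

  v0 <- structure(list(force = force * 0, matches = tibble::tibble(),
                       paths = list()), class = "VelocityResult")
  expect_warning(pr0 <- prioritize_forces(v0, lab), "zero")
  expect_true(all(pr0$score == 0))
})
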