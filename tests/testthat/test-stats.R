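test_that("signed modularity reduces to the analytic value on canonical graphs", {
  # all-positive matrix, single module: Q = 0 exactly
  m <- abs(random_symmetric(6, 1, signed = FALSE))
  expect_equal(signed_modularity(m, rep("A", 6)), 0)

  # two disconnected K4 cliques with unit weights, partition = cliques:
  # v = 24, 24 within edges of weight 1, e_ij = 9/24 over all 2*16 ordered
  # within-module pairs (incl. i = j) -> Q = (24 - 32*9/24)/24 = 0.5
  k4 <- matrix(1, 4, 4) - diag(4)
  two_cliques <- rbind(cbind(k4, matrix(0, 4, 4)), cbind(matrix(0, 4, 4), k4))
  labels <- rep(c("A", "B"), each = 4)
  expect_equal(signed_modularity(two_cliques, labels), 0.5)
  expect_equal(
    signed_modularity(two_cliques, labels),
    oracle_newman_q(two_cliques, labels),
    tolerance = 1e-12
  )
})

test_that("signed modularity equals the literal double-sum on random signed graphs", {
  for (s in 1:10) {
    m <- random_symmetric(12, 100 + s)
    labels <- sample(c("A", "B", "C"), 12, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1] <- setdiff(c("A", "B", "C"), labels)[1]
    expect_equal(signed_modularity(m, labels), oracle_signed_modularity(m, labels),
      tolerance = 1e-12
    )
  }
})

test_that("signed modularity is invariant under simultaneous relabeling", {
  m <- random_symmetric(10, 77)
  labels <- rep(c("A", "B"), each = 5)
  p <- sample(10)
  expect_equal(
    signed_modularity(m[p, p], labels[p]),
    signed_modularity(m, labels),
    tolerance = 1e-12
  )
  expect_error(signed_modularity(matrix(0, 4, 4), rep("A", 4)), "all-zero")
  expect_error(signed_modularity(m, labels[1:5]), "labels")
})

test_that("one-way ICC matches the hand-computed ANOVA on the 3x2 fixture", {
  w <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3, byrow = TRUE)
  res <- icc_oneway(w, "subject")
  # MSB = 8, MSW = 0.5 -> ICC = 7.5/8.5, F = 16 on (2, 3) df
  expect_equal(res$icc, 7.5 / 8.5, tolerance = 1e-12)
  expect_equal(res$f_stat, 16, tolerance = 1e-12)
  expect_equal(res$df_between, 2L)
  expect_equal(res$df_within, 3L)
  expect_equal(res$p, stats::pf(16, 2, 3, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("ICC grouping transposes units and ratings", {
  set.seed(6)
  w <- matrix(rnorm(24), 6, 4)
  expect_equal(icc_oneway(w, "band"), {
    r <- icc_oneway(t(w), "subject")
    r$grouping <- "band"
    r
  })
  expect_error(icc_oneway(matrix(1, 3, 2), "subject"), "identical")
  expect_error(icc_oneway(matrix(1:4, 1, 4), "subject"), "2 units")
})

test_that("edge_correlation matches the direct Pearson formula", {
  set.seed(91)
  x <- rnorm(500)
  y <- 0.4 * x + rnorm(500)
  res <- edge_correlation(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_hand <- r_hand * sqrt((500 - 2) / (1 - r_hand^2))
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  expect_equal(res$p, 2 * stats::pt(abs(t_hand), 498, lower.tail = FALSE),
    tolerance = 1e-12
  )
  expect_equal(edge_correlation(x, x)$r, 1)
  expect_equal(edge_correlation(x, -x)$r, -1)
  m <- random_symmetric(5, 3)
  expect_equal(edge_correlation(m, m)$n_edges, 10)
  expect_error(edge_correlation(x, rep(1, 500)), "zero-variance")
})

test_that("motion_spearman handles ties like the rank-then-Pearson oracle", {
  x <- c(1, 2, 2, 3, 5, 5, 7, 8)
  y <- c(2, 1, 4, 4, 6, 7, 7, 9)
  res <- motion_spearman(x, y)
  rho_hand <- stats::cor(rank(x), rank(y))
  expect_equal(res$rho, rho_hand, tolerance = 1e-12)
  expect_equal(motion_spearman(1:6, 2^(1:6))$rho, 1)
  expect_equal(motion_spearman(1:6, rev(1:6))$rho, -1)
  expect_error(motion_spearman(1:3, 3:1), "4 subjects")
  expect_error(motion_spearman(1:6, rep(2, 6)), "constant")
})

test_that("top_edges selects planted blocks and conserves counts", {
  part <- make_partition(12, 3)
  m <- devectorize(make_icn_trait(part, 0.1, 0.1, jitter_sd = 0.01, seed = 4))
  # plant a strong within-M1 block
  idx <- which(part == "M1")
  m[idx, idx] <- 5
  diag(m) <- 0
  te <- top_edges(m, part, percentile = 95)
  expect_true(all(te$edges$module_i == "M1" & te$edges$module_j == "M1"))
  upper_plus_diag <- te$module_counts
  upper_plus_diag[lower.tri(upper_plus_diag)] <- 0
  expect_equal(sum(upper_plus_diag), nrow(te$edges))

  # degenerate all-equal weights: >= keeps everything, > drops everything
  m2 <- matrix(1, 6, 6) - diag(6)
  expect_equal(nrow(top_edges(m2, rep(c("A", "B"), 3))$edges), 15)
  expect_warning(
    te2 <- top_edges(m2, rep(c("A", "B"), 3), strict = TRUE),
    "no edges"
  )
  expect_equal(nrow(te2$edges), 0)

  # nodal mode ranks by endpoint strength sums
  te3 <- top_edges(m, part, percentile = 95, mode = "nodal")
  expect_true(all(te3$edges$i %in% idx | te3$edges$j %in% idx))
})

test_that("signed null randomization preserves weight multisets and approximate strengths", {
  m <- random_symmetric(20, 12)
  set.seed(99)
  null <- connica:::randomize_signed_weights(m)
  expect_equal(diag(null), rep(0, 20))
  expect_equal(null, t(null))
  expect_equal(
    sort(null[upper.tri(null)][null[upper.tri(null)] > 0]),
    sort(m[upper.tri(m)][m[upper.tri(m)] > 0]),
    tolerance = 1e-12
  )
  expect_equal(
    sort(null[upper.tri(null)][null[upper.tri(null)] < 0]),
    sort(m[upper.tri(m)][m[upper.tri(m)] < 0]),
    tolerance = 1e-12
  )
  # strengths approximately preserved per sign class
  sp_orig <- rowSums(pmax(m, 0))
  sp_null <- rowSums(pmax(null, 0))
  expect_gt(stats::cor(sp_orig, sp_null), 0.8)
  expect_false(identical(null, m))
})

test_that("modularity_pvalue hits the floor for strongly modular graphs", {
  part <- make_partition(12, 2)
  m <- devectorize(make_icn_trait(part, 1, 0, jitter_sd = 0.02, seed = 9))
  res <- modularity_pvalue(m, part, n_iter = 200, seed = 3)
  expect_equal(res$p, 1 / 201)
  expect_equal(res$Q, signed_modularity(m, part))
  expect_length(res$null_Q, 200)
  expect_true(all(res$null_Q < res$Q))
  g <- glance(res)
  expect_equal(g$p, res$p)
  expect_error(modularity_pvalue(m, part, n_iter = 0), "n_iter")
})

test_that("the shipped 148-region partition fixture loads and drives modularity", {
  path <- system.file("extdata", "partition_148_yeo7_synthetic.tsv", package = "connica")
  part <- read_partition(path)
  expect_length(part, 148)
  expect_equal(nlevels(part), 7)
  m <- devectorize(make_icn_trait(part, 1, 0, jitter_sd = 0.05, seed = 3))
  expect_equal(dim(m), c(148L, 148L))
  expect_gt(signed_modularity(m, part), 0.5)
})

test_that("shuffled labels give unremarkable modularity p values", {
  part <- make_partition(12, 2)
  m <- devectorize(make_icn_trait(part, 1, 0, jitter_sd = 0.02, seed = 9))
  set.seed(14)
  shuffled <- sample(as.character(part))
  res <- modularity_pvalue(m, shuffled, n_iter = 100, seed = 5)
  expect_gt(res$p, 0.05)
})
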