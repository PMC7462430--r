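test_that("pca_reduce picks the minimal PC count and matches an SVD oracle", {
  set.seed(41)
  # noiseless rank-1 data -> one PC regardless of var_frac
  x1 <- outer(rnorm(8), rnorm(40))
  r1 <- pca_reduce(x1, 0.5)
  expect_equal(r1$n_components, 1L)
  expect_equal(pca_reduce(x1, 0.99)$n_components, 1L)

  x <- matrix(rnorm(20 * 60), 20, 60)
  r <- pca_reduce(x, 0.8)
  sv <- svd(sweep(x, 2, colMeans(x)))
  frac <- cumsum(sv$d^2) / sum(sv$d^2)
  expect_equal(r$n_components, which(frac >= 0.8)[1])
  expect_equal(r$d, sv$d[seq_len(r$n_components)])
  # reconstruction captures at least the requested variance
  recon <- r$scores %*% r$basis
  xc <- sweep(x, 2, colMeans(x))
  expect_gte(sum(recon^2) / sum(xc^2), 0.8)
})

test_that("retained PC count is non-decreasing in var_frac", {
  set.seed(42)
  x <- matrix(rnorm(15 * 50), 15, 50)
  ps <- vapply(
    c(0.5, 0.6, 0.7, 0.8, 0.9, 0.99),
    function(v) pca_reduce(x, v)$n_components, integer(1)
  )
  expect_true(all(diff(ps) >= 0))
  expect_error(pca_reduce(x, 0), "var_frac")
  expect_error(pca_reduce(x, 1.2), "var_frac")
  expect_error(pca_reduce(matrix(1, 5, 5), 0.9), "constant")
})

test_that("ica_decompose separates Laplacian sources mixed into rows", {
  set.seed(7)
  n_samp <- 2000
  s_true <- cbind(
    rexp(n_samp) * sample(c(-1, 1), n_samp, TRUE),
    rexp(n_samp) * sample(c(-1, 1), n_samp, TRUE)
  )
  mix <- matrix(rnorm(8), 4, 2) # 4 observed rows, 2 sources
  x <- mix %*% t(s_true) # 4 x n_samp
  r <- pca_reduce(x, 0.999)
  run <- ica_decompose(r, 2, seed = 11)
  expect_true(run$converged)
  cors <- abs(cor(t(run$traits), s_true))
  # each true source recovered by exactly one trait
  expect_gt(max(cors[1, ]), 0.99)
  expect_gt(max(cors[2, ]), 0.99)
  expect_lt(min(apply(cors, 1, max) - apply(cors, 1, min)), 1)
})

test_that("same seed gives bit-identical decompositions", {
  set.seed(13)
  x <- matrix(rnorm(12 * 80), 12, 80)
  r <- pca_reduce(x, 0.9)
  a <- ica_decompose(r, 3, seed = 5)
  b <- ica_decompose(r, 3, seed = 5)
  d <- ica_decompose(r, 3, seed = 6)
  expect_identical(a$traits, b$traits)
  expect_identical(a$weights, b$weights)
  expect_false(identical(a$traits, d$traits))
})

test_that("with n_ics = P the component model reconstructs the reduced data", {
  set.seed(19)
  x <- matrix(rnorm(10 * 120), 10, 120) + outer(rnorm(10), rnorm(120))
  r <- pca_reduce(x, 0.75)
  p <- r$n_components
  run <- ica_decompose(r, p, seed = 2)
  recon <- run$weights %*% run$traits +
    outer(run$row_offsets, rep(1, ncol(run$traits)))
  expect_lt(max(abs(r$scores %*% r$basis - recon)), 1e-6)
})

test_that("n_ics outside [1, P] is rejected with an actionable message", {
  set.seed(23)
  r <- pca_reduce(matrix(rnorm(8 * 30), 8, 30), 0.7)
  expect_error(ica_decompose(r, r$n_components + 1), "lower n_ics or raise var_frac")
  expect_error(ica_decompose(r, 0), "n_ics")
})

test_that("identical runs are all robust with occurrence 1 and the shared trait", {
  set.seed(29)
  x <- matrix(rnorm(10 * 60), 10, 60)
  r <- pca_reduce(x, 0.9)
  run <- ica_decompose(r, 3, seed = 4)
  comps <- stability_select(rep(list(run), 6))
  expect_length(comps, 3)
  for (rc in comps) {
    expect_equal(rc$occurrence, 1)
    expect_equal(rc$mean_trait_r, 1)
    # averaged trait equals one of the shared traits up to sign
    best <- max(abs(cor(rc$trait, t(run$traits))))
    expect_equal(best, 1, tolerance = 1e-12)
  }
})

test_that("low-noise planted traits are recovered exactly as K robust components", {
  gt <- subject_general_gt(S = 12, B = 3, n_regions = 24, noise_sd = 0.02)
  ds <- simulate_dataset(gt, seed = 101, band_names = c("theta", "alpha", "gamma"))
  h <- build_hybrid_matrix(ds, band_order = c("theta", "alpha", "gamma"))
  fit <- run_connica(h, n_ics = 2, var_frac = 0.9, n_runs = 30, base_seed = 3)
  expect_length(fit$components, 2)
  rep <- recovery_report(fit, gt)
  expect_true(all(rep$fmri_r > 0.95))
  expect_true(all(rep$eeg_r > 0.95))
  expect_true(all(rep$weight_r > 0.95))
})

test_that("pure noise data yields no robust components", {
  set.seed(55)
  x <- matrix(rnorm(30 * 500), 30, 500)
  r <- pca_reduce(x, 0.75)
  runs <- lapply(1:20, function(i) ica_decompose(r, 5, seed = 100 + i))
  comps <- stability_select(runs)
  expect_length(comps, 0)
})

test_that("stability selection is order-invariant on clean runs", {
  gt <- subject_general_gt(S = 10, B = 2, n_regions = 16, noise_sd = 0.01)
  ds <- simulate_dataset(gt, seed = 7, band_names = c("alpha", "gamma"))
  h <- build_hybrid_matrix(ds, band_order = c("alpha", "gamma"))
  red <- pca_reduce(h, 0.9)
  runs <- lapply(1:8, function(i) ica_decompose(red, 2, seed = 200 + i))
  c_fwd <- stability_select(runs)
  c_rev <- stability_select(rev(runs))
  expect_equal(length(c_fwd), length(c_rev))
  for (a in seq_along(c_fwd)) {
    match_r <- vapply(
      c_rev,
      function(rc) abs(fast_cor_test_helper(rc$trait, c_fwd[[a]]$trait)),
      numeric(1)
    )
    expect_equal(max(match_r), 1, tolerance = 1e-9)
  }
})

test_that("scaling the hybrid matrix leaves robust trait directions unchanged", {
  gt <- subject_general_gt(S = 10, B = 2, n_regions = 16, noise_sd = 0.02)
  ds <- simulate_dataset(gt, seed = 31, band_names = c("alpha", "gamma"))
  h <- build_hybrid_matrix(ds, band_order = c("alpha", "gamma"))
  f1 <- run_connica(h, n_ics = 2, var_frac = 0.9, n_runs = 10, base_seed = 9)
  h$values <- h$values * 4.2
  f2 <- run_connica(h, n_ics = 2, var_frac = 0.9, n_runs = 10, base_seed = 9)
  expect_equal(length(f1$components), length(f2$components))
  for (a in seq_along(f1$components)) {
    r <- vapply(
      f2$components,
      function(rc) abs(fast_cor_test_helper(rc$trait, f1$components[[a]]$trait)),
      numeric(1)
    )
    expect_equal(max(r), 1, tolerance = 1e-6)
  }
})

test_that("split_component separates the fMRI and EEG halves", {
  e_len <- 10 # n = 5
  trait <- c(rep(1, e_len), rep(0, e_len))
  parts <- split_component(trait / sqrt(sum(trait^2)))
  expect_true(all(parts$fmri_part[upper.tri(parts$fmri_part)] > 0))
  expect_true(all(parts$eeg_part == 0))
  expect_error(split_component(rep(1, 11)), "even")
})
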