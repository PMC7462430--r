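test_that("make_icn_trait lays out within/between weights on the edge grid", {
  part <- make_partition(6, 2) # two modules of 3 regions
  v <- make_icn_trait(part, within_weight = 1, between_weight = 0, jitter_sd = 0)
  expect_length(v, 15)
  expect_equal(sum(v == 1), 6) # two K3 blocks: 3 within edges each
  expect_equal(sum(v == 0), 9)
  # modular by construction under its own partition
  expect_gt(signed_modularity(devectorize(v), part), 0)
})

test_that("make_icn_trait jitter is seeded and reproducible", {
  part <- make_partition(8, 2)
  v1 <- make_icn_trait(part, 1, 0, jitter_sd = 0.1, seed = 7)
  v2 <- make_icn_trait(part, 1, 0, jitter_sd = 0.1, seed = 7)
  v3 <- make_icn_trait(part, 1, 0, jitter_sd = 0.1, seed = 8)
  expect_identical(v1, v2)
  expect_false(identical(v1, v3))
  base <- make_icn_trait(part, 1, 0, jitter_sd = 0)
  set.seed(7)
  expect_equal(v1, base + rnorm(length(base), sd = 0.1))
})

test_that("make_icn_trait module restriction zeroes edges outside the set", {
  part <- make_partition(9, 3)
  v <- make_icn_trait(part, 1, 0.5, jitter_sd = 0, modules = c("M1", "M2"))
  et <- edge_index_table(9)
  outside <- !(part[et$i] %in% c("M1", "M2") & part[et$j] %in% c("M1", "M2"))
  expect_true(all(v[outside] == 0))
  within <- part[et$i] == part[et$j] & !outside
  expect_true(all(v[within] == 1))
})

test_that("make_icn_trait rejects degenerate partitions", {
  expect_error(make_icn_trait(factor(rep("A", 5)), 1, 0), "2 modules")
  expect_error(make_icn_trait(make_partition(6, 2), 1, 0, jitter_sd = -1))
})

test_that("subject_general mixing is constant across bands, frequency_tuned follows the profile", {
  w <- make_mixing(10, 5, "subject_general", effect_sd = 0.4, seed = 3)
  expect_equal(dim(w), c(10L, 5L))
  expect_true(all(apply(w, 1, function(r) diff(range(r)) == 0)))
  expect_gt(sd(w[, 1]), 0)

  wf <- make_mixing(4, 5, "frequency_tuned",
    effect_sd = 0,
    band_profile = c(0, 0, 0, 0, 1), seed = 3
  )
  expect_equal(wf[, 5], rep(1, 4))
  expect_true(all(wf[, 1:4] == 0))
  expect_error(
    make_mixing(4, 5, "frequency_tuned", band_profile = c(1, 2)),
    "length"
  )
})

test_that("mixing modes drive the expected ICC structure", {
  w <- make_mixing(20, 5, "subject_general", effect_sd = 0.4, seed = 11)
  expect_equal(icc_oneway(w, "subject")$icc, 1) # zero within-subject noise
  wf <- make_mixing(20, 5, "frequency_tuned",
    effect_sd = 0.02,
    band_profile = c(0.1, 0.1, 0.15, 0.25, 0.6), seed = 11
  )
  expect_gt(icc_oneway(wf, "band")$icc, 0.9)
  expect_gt(icc_oneway(wf, "band")$icc, icc_oneway(wf, "subject")$icc)
})

test_that("simulate_dataset reproduces planted patterns exactly at zero noise", {
  part <- make_partition(10, 2)
  tr <- list(list(
    fmri = make_icn_trait(part, 1, 0, jitter_sd = 0.05, seed = 1),
    eeg = make_icn_trait(part, 0.6, -0.1, jitter_sd = 0.05, seed = 2)
  ))
  mix <- array(1, c(3, 2, 1))
  mix[2, , 1] <- 2 # subject 2 has doubled weights
  gt <- ground_truth(tr, mix, noise_sd = 0, n_regions = 10, seed = 5)
  ds <- simulate_dataset(gt, band_names = c("alpha", "gamma"))
  expect_equal(nrow(ds), 3 * 3) # 1 fMRI + 2 EEG per subject
  eeg1 <- ds$conn[[which(ds$subject_id == "sub01" & ds$band == "alpha")]]
  expect_equal(vectorize_upper(eeg1), tr[[1]]$eeg)
  # linearity: subject 2 is exactly twice subject 1
  eeg2 <- ds$conn[[which(ds$subject_id == "sub02" & ds$band == "alpha")]]
  expect_equal(vectorize_upper(eeg2), 2 * vectorize_upper(eeg1))
  fmri2 <- ds$conn[[which(ds$subject_id == "sub02" & ds$modality == "fmri")]]
  fmri1 <- ds$conn[[which(ds$subject_id == "sub01" & ds$modality == "fmri")]]
  expect_equal(vectorize_upper(fmri2), 2 * vectorize_upper(fmri1))
})

test_that("simulated connectomes are symmetric, hollow, and seed-reproducible", {
  gt <- subject_general_gt(S = 4, B = 2, n_regions = 12, noise_sd = 0.1)
  ds1 <- simulate_dataset(gt, seed = 9)
  ds2 <- simulate_dataset(gt, seed = 9)
  ds3 <- simulate_dataset(gt, seed = 10)
  for (k in seq_len(nrow(ds1))) {
    m <- unclass(ds1$conn[[k]])
    expect_equal(m, t(m))
    expect_true(all(diag(m) == 0))
    expect_identical(m, unclass(ds2$conn[[k]]))
  }
  expect_false(identical(unclass(ds1$conn[[1]]), unclass(ds3$conn[[1]])))
})

test_that("the standard study dimensions give the expected hybrid shape", {
  gt <- example_ground_truth(S = 26, B = 5, n_regions = 60)
  ds <- simulate_dataset(gt)
  h <- build_hybrid_matrix(ds)
  expect_equal(dim(h$values), c(130L, 3540L)) # 26*5 rows, 2*1770 edges
})

test_that("recovery_report scores exact and sign-flipped ground truth at 1", {
  gt <- subject_general_gt(S = 6, B = 2, n_regions = 12, noise_sd = 0)
  make_rc <- function(k, flip = 1) {
    trait <- flip * c(gt$traits[[k]]$fmri, gt$traits[[k]]$eeg)
    structure(
      list(
        trait = trait,
        weights = flip * as.vector(t(gt$mixing[, , k])),
        occurrence = 1, mean_trait_r = 1, mean_weight_r = 1, n_matched = 1,
        fmri_part = devectorize(gt$traits[[k]]$fmri),
        eeg_part = devectorize(gt$traits[[k]]$eeg)
      ),
      class = "robust_component"
    )
  }
  rep1 <- recovery_report(list(make_rc(1), make_rc(2)), gt)
  expect_equal(rep1$fmri_r, c(1, 1))
  expect_equal(rep1$eeg_r, c(1, 1))
  expect_equal(rep1$weight_r, c(1, 1))
  rep2 <- recovery_report(list(make_rc(1, flip = -1), make_rc(2, flip = -1)), gt)
  expect_equal(rep2$fmri_r, c(1, 1)) # sign indeterminacy absorbed
  expect_equal(rep2$weight_r, c(1, 1))
  expect_error(
    recovery_report(list(structure(list(trait = 1:4, weights = 1:4),
      class = "robust_component"
    )), gt),
    "length"
  )
})

test_that("ground_truth validates dimensions and noise", {
  part <- make_partition(6, 2)
  tr <- list(list(
    fmri = make_icn_trait(part, 1, 0),
    eeg = make_icn_trait(part, 1, 0)
  ))
  expect_error(ground_truth(tr, array(1, c(2, 2, 2)), 0.1, 6), "K = number of traits")
  expect_error(ground_truth(tr, array(1, c(2, 2, 1)), -0.1, 6), "noise_sd")
  expect_error(ground_truth(tr, array(1, c(2, 2, 1)), 0.1, 8), "length")
  gt <- ground_truth(tr, array(1, c(2, 2, 1)), 0.1, 6, seed = 3)
  expect_error(simulate_dataset(gt, S = 5), "do not match")
})
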