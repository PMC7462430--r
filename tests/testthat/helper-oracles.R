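# Independent brute-force oracles used across tests. These deliberately use
# literal loops / textbook formulas, not the package's vectorized code paths.

# Literal double-sum evaluation of the signed modularity quality function.
oracle_signed_modularity <- function(w, labels) {
  n <- nrow(w)
  wp <- matrix(0, n, n)
  wn <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        if (w[i, j] > 0) wp[i, j] <- w[i, j] else wn[i, j] <- -w[i, j]
      }
    }
  }
  vp <- sum(wp)
  vn <- sum(wn)
  q_pos <- 0
  q_neg <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (labels[i] == labels[j]) {
        if (vp > 0) q_pos <- q_pos + (wp[i, j] - sum(wp[i, ]) * sum(wp[, j]) / vp)
        if (vn > 0) q_neg <- q_neg + (wn[i, j] - sum(wn[i, ]) * sum(wn[, j]) / vn)
      }
    }
  }
  out <- 0
  if (vp > 0) out <- q_pos / vp
  if (vn > 0) out <- out - q_neg / (vp + vn)
  out
}

# Classic Newman weighted modularity for nonnegative matrices.
oracle_newman_q <- function(w, labels) {
  v <- sum(w)
  s <- rowSums(w)
  q <- 0
  for (i in seq_len(nrow(w))) {
    for (j in seq_len(ncol(w))) {
      if (labels[i] == labels[j]) q <- q + w[i, j] - s[i] * s[j] / v
    }
  }
  q / v
}

# Row-pair Pearson correlation with explicit column deletion (harmonization
# oracle).
oracle_harmonize <- function(m) {
  n <- nrow(m)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        ri <- m[i, -c(i, j)]
        rj <- m[j, -c(i, j)]
        out[i, j] <- sum((ri - mean(ri)) * (rj - mean(rj))) /
          sqrt(sum((ri - mean(ri))^2) * sum((rj - mean(rj))^2))
      }
    }
  }
  out
}

fast_cor_test_helper <- function(x, y) stats::cor(x, y)

# strip connectome/class attributes down to a plain numeric matrix
as_plain <- function(x) matrix(as.numeric(x), nrow(x), ncol(x))

random_symmetric <- function(n, seed, signed = TRUE) {
  set.seed(seed)
  m <- matrix(rnorm(n * n), n, n)
  if (!signed) m <- abs(m)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

# Small two-trait ground truth where BOTH traits carry subject-general
# mixing, so each planted trait is a single hybrid direction and recovery is
# exact in the low-noise limit. Trait patterns mirror the reference design:
# a graded modular trait and an orthogonal pair of signed contrasts.
subject_general_gt <- function(S = 12, B = 3, n_regions = 24, noise_sd = 0.02,
                               seed = 42) {
  part <- make_partition(n_regions, 4)
  mods <- levels(part)
  strengths <- c(2.4, 1.7, 1.2, 0.9)
  e_len <- n_regions * (n_regions - 1) / 2
  modular <- function(jit_seed) {
    v <- Reduce(`+`, lapply(1:4, function(m) {
      make_icn_trait(part, strengths[m], 0, jitter_sd = 0, modules = mods[m])
    }))
    set.seed(jit_seed)
    v + rnorm(e_len, sd = 0.05)
  }
  f2 <- make_icn_trait(part, 1, 0, jitter_sd = 0, modules = mods[1]) -
    make_icn_trait(part, 1, 0, jitter_sd = 0, modules = mods[2])
  e2 <- make_icn_trait(part, 0, 1, jitter_sd = 0, modules = mods[3:4]) -
    make_icn_trait(part, 0, 1, jitter_sd = 0, modules = mods[1:2])
  set.seed(seed + 3)
  f2 <- f2 + rnorm(e_len, sd = 0.05)
  set.seed(seed + 4)
  e2 <- e2 + rnorm(e_len, sd = 0.05)
  traits <- list(
    list(fmri = modular(seed + 1), eeg = modular(seed + 2)),
    list(fmri = f2, eeg = e2)
  )
  mixing <- array(NA_real_, c(S, B, 2))
  mixing[, , 1] <- make_mixing(S, B, "subject_general", effect_sd = 0.3, seed = seed + 5)
  mixing[, , 2] <- make_mixing(S, B, "subject_general", effect_sd = 0.3, seed = seed + 6)
  ground_truth(traits, mixing, noise_sd, n_regions, partition = part, seed = seed)
}
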