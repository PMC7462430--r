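#' PCA variance reduction of a hybrid matrix
#'
#' Column-centers the hybrid matrix and keeps the smallest number of
#' principal components whose cumulative explained variance reaches
#' `var_frac`. The basis sign is fixed so the largest-magnitude loading of
#' each component is positive, making the decomposition deterministic.
#'
#' @param h A `hybrid_matrix` (or plain numeric matrix).
#' @param var_frac Target cumulative explained-variance fraction in (0, 1].
#' @return A `reduced_fc` object: `scores` (R x P), `basis` (P x C),
#'   `col_means`, `d` (singular values, length P),
#'   `explained_variance_fractions` (per-component, length P),
#'   `var_frac_requested`, plus row/column metadata carried over from the
#'   hybrid matrix when available.
#' @export
pca_reduce <- function(h, var_frac) {
  check_scalar_number(var_frac, "var_frac")
  if (var_frac <= 0 || var_frac > 1) abort("`var_frac` must be in (0, 1].")
  x <- if (inherits(h, "hybrid_matrix")) h$values else as.matrix(h)
  if (nrow(x) < 2L) abort("need at least 2 rows.")
  col_means <- colMeans(x)
  xc <- sweep(x, 2L, col_means)
  total_var <- sum(xc^2)
  if (total_var == 0) abort("constant matrix: zero variance, PCA undefined.")
  sv <- svd(xc)
  ev <- sv$d^2
  frac <- ev / sum(ev)
  p_keep <- which(cumsum(frac) >= var_frac - 1e-12)[1]
  scores <- sv$u[, seq_len(p_keep), drop = FALSE] %*% diag(sv$d[seq_len(p_keep)], p_keep)
  basis <- t(sv$v[, seq_len(p_keep), drop = FALSE])
  # deterministic sign: largest-|loading| entry of each basis row positive
  for (k in seq_len(p_keep)) {
    m_idx <- which.max(abs(basis[k, ]))
    if (basis[k, m_idx] < 0) {
      basis[k, ] <- -basis[k, ]
      scores[, k] <- -scores[, k]
    }
  }
  structure(
    list(
      scores = scores, basis = basis, col_means = col_means,
      d = sv$d[seq_len(p_keep)],
      explained_variance_fractions = frac[seq_len(p_keep)],
      var_frac_requested = var_frac,
      n_components = p_keep,
      row_meta = if (inherits(h, "hybrid_matrix")) h$row_meta else NULL,
      col_meta = if (inherits(h, "hybrid_matrix")) h$col_meta else NULL,
      n_regions = if (inherits(h, "hybrid_matrix")) h$n_regions else NULL,
      band_order = if (inherits(h, "hybrid_matrix")) h$band_order else NULL
    ),
    class = "reduced_fc"
  )
}

#' @export
print.reduced_fc <- function(x, ...) {
  cat(sprintf(
    "<reduced_fc> %d PCs for %.0f%% variance (achieved %.1f%%), %d rows x %d columns\n",
    x$n_components, 100 * x$var_frac_requested,
    100 * sum(x$explained_variance_fractions),
    nrow(x$scores), length(x$col_means)
  ))
  invisible(x)
}

# Symmetric fixed-point FastICA with tanh contrast on pre-whitened data.
# z: samples x dims (unit-variance uncorrelated columns); returns the K x dims
# unmixing rotation, convergence flag and iteration count.
fastica_symm <- function(z, n_comp, seed, tol = 1e-6, max_iter = 1000L) {
  p <- ncol(z)
  n <- nrow(z)
  sym_decorr <- function(w) {
    e <- eigen(w %*% t(w), symmetric = TRUE)
    vals <- pmax(e$values, .Machine$double.eps)
    (e$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(e$vectors)) %*% w
  }
  set.seed(seed)
  w <- sym_decorr(matrix(rnorm(n_comp * p), n_comp, p))
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    u <- z %*% t(w) # n x K
    g <- tanh(u)
    g_prime_mean <- colMeans(1 - g^2)
    w_new <- crossprod(g, z) / n - diag(g_prime_mean, n_comp) %*% w
    w_new <- sym_decorr(w_new)
    delta <- max(abs(abs(rowSums(w_new * w)) - 1))
    w <- w_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(w = w, converged = converged, n_iter = it)
}

#' One ICA decomposition of PCA-reduced hybrid data
#'
#' Runs fixed-point negentropy-maximizing ICA (tanh contrast, symmetric
#' decorrelation) in the retained P-dimensional principal subspace, with the
#' edges of the hybrid matrix as samples, and maps the recovered sources
#' back to the full column space: each of the `n_ics` traits is a
#' unit-norm vector over the 2E hybrid columns, and the mixing weights are
#' the least-squares loadings of each (centered) hybrid row on the traits.
#' The same seed gives bit-identical output; non-convergence within
#' `max_iter` iterations is flagged so the run can be discarded downstream.
#'
#' @param r A `reduced_fc` from [pca_reduce()].
#' @param n_ics Number of independent components, `1 <= n_ics <= P`.
#' @param seed Integer seed for the random rotation initialization.
#' @param tol Fixed-point convergence tolerance (default 1e-6).
#' @param max_iter Maximum fixed-point iterations (default 1000).
#' @return An `ica_run`: `traits` (K x C, unit-norm rows), `weights`
#'   (R x K), `row_offsets` (per-row reconstruction offsets), `seed`,
#'   `converged`, `n_iter`.
#' @export
ica_decompose <- function(r, n_ics, seed = 1L, tol = 1e-6, max_iter = 1000L) {
  stopifnot(inherits(r, "reduced_fc"))
  p <- r$n_components
  if (n_ics < 1L) abort("`n_ics` must be >= 1.")
  if (n_ics > p) {
    abort(sprintf(
      "n_ics = %d exceeds the %d principal components retained at var_frac = %g; lower n_ics or raise var_frac.",
      n_ics, p, r$var_frac_requested
    ))
  }
  # edge-space coordinates of the rank-P data: T = V %*% diag(d)  (C x P)
  t_mat <- t(r$basis) %*% diag(r$d, p)
  t_means <- colMeans(t_mat)
  tc <- sweep(t_mat, 2L, t_means)
  cv <- crossprod(tc) / (nrow(tc) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  keep <- eg$values > max(eg$values) * 1e-12
  if (sum(keep) < n_ics) {
    abort(sprintf(
      "effective rank %d after edge-centering is below n_ics = %d.",
      sum(keep), n_ics
    ))
  }
  wh <- eg$vectors[, keep, drop = FALSE] %*% diag(1 / sqrt(eg$values[keep]), sum(keep))
  z <- tc %*% wh # C x P_eff, whitened
  fi <- fastica_symm(z, n_ics, seed = seed, tol = tol, max_iter = max_iter)
  s <- z %*% t(fi$w) # C x K independent sources over edges
  norms <- sqrt(colSums(s^2))
  traits <- t(sweep(s, 2L, norms, "/")) # K x C, orthonormal rows
  # least-squares loadings of the centered data rows on the traits
  weights <- r$scores %*% (r$basis %*% t(traits))
  recon <- weights %*% traits
  xc_p <- r$scores %*% r$basis
  row_offsets <- rowMeans(xc_p - recon)
  structure(
    list(
      traits = traits, weights = weights, row_offsets = row_offsets,
      seed = as.integer(seed), converged = fi$converged, n_iter = fi$n_iter,
      n_ics = as.integer(n_ics)
    ),
    class = "ica_run"
  )
}

#' @export
print.ica_run <- function(x, ...) {
  cat(sprintf(
    "<ica_run> %d ICs, seed %d, %s in %d iterations\n",
    x$n_ics, x$seed, if (x$converged) "converged" else "NOT converged", x$n_iter
  ))
  invisible(x)
}
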