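# Greedy one-to-one assignment between two trait matrices by highest
# absolute correlation; returns per-reference-component match index (NA if
# unmatched), the signed correlation and the weight correlation.
match_runs <- function(ref, run) {
  k_ref <- nrow(ref$traits)
  k_run <- nrow(run$traits)
  cmat <- matrix(NA_real_, k_ref, k_run)
  for (a in seq_len(k_ref)) {
    for (b in seq_len(k_run)) {
      cmat[a, b] <- fast_cor(ref$traits[a, ], run$traits[b, ])
    }
  }
  amat <- abs(cmat)
  match_idx <- rep(NA_integer_, k_ref)
  trait_r <- rep(NA_real_, k_ref)
  for (step in seq_len(min(k_ref, k_run))) {
    best <- which(amat == max(amat, na.rm = TRUE), arr.ind = TRUE)[1, , drop = TRUE]
    a <- best[1]
    b <- best[2]
    match_idx[a] <- b
    trait_r[a] <- cmat[a, b]
    amat[a, ] <- NA_real_
    amat[, b] <- NA_real_
    if (all(is.na(amat))) break
  }
  weight_r <- rep(NA_real_, k_ref)
  for (a in seq_len(k_ref)) {
    if (!is.na(match_idx[a])) {
      weight_r[a] <- fast_cor(ref$weights[, a], run$weights[, match_idx[a]])
    }
  }
  list(match_idx = match_idx, trait_r = trait_r, weight_r = weight_r)
}

#' Stability selection of robust components across repeated ICA runs
#'
#' Matches every run's components to those of a reference run (the first
#' converged run) by greedy one-to-one assignment on absolute trait
#' correlation. A reference component counts as re-found in a run when both
#' the absolute trait correlation and the absolute mixing-weight correlation
#' of its match exceed their thresholds. Components re-found in at least
#' `occurrence_thr` of the converged runs are returned as robust, each the
#' sign-aligned average of its matched instances (traits renormalized to
#' unit norm). The overall sign is fixed so the mean mixing weight is
#' positive; when that mean is numerically zero — as it is whenever the
#' weights come from column-centered data — the largest-magnitude trait
#' entry is made positive instead, which in particular renders a modular
#' trait's within-module edges positive.
#'
#' @param runs List of `ica_run` objects (non-converged runs are dropped;
#'   at least 2 converged runs are required).
#' @param occurrence_thr Minimum fraction of converged runs a component must
#'   appear in (default 0.75).
#' @param trait_thr,weight_thr Minimum absolute correlations for a match
#'   (default 0.75 each).
#' @return List of `robust_component` objects, each with `trait`, `weights`,
#'   `occurrence`, `mean_trait_r`, `mean_weight_r` (means over matched
#'   non-reference instances), `n_matched`, and the devectorized
#'   `fmri_part` / `eeg_part` matrices.
#' @export
stability_select <- function(runs, occurrence_thr = 0.75, trait_thr = 0.75,
                             weight_thr = 0.75) {
  for (thr in c(occurrence_thr, trait_thr, weight_thr)) {
    if (!is.numeric(thr) || thr <= 0 || thr >= 1) abort("thresholds must lie in (0, 1).")
  }
  conv <- Filter(function(r) isTRUE(r$converged), runs)
  if (length(conv) == 0L) abort("no converged runs.")
  if (length(conv) < 2L) abort("stability selection needs at least 2 converged runs.")
  ref <- conv[[1]]
  k_ref <- nrow(ref$traits)
  n_conv <- length(conv)
  trait_acc <- vector("list", k_ref)
  weight_acc <- vector("list", k_ref)
  n_match <- integer(k_ref)
  r_trait <- vector("list", k_ref)
  r_weight <- vector("list", k_ref)
  for (a in seq_len(k_ref)) {
    trait_acc[[a]] <- ref$traits[a, ]
    weight_acc[[a]] <- ref$weights[, a]
    n_match[a] <- 1L
  }
  for (r_idx in seq.int(2L, n_conv)) {
    mm <- match_runs(ref, conv[[r_idx]])
    for (a in seq_len(k_ref)) {
      b <- mm$match_idx[a]
      if (is.na(b)) next
      if (abs(mm$trait_r[a]) > trait_thr && abs(mm$weight_r[a]) > weight_thr) {
        sgn <- sign(mm$trait_r[a])
        trait_acc[[a]] <- trait_acc[[a]] + sgn * conv[[r_idx]]$traits[b, ]
        weight_acc[[a]] <- weight_acc[[a]] + sgn * conv[[r_idx]]$weights[, b]
        n_match[a] <- n_match[a] + 1L
        r_trait[[a]] <- c(r_trait[[a]], abs(mm$trait_r[a]))
        r_weight[[a]] <- c(r_weight[[a]], abs(mm$weight_r[a]))
      }
    }
  }
  out <- list()
  for (a in seq_len(k_ref)) {
    occ <- n_match[a] / n_conv
    if (occ < occurrence_thr) next
    trait <- trait_acc[[a]] / n_match[a]
    trait <- trait / sqrt(sum(trait^2))
    weights <- weight_acc[[a]] / n_match[a]
    # overall sign: mean mixing weight positive; for weights from
    # column-centered data the mean is numerically zero, so fall back to
    # making the largest-magnitude trait entry positive (deterministic)
    s_ref <- mean(weights)
    if (abs(s_ref) <= 1e-8 * sd(weights)) s_ref <- trait[which.max(abs(trait))]
    if (s_ref < 0) {
      weights <- -weights
      trait <- -trait
    }
    # hybrid traits devectorize into per-modality matrices; plain (non-hybrid)
    # traits keep NULL parts
    parts <- tryCatch(split_component(trait), error = function(e) NULL)
    out[[length(out) + 1L]] <- structure(
      list(
        trait = trait, weights = as.vector(weights), occurrence = occ,
        mean_trait_r = if (length(r_trait[[a]])) mean(r_trait[[a]]) else 1,
        mean_weight_r = if (length(r_weight[[a]])) mean(r_weight[[a]]) else 1,
        n_matched = n_match[a],
        fmri_part = parts$fmri_part,
        eeg_part = parts$eeg_part
      ),
      class = "robust_component"
    )
  }
  out
}

#' @export
print.robust_component <- function(x, ...) {
  cat(sprintf(
    "<robust_component> occurrence %.2f, mean trait r %.3f, mean weight r %.3f\n",
    x$occurrence, x$mean_trait_r, x$mean_weight_r
  ))
  invisible(x)
}

#' Split a hybrid component into its fMRI and EEG matrices
#'
#' @param rc A `robust_component` (or a bare hybrid trait vector of even,
#'   twice-triangular length).
#' @return List with `fmri_part` and `eeg_part` symmetric matrices.
#' @export
split_component <- function(rc) {
  v <- if (inherits(rc, "robust_component")) rc$trait else rc
  halves <- split_hybrid_vector(v)
  list(fmri_part = devectorize(halves$fmri), eeg_part = devectorize(halves$eeg))
}

#' Repeated-run connICA decomposition with stability selection
#'
#' The main decomposition entry point: reduces the hybrid matrix by PCA to
#' the requested explained-variance fraction, runs ICA `n_runs` times with
#' per-run seeds `base_seed + run index`, and stability-selects the robust
#' components.
#'
#' @param h A `hybrid_matrix` (or a `reduced_fc` if PCA was done already).
#' @param n_ics Number of ICs per run.
#' @param var_frac PCA explained-variance fraction (default 0.75).
#' @param n_runs Number of ICA runs (default 500).
#' @param base_seed Base seed; run r uses seed `base_seed + r`.
#' @param occurrence_thr,trait_thr,weight_thr Stability thresholds
#'   (default 0.75 each).
#' @param tol,max_iter FastICA convergence controls.
#' @return A `connica_fit`: `components` (list of `robust_component`),
#'   `reduced` (the `reduced_fc`), `n_runs`, `n_converged`, parameters, and
#'   the hybrid row/column metadata. `tidy()` returns the mixing weights in
#'   long form; `glance()` a one-row summary.
#' @export
run_connica <- function(h, n_ics, var_frac = 0.75, n_runs = 500L, base_seed = 1L,
                        occurrence_thr = 0.75, trait_thr = 0.75, weight_thr = 0.75,
                        tol = 1e-6, max_iter = 1000L) {
  if (n_runs < 2L) abort("`n_runs` must be >= 2.")
  red <- if (inherits(h, "reduced_fc")) h else pca_reduce(h, var_frac)
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    runs[[r]] <- ica_decompose(red, n_ics,
      seed = as.integer(base_seed) + r,
      tol = tol, max_iter = max_iter
    )
  }
  comps <- stability_select(runs,
    occurrence_thr = occurrence_thr,
    trait_thr = trait_thr, weight_thr = weight_thr
  )
  structure(
    list(
      components = comps,
      reduced = red,
      n_runs = as.integer(n_runs),
      n_converged = sum(vapply(runs, function(r) isTRUE(r$converged), logical(1))),
      n_ics = as.integer(n_ics),
      var_frac = red$var_frac_requested,
      base_seed = as.integer(base_seed),
      thresholds = c(
        occurrence = occurrence_thr, trait = trait_thr,
        weight = weight_thr
      ),
      row_meta = red$row_meta,
      col_meta = red$col_meta,
      n_regions = red$n_regions,
      band_order = red$band_order
    ),
    class = "connica_fit"
  )
}

#' @export
print.connica_fit <- function(x, ...) {
  cat(sprintf(
    "<connica_fit> %d robust components (%d/%d runs converged; var_frac %.2f -> %d PCs; %d ICs/run)\n",
    length(x$components), x$n_converged, x$n_runs,
    x$var_frac, x$reduced$n_components, x$n_ics
  ))
  for (i in seq_along(x$components)) {
    c_i <- x$components[[i]]
    cat(sprintf(
      "  [%d] occurrence %.2f, mean trait r %.3f, mean weight r %.3f\n",
      i, c_i$occurrence, c_i$mean_trait_r, c_i$mean_weight_r
    ))
  }
  invisible(x)
}

#' Extract one component's mixing weights as a subject-by-band matrix
#'
#' @param fit A `connica_fit`.
#' @param component 1-based component index.
#' @return Subject-by-band numeric matrix.
#' @export
component_weights <- function(fit, component = 1L) {
  stopifnot(inherits(fit, "connica_fit"))
  if (component < 1L || component > length(fit$components)) {
    abort(sprintf("`component` must be in 1..%d.", length(fit$components)))
  }
  if (is.null(fit$row_meta)) abort("fit carries no row metadata.")
  mixing_weight_matrix(fit$components[[component]]$weights, fit$row_meta)
}
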