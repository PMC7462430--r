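#' Cross-dataset parameter sweep
#'
#' Runs the full PCA + repeated-ICA + stability-selection procedure for
#' every combination of explained-variance fraction and IC count on two
#' datasets, matches the robust components across datasets by greedy
#' absolute trait correlation, and selects the common parameter cell that
#' maximizes the mean matched correlation (averaged over up to
#' `n_components` matched pairs and both modality parts, mirroring the
#' mean-of-diagonals selection over the tracked components). Tracked
#' components a cell fails to match contribute a correlation of zero to its
#' score, and cells in which either dataset yields no robust component score
#' 0 outright — the consistent-zero convention.
#'
#' @param dataset_a,dataset_b Connectome dataset tibbles (see
#'   [build_hybrid_matrix()]) or prebuilt `hybrid_matrix` objects sharing
#'   region count and band set.
#' @param var_fracs Grid of PCA explained-variance fractions
#'   (default `c(0.75, 0.80, 0.85, 0.90)`).
#' @param ic_counts Grid of IC counts (default `c(5, 10, 15, 20)`).
#' @param runs_per_cell ICA runs per dataset per cell (default 100).
#' @param base_seed Base seed; each (cell, dataset) gets a deterministic
#'   sub-seed.
#' @param n_components Number of matched component pairs that enter the
#'   selection score (default 2, the number of tracked components); `Inf`
#'   uses all matched pairs.
#' @param band_order Optional band order passed to the stacking step.
#' @param occurrence_thr,trait_thr,weight_thr Stability thresholds.
#' @return A `sweep_report`: `cells` (one row per grid cell: `var_frac`,
#'   `n_ics`, robust counts, `score`), `pairs` (one row per matched
#'   component pair per cell: signed `r_fmri`, `r_eeg`, `r_trait`),
#'   `selected` (the winning cell's row), and the two fits of the selected
#'   cell (`fit_a`, `fit_b`).
#' @export
sweep_parameters <- function(dataset_a, dataset_b,
                             var_fracs = c(0.75, 0.80, 0.85, 0.90),
                             ic_counts = c(5L, 10L, 15L, 20L),
                             runs_per_cell = 100L, base_seed = 1L,
                             n_components = 2L, band_order = NULL,
                             occurrence_thr = 0.75, trait_thr = 0.75,
                             weight_thr = 0.75) {
  if (length(var_fracs) == 0L || length(ic_counts) == 0L) abort("empty parameter grid.")
  as_hybrid <- function(d) {
    if (inherits(d, "hybrid_matrix")) d else build_hybrid_matrix(d, band_order = band_order)
  }
  ha <- as_hybrid(dataset_a)
  hb <- as_hybrid(dataset_b)
  if (ha$n_regions != hb$n_regions) abort("datasets differ in region count.")
  if (!identical(ha$band_order, hb$band_order)) abort("datasets differ in band set/order.")
  cells <- list()
  pairs <- list()
  best <- NULL
  cell_idx <- 0L
  for (vf in var_fracs) {
    red_a <- pca_reduce(ha, vf)
    red_b <- pca_reduce(hb, vf)
    for (ic in ic_counts) {
      cell_idx <- cell_idx + 1L
      fit_of <- function(red, which_ds) {
        if (ic > red$n_components) {
          return(NULL)
        }
        run_connica(red,
          n_ics = ic, n_runs = runs_per_cell,
          base_seed = sub_seed(base_seed, 2L * cell_idx + which_ds),
          occurrence_thr = occurrence_thr, trait_thr = trait_thr,
          weight_thr = weight_thr
        )
      }
      fit_a <- fit_of(red_a, 0L)
      fit_b <- fit_of(red_b, 1L)
      n_a <- if (is.null(fit_a)) 0L else length(fit_a$components)
      n_b <- if (is.null(fit_b)) 0L else length(fit_b$components)
      score <- 0
      n_matched <- 0L
      if (n_a > 0L && n_b > 0L) {
        ta <- do.call(rbind, lapply(fit_a$components, function(x) x$trait))
        tb <- do.call(rbind, lapply(fit_b$components, function(x) x$trait))
        mm <- match_runs(
          list(traits = ta, weights = matrix(0, 1, n_a)),
          list(traits = tb, weights = matrix(0, 1, n_b))
        )
        pr <- list()
        for (a in seq_len(n_a)) {
          b <- mm$match_idx[a]
          if (is.na(b)) next
          fa <- fit_a$components[[a]]
          fb <- fit_b$components[[b]]
          pr[[length(pr) + 1L]] <- tibble(
            var_frac = vf, n_ics = ic, component_a = a, component_b = b,
            r_trait = mm$trait_r[a],
            r_fmri = fast_cor(vectorize_upper(fa$fmri_part), vectorize_upper(fb$fmri_part)),
            r_eeg = fast_cor(vectorize_upper(fa$eeg_part), vectorize_upper(fb$eeg_part))
          )
        }
        if (length(pr)) {
          pr <- dplyr::bind_rows(pr)
          pr <- pr[order(-abs(pr$r_trait)), ]
          n_track <- if (is.finite(n_components)) n_components else nrow(pr)
          use <- head(pr, n = n_track)
          # tracked components that a cell fails to match contribute r = 0
          score <- sum(abs(use$r_fmri), abs(use$r_eeg)) / (2 * n_track)
          n_matched <- nrow(pr)
          pairs[[length(pairs) + 1L]] <- pr
        }
      }
      row <- tibble(
        var_frac = vf, n_ics = ic, n_robust_a = n_a, n_robust_b = n_b,
        n_matched = n_matched, score = score
      )
      cells[[length(cells) + 1L]] <- row
      if (is.null(best) || score > best$score) {
        best <- list(score = score, row = row, fit_a = fit_a, fit_b = fit_b)
      }
    }
  }
  structure(
    list(
      cells = dplyr::bind_rows(cells),
      pairs = if (length(pairs)) dplyr::bind_rows(pairs) else tibble(),
      selected = best$row,
      fit_a = best$fit_a,
      fit_b = best$fit_b
    ),
    class = "sweep_report"
  )
}

#' @export
print.sweep_report <- function(x, ...) {
  cat(sprintf(
    "<sweep_report> %d cells; selected var_frac = %.2f, n_ics = %d (score %.3f)\n",
    nrow(x$cells), x$selected$var_frac, x$selected$n_ics, x$selected$score
  ))
  invisible(x)
}
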