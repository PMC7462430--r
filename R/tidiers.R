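#' Tidy a connICA fit into long-form mixing weights
#'
#' @param x A `connica_fit`.
#' @param ... Unused.
#' @return A tibble with one row per (component, hybrid row): `component`,
#'   `subject_id`, `band`, `weight`.
#' @export
tidy.connica_fit <- function(x, ...) {
  if (length(x$components) == 0L) {
    return(tibble(
      component = integer(), subject_id = character(),
      band = character(), weight = numeric()
    ))
  }
  purrr::map_dfr(seq_along(x$components), function(i) {
    tibble(
      component = i,
      subject_id = x$row_meta$subject_id,
      band = x$row_meta$band,
      weight = x$components[[i]]$weights
    )
  })
}

#' One-row summary of a connICA fit
#'
#' @param x A `connica_fit`.
#' @param ... Unused.
#' @return A one-row tibble: component count, run counts, retained PCs,
#'   parameters, mean stability metrics.
#' @export
glance.connica_fit <- function(x, ...) {
  occ <- vapply(x$components, function(c) c$occurrence, numeric(1))
  tibble(
    n_components = length(x$components),
    n_runs = x$n_runs,
    n_converged = x$n_converged,
    n_pcs = x$reduced$n_components,
    var_frac = x$var_frac,
    n_ics = x$n_ics,
    mean_occurrence = if (length(occ)) mean(occ) else NA_real_,
    mean_trait_r = if (length(occ)) {
      mean(vapply(x$components, function(c) c$mean_trait_r, numeric(1)))
    } else {
      NA_real_
    }
  )
}
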