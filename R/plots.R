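# ggplot2 views of the main result types.

matrix_long <- function(m) {
  tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m)
  )
}

#' Heatmaps of a component's fMRI and EEG matrices
#'
#' @param fit A `connica_fit` (or a single `robust_component`).
#' @param component Component index when `fit` is a fit.
#' @return A ggplot (two facets: fMRI part, EEG part).
#' @export
plot_component <- function(fit, component = 1L) {
  rc <- if (inherits(fit, "connica_fit")) fit$components[[component]] else fit
  d <- dplyr::bind_rows(
    dplyr::mutate(matrix_long(rc$fmri_part), part = "fMRI part"),
    dplyr::mutate(matrix_long(rc$eeg_part), part = "EEG part")
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$col, .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~part) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "region", y = "region", fill = "weight") +
    ggplot2::theme_minimal()
}

#' Subject-by-band mixing-weight heatmap
#'
#' @inheritParams plot_component
#' @return A ggplot.
#' @export
plot_mixing_weights <- function(fit, component = 1L) {
  w <- component_weights(fit, component)
  d <- matrix_long(w)
  d$band <- factor(colnames(w)[d$col], levels = colnames(w))
  d$subject <- rownames(w)[d$row]
  ggplot2::ggplot(d, ggplot2::aes(.data$band, .data$subject, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b") +
    ggplot2::labs(x = "frequency band", y = "subject", fill = "weight") +
    ggplot2::theme_minimal()
}

#' Parameter-sweep consistency grid
#'
#' @param x A `sweep_report`.
#' @return A ggplot of the per-cell cross-dataset consistency score.
#' @export
plot_sweep <- function(x) {
  stopifnot(inherits(x, "sweep_report"))
  d <- x$cells
  ggplot2::ggplot(d, ggplot2::aes(factor(.data$n_ics), factor(.data$var_frac),
    fill = .data$score
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$score)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#b2182b", limits = c(0, 1)) +
    ggplot2::labs(
      x = "number of ICs", y = "PCA variance fraction",
      fill = "cross-dataset\nconsistency"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.modularity_test <- function(object, ...) {
  d <- tibble(null_Q = object$null_Q)
  ggplot2::ggplot(d, ggplot2::aes(.data$null_Q)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$Q, color = "#b2182b", linewidth = 1) +
    ggplot2::labs(
      x = "null modularity Q", y = "count",
      title = sprintf("observed Q = %.3g, p = %.3g", object$Q, object$p)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.connica_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$band, .data$weight, group = .data$subject_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::facet_wrap(~component, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "frequency band", y = "mixing weight") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
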