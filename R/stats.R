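#' Pearson correlation between two edge vectors or component parts
#'
#' Correlates two edge patterns (e.g. the fMRI and EEG halves of a hybrid
#' component, or matched components from two datasets). Square matrices are
#' vectorized over their upper triangles first; the two-sided p value comes
#' from the usual t approximation.
#'
#' @param x,y Numeric edge vectors of equal length (>= 3), or square
#'   symmetric matrices.
#' @return A one-row tibble: `r`, `p`, `n_edges`.
#' @export
edge_correlation <- function(x, y) {
  if (is.matrix(x)) x <- vectorize_upper(x)
  if (is.matrix(y)) y <- vectorize_upper(y)
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3L) abort("need at least 3 edges.")
  if (sd(x) == 0 || sd(y) == 0) abort("zero-variance input.")
  ct <- cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), p = ct$p.value, n_edges = length(x))
}

#' Spearman association between subject mixing weights and head motion
#'
#' Rank correlation (mid-rank ties) between a per-subject summary of mixing
#' weights and a per-subject motion summary (e.g. mean framewise
#' displacement), with a two-sided p value from the t approximation.
#'
#' @param subject_weights Per-subject numeric vector (e.g. row means of
#'   [mixing_weight_matrix()]).
#' @param motion Per-subject numeric vector, same length and order.
#' @return A one-row tibble: `rho`, `p`, `n_subjects`.
#' @export
motion_spearman <- function(subject_weights, motion) {
  if (length(subject_weights) != length(motion)) abort("inputs must be paired.")
  if (length(subject_weights) < 4L) abort("need at least 4 subjects.")
  if (sd(subject_weights) == 0 || sd(motion) == 0) abort("constant input.")
  ct <- suppressWarnings(
    cor.test(subject_weights, motion, method = "spearman", exact = FALSE)
  )
  tibble(rho = unname(ct$estimate), p = ct$p.value, n_subjects = length(motion))
}

#' Top-percentile edges and their module-pair counts
#'
#' Selects the strongest connections of a component part and summarizes how
#' they distribute over module pairs. `mode = "edge"` ranks edges by their
#' own weight; `mode = "nodal"` ranks edges by the summed strength of their
#' two endpoint nodes. The threshold is the linear-interpolation percentile
#' of the ranking statistic over all upper-triangle edges; selection uses
#' `>=` by default so exact ties at the threshold are kept.
#'
#' @param part_matrix Square symmetric numeric matrix.
#' @param partition Module labels, see [as_partition()].
#' @param percentile Percentile threshold in (0, 100), default 99.
#' @param mode `"edge"` (edge-weight ranking) or `"nodal"` (endpoint
#'   strength-sum ranking).
#' @param strict If `TRUE`, use `>` instead of `>=` at the threshold.
#' @return A list of class `top_edges`: `edges` (tibble `i`, `j`, `weight`,
#'   `stat`, `module_i`, `module_j`) and `module_counts` (module x module
#'   symmetric count matrix whose upper triangle + diagonal sums to the
#'   number of selected edges).
#' @export
top_edges <- function(part_matrix, partition, percentile = 99,
                      mode = c("edge", "nodal"), strict = FALSE) {
  mode <- match.arg(mode)
  m <- unclass(as.matrix(part_matrix))
  check_symmetric(m, "part_matrix")
  part <- as_partition(partition, nrow(m))
  et <- edge_index_table(nrow(m))
  w <- vectorize_upper(m)
  stat <- if (mode == "edge") {
    w
  } else {
    s <- rowSums(abs(m))
    s[et$i] + s[et$j]
  }
  thr <- quantile(stat, probs = percentile / 100, type = 7, names = FALSE)
  keep <- if (strict) stat > thr else stat >= thr
  if (!any(keep)) {
    warn("no edges selected at the requested percentile (degenerate ties under strict mode).")
  }
  edges <- tibble(
    i = et$i[keep], j = et$j[keep], weight = w[keep], stat = stat[keep],
    module_i = as.character(part[et$i[keep]]),
    module_j = as.character(part[et$j[keep]])
  )
  mods <- levels(part)
  counts <- matrix(0L, length(mods), length(mods), dimnames = list(mods, mods))
  for (k in seq_len(nrow(edges))) {
    a <- edges$module_i[k]
    b <- edges$module_j[k]
    counts[a, b] <- counts[a, b] + 1L
    if (a != b) counts[b, a] <- counts[b, a] + 1L
  }
  structure(list(edges = edges, module_counts = counts, threshold = thr, mode = mode),
    class = "top_edges"
  )
}

#' @export
print.top_edges <- function(x, ...) {
  cat(sprintf(
    "<top_edges> %d edges at threshold %.4g (%s mode)\n",
    nrow(x$edges), x$threshold, x$mode
  ))
  invisible(x)
}
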