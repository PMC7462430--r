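#' One-way random-effects intraclass correlation of mixing weights
#'
#' Quantifies how much of the variance of a subject-by-band mixing-weight
#' matrix is attributable to subjects (`grouping = "subject"`: units are
#' subjects, bands are the repeated ratings) or to frequency bands
#' (`grouping = "band"`: the transposed layout). Uses the one-way
#' random-effects form
#' \deqn{ICC(1) = \frac{MS_B - MS_W}{MS_B + (k - 1)\,MS_W}}
#' with the one-way ANOVA F test \eqn{F = MS_B / MS_W} on
#' \eqn{(n - 1,\; n(k - 1))} degrees of freedom (n units, k ratings each).
#' ICC(1) can be negative (down to \eqn{-1/(k-1)}) when units agree less than
#' chance.
#'
#' @param weights Numeric subject-by-band matrix (rows = subjects, columns =
#'   bands), e.g. from [mixing_weight_matrix()].
#' @param grouping `"subject"` or `"band"` — which dimension defines the
#'   units whose agreement is measured.
#' @return A one-row tibble: `grouping`, `icc`, `f_stat`, `df_between`,
#'   `df_within`, `p`, `n_units`, `n_ratings`.
#' @examples
#' w <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3, byrow = TRUE)
#' icc_oneway(w, "subject")
#' @export
icc_oneway <- function(weights, grouping = c("subject", "band")) {
  grouping <- match.arg(grouping)
  w <- as.matrix(weights)
  if (grouping == "band") w <- t(w)
  n <- nrow(w) # units
  k <- ncol(w) # ratings per unit
  if (n < 2L) abort("need at least 2 units after grouping.")
  if (k < 2L) abort("need at least 2 ratings per unit after grouping.")
  if (anyNA(w)) abort("`weights` contains missing values.")
  row_means <- rowMeans(w)
  grand <- mean(w)
  ss_between <- k * sum((row_means - grand)^2)
  ss_within <- sum((w - row_means)^2)
  df_b <- n - 1L
  df_w <- n * (k - 1L)
  ms_b <- ss_between / df_b
  ms_w <- ss_within / df_w
  if (ms_b == 0 && ms_w == 0) abort("all weights identical: ICC is undefined (0/0).")
  icc <- (ms_b - ms_w) / (ms_b + (k - 1) * ms_w)
  f_stat <- ms_b / ms_w
  p <- stats::pf(f_stat, df_b, df_w, lower.tail = FALSE)
  tibble(
    grouping = grouping, icc = icc, f_stat = f_stat,
    df_between = df_b, df_within = df_w, p = p,
    n_units = n, n_ratings = k
  )
}

#' Reshape a component's mixing weights to a subject-by-band matrix
#'
#' @param weights Length-R numeric vector of mixing weights, one per hybrid
#'   row, or a `robust_component`.
#' @param row_meta Tibble with `subject_id` and `band` per hybrid row (e.g.
#'   `h$row_meta` or `fit$row_meta`); ignored when `weights` is taken from a
#'   fit via [component_weights()].
#' @return Subject-by-band numeric matrix (subjects in first-appearance
#'   order, bands in the hybrid band order).
#' @export
mixing_weight_matrix <- function(weights, row_meta) {
  if (inherits(weights, "robust_component")) weights <- weights$weights
  stopifnot(length(weights) == nrow(row_meta))
  subjects <- unique(row_meta$subject_id)
  bands <- unique(row_meta$band)
  m <- matrix(NA_real_, length(subjects), length(bands),
    dimnames = list(subjects, bands)
  )
  m[cbind(
    match(row_meta$subject_id, subjects),
    match(row_meta$band, bands)
  )] <- weights
  m
}
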