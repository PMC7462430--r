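#' Edge indexing for upper-triangle vectorization
#'
#' The fixed edge ordering used everywhere in the package: row-major upper
#' triangle (1,2), (1,3), ..., (1,n), (2,3), ..., (n-1,n).
#'
#' @param n_regions Number of regions.
#' @return A tibble with columns `edge`, `i`, `j` (1-based region indices,
#'   i < j), `n_regions(n_regions - 1)/2` rows.
#' @export
edge_index_table <- function(n_regions) {
  if (n_regions < 2L) abort("need at least 2 regions.")
  i <- rep.int(seq_len(n_regions - 1L), times = (n_regions - 1L):1L)
  j <- unlist(lapply(seq_len(n_regions - 1L), function(k) seq.int(k + 1L, n_regions)))
  tibble(edge = seq_along(i), i = i, j = j)
}

#' Vectorize the upper triangle of a connectome
#'
#' @param c_mat Square symmetric matrix (or `connectome`).
#' @param tol Symmetry tolerance.
#' @return Numeric vector of length `n(n-1)/2` in row-major upper-triangle
#'   order.
#' @examples
#' vectorize_upper(matrix(0, 4, 4)) # length 6
#' @export
vectorize_upper <- function(c_mat, tol = 1e-9) {
  m <- unclass(as.matrix(c_mat))
  check_symmetric(m, "c_mat", tol = tol)
  t(m)[lower.tri(m)]
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' Inverse of [vectorize_upper()]: fills the upper triangle in row-major
#' order, mirrors it, and zeroes the diagonal.
#'
#' @param v Edge vector whose length is a triangular number `n(n-1)/2`.
#' @return An `n x n` symmetric numeric matrix with zero diagonal.
#' @export
devectorize <- function(v) {
  e <- length(v)
  n <- (1 + sqrt(1 + 8 * e)) / 2
  if (e < 1L || abs(n - round(n)) > 1e-9) {
    abort(sprintf("length %d is not a triangular number n(n-1)/2.", e))
  }
  n <- as.integer(round(n))
  m <- matrix(0, n, n)
  mt <- matrix(0, n, n)
  mt[lower.tri(mt)] <- v
  m <- t(mt)
  m + mt
}

#' Assemble the hybrid (subject x band) by (fMRI || EEG) matrix
#'
#' Stacks, for every subject `s` and band `b`, the row
#' `[vec(FC_fmri(s)) || vec(FC_eeg(s, b))]`. The fMRI edge block is repeated
#' across all of a subject's band rows; rows are ordered subject-major,
#' band-minor following `band_order`; columns are all fMRI edges followed by
#' all EEG edges.
#'
#' @param dataset A tibble with columns `subject_id`, `modality`
#'   (`"fmri"` or an EEG modality), `band`, and `conn` (list-column of
#'   square symmetric matrices), e.g. from [simulate_dataset()] or
#'   [load_dataset()]. Every subject needs exactly one fMRI connectome and
#'   one EEG connectome per band.
#' @param band_order Character vector fixing the band (row) order; defaults
#'   to the bands present, in `eeg_bands()` order where applicable.
#' @return A `hybrid_matrix`: list with `values` (R x 2E matrix),
#'   `row_meta` (tibble `row`, `subject_id`, `band`), `col_meta` (tibble
#'   `col`, `modality`, `i`, `j`), `n_regions`, `band_order`, `subjects`.
#' @export
build_hybrid_matrix <- function(dataset, band_order = NULL) {
  stopifnot(is.data.frame(dataset))
  need <- c("subject_id", "modality", "band", "conn")
  if (!all(need %in% names(dataset))) {
    abort(sprintf("`dataset` must have columns %s.", paste(need, collapse = ", ")))
  }
  fmri <- dataset[dataset$modality == "fmri", ]
  eeg <- dataset[dataset$modality != "fmri", ]
  subjects <- unique(dataset$subject_id)
  if (is.null(band_order)) {
    present <- unique(eeg$band)
    canon <- eeg_bands()$band
    band_order <- c(intersect(canon, present), setdiff(present, canon))
  }
  n_set <- unique(vapply(dataset$conn, nrow, integer(1)))
  if (length(n_set) != 1L) abort("inconsistent region counts across connectomes.")
  n <- n_set
  e_len <- n * (n - 1L) / 2L
  for (s in subjects) {
    if (sum(fmri$subject_id == s) != 1L) {
      abort(sprintf("subject '%s' must have exactly one fMRI connectome.", s))
    }
    for (b in band_order) {
      if (sum(eeg$subject_id == s & eeg$band == b) != 1L) {
        abort(sprintf("missing or duplicated EEG connectome for (subject '%s', band '%s').", s, b))
      }
    }
  }
  n_rows <- length(subjects) * length(band_order)
  values <- matrix(NA_real_, n_rows, 2L * e_len)
  row_meta <- tibble(
    row = seq_len(n_rows),
    subject_id = rep(subjects, each = length(band_order)),
    band = rep(band_order, times = length(subjects))
  )
  for (s_idx in seq_along(subjects)) {
    s <- subjects[s_idx]
    v_f <- vectorize_upper(fmri$conn[[which(fmri$subject_id == s)]])
    for (b_idx in seq_along(band_order)) {
      b <- band_order[b_idx]
      v_e <- vectorize_upper(eeg$conn[[which(eeg$subject_id == s & eeg$band == b)]])
      r <- (s_idx - 1L) * length(band_order) + b_idx
      values[r, ] <- c(v_f, v_e)
    }
  }
  et <- edge_index_table(n)
  col_meta <- tibble(
    col = seq_len(2L * e_len),
    modality = rep(c("fmri", "eeg"), each = e_len),
    i = rep(et$i, 2L),
    j = rep(et$j, 2L)
  )
  structure(
    list(
      values = values, row_meta = row_meta, col_meta = col_meta,
      n_regions = n, band_order = band_order, subjects = subjects
    ),
    class = "hybrid_matrix"
  )
}

#' @export
print.hybrid_matrix <- function(x, ...) {
  cat(sprintf(
    "<hybrid_matrix> %d rows (%d subjects x %d bands) x %d columns (2 x %d edges, %d regions)\n",
    nrow(x$values), length(x$subjects), length(x$band_order),
    ncol(x$values), ncol(x$values) / 2, x$n_regions
  ))
  invisible(x)
}

# Split a hybrid column vector into its fMRI and EEG edge halves.
split_hybrid_vector <- function(v) {
  c2 <- length(v)
  if (c2 %% 2L != 0L) abort("hybrid vector length must be even (fMRI || EEG halves).")
  e <- c2 %/% 2L
  list(fmri = v[seq_len(e)], eeg = v[seq.int(e + 1L, c2)])
}
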