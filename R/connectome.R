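#' Connectome objects
#'
#' A connectome is a square, symmetric region-by-region weight matrix with a
#' zero diagonal, tagged with its modality (`"fmri"`, `"eeg_raw_icoh"`, or
#' `"eeg_harmonized"`), an optional frequency band name, and a subject id.
#' Raw imaginary-coherency connectomes live in \[0, 1\]; fMRI and harmonized
#' EEG connectomes are correlation-like and nominally live in \[-1, 1\]
#' (simulated trait matrices may exceed that range, so the range check warns
#' rather than errors unless `strict = TRUE`).
#'
#' @param weights Square symmetric numeric matrix; the diagonal is forced to 0.
#' @param modality One of `"fmri"`, `"eeg_raw_icoh"`, `"eeg_harmonized"`.
#' @param band Optional band name (e.g. `"gamma"`); `NA` for fMRI.
#' @param subject_id Subject identifier string.
#' @param strict If `TRUE`, range violations are errors instead of warnings.
#' @param check_range If `FALSE`, skip the range check for correlation-like
#'   modalities (simulated trait-sum matrices are weights, not correlations);
#'   the \[0, 1\] check for raw imaginary coherency always applies.
#' @return A `connectome` object (numeric matrix with metadata attributes).
#' @examples
#' m <- matrix(c(0, .5, .5, 0), 2, 2)
#' connectome(m, "fmri", subject_id = "s01")
#' @export
connectome <- function(weights, modality = c("fmri", "eeg_raw_icoh", "eeg_harmonized"),
                       band = NA_character_, subject_id = "", strict = FALSE,
                       check_range = TRUE) {
  modality <- match.arg(modality)
  check_symmetric(weights, "weights")
  diag(weights) <- 0
  if (!check_range && modality != "eeg_raw_icoh") {
    return(structure(weights,
      class = c("connectome", "matrix", "array"),
      modality = modality, band = as.character(band), subject_id = subject_id
    ))
  }
  rng <- suppressWarnings(range(weights, na.rm = TRUE))
  bad <- if (modality == "eeg_raw_icoh") {
    rng[1] < 0 || rng[2] > 1
  } else {
    rng[1] < -1 - 1e-9 || rng[2] > 1 + 1e-9
  }
  if (isTRUE(bad)) {
    msg <- sprintf(
      "connectome values outside the nominal range for modality '%s': [%.4g, %.4g]",
      modality, rng[1], rng[2]
    )
    if (modality == "eeg_raw_icoh" || strict) abort(msg) else warn(msg)
  }
  structure(weights,
    class = c("connectome", "matrix", "array"),
    modality = modality, band = as.character(band), subject_id = subject_id
  )
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf(
    "<connectome> %d x %d, modality = %s, band = %s, subject = %s\n",
    nrow(x), ncol(x), attr(x, "modality"),
    attr(x, "band") %||% NA, attr(x, "subject_id")
  ))
  invisible(x)
}

#' Canonical EEG frequency bands
#'
#' Delta 0.5-4 Hz, theta 4-8 Hz, alpha 8-12 Hz, beta 12-30 Hz and gamma
#' 30-60 Hz, in the fixed delta-to-gamma order used throughout the package.
#'
#' @return A tibble with columns `band`, `low`, `high` (Hz).
#' @export
eeg_bands <- function() {
  tibble(
    band = c("delta", "theta", "alpha", "beta", "gamma"),
    low = c(0.5, 4, 8, 12, 30),
    high = c(4, 8, 12, 30, 60)
  )
}

#' Pearson functional connectivity from region time series
#'
#' Computes the sample Pearson correlation between every pair of regional
#' time courses (the standard fMRI functional-connectivity estimator) and
#' stores the result as a `connectome` with a zero diagonal.
#'
#' @param ts Time-by-region numeric matrix (or data frame); column names are
#'   used as region labels when present.
#' @param subject_id Subject identifier carried into the result.
#' @return A `connectome` with modality `"fmri"`.
#' @examples
#' x <- matrix(rnorm(200), 50, 4)
#' pearson_fc(x)
#' @export
pearson_fc <- function(ts, subject_id = "") {
  ts <- as.matrix(ts)
  if (nrow(ts) < 2L || ncol(ts) < 2L) {
    abort("`ts` needs at least 2 time points and 2 regions.")
  }
  if (anyNA(ts)) abort("`ts` contains missing values.")
  sds <- apply(ts, 2L, sd)
  if (any(sds == 0)) {
    labs <- colnames(ts) %||% as.character(seq_len(ncol(ts)))
    abort(sprintf(
      "zero-variance region(s): %s",
      paste(labs[sds == 0], collapse = ", ")
    ))
  }
  w <- cor(ts)
  w <- (w + t(w)) / 2
  connectome(w, "fmri", subject_id = subject_id)
}

#' Band-limited imaginary coherency from epoched time series
#'
#' For every epoch each regional signal is Hann-tapered and Fourier
#' transformed; cross-spectra are pooled over the frequency bins inside the
#' requested band and normalized into a complex coherency
#' \eqn{C_{ij} = S_{ij} / \sqrt{S_{ii} S_{jj}}}. The signed imaginary part is
#' averaged over epochs and the absolute value taken at the end, so the null
#' level shrinks with the number of epochs while genuine phase-lagged
#' coupling is retained; set `abs_before_average = TRUE` to take the absolute
#' value per epoch instead. Values lie in \[0, 1\]; zero-lag (volume
#' conducted) coupling contributes nothing.
#'
#' @param epochs Numeric array `epoch x sample x region`.
#' @param band Length-2 numeric `c(low, high)` in Hz, inside Nyquist.
#' @param sampling_rate Sampling rate in Hz.
#' @param band_name Optional band label stored on the result.
#' @param subject_id Subject identifier.
#' @param abs_before_average Take `|Im C|` per epoch before averaging.
#' @return A `connectome` with modality `"eeg_raw_icoh"`.
#' @export
band_icoh <- function(epochs, band, sampling_rate, band_name = NA_character_,
                      subject_id = "", abs_before_average = FALSE) {
  if (length(dim(epochs)) != 3L) abort("`epochs` must be an epoch x sample x region array.")
  n_epoch <- dim(epochs)[1]
  n_samp <- dim(epochs)[2]
  n_reg <- dim(epochs)[3]
  if (n_epoch < 1L) abort("need at least one epoch.")
  if (length(band) != 2L || band[1] >= band[2]) abort("`band` must be c(low, high) with low < high.")
  if (band[2] > sampling_rate / 2) abort("band upper edge exceeds the Nyquist frequency.")
  freqs <- (seq_len(n_samp) - 1L) * sampling_rate / n_samp
  bins <- which(freqs >= band[1] & freqs <= band[2] & freqs > 0 & freqs <= sampling_rate / 2)
  if (length(bins) == 0L) {
    abort(sprintf(
      "no frequency bins in [%g, %g] Hz for %d samples at %g Hz (resolution %g Hz).",
      band[1], band[2], n_samp, sampling_rate, sampling_rate / n_samp
    ))
  }
  taper <- 0.5 - 0.5 * cos(2 * pi * seq(0, n_samp - 1) / n_samp) # Hann
  acc <- matrix(0, n_reg, n_reg)
  for (e in seq_len(n_epoch)) {
    x <- epochs[e, , , drop = TRUE]
    x <- matrix(x, n_samp, n_reg)
    x <- sweep(x, 2L, colMeans(x)) * taper
    X <- stats::mvfft(x)[bins, , drop = FALSE]
    cross <- crossprod(Conj(X), X) # S_ij pooled over in-band bins
    pow <- Re(diag(cross))
    pow[pow <= 0] <- .Machine$double.eps
    coh <- cross / sqrt(outer(pow, pow))
    im <- Im(coh)
    acc <- acc + if (abs_before_average) abs(im) else im
  }
  out <- acc / n_epoch
  if (!abs_before_average) out <- abs(out)
  out <- (out + t(out)) / 2
  out <- pmin(out, 1)
  diag(out) <- 0
  connectome(out, "eeg_raw_icoh", band = band_name, subject_id = subject_id)
}

#' Range-harmonize an imaginary-coherency connectome
#'
#' Maps an EEG imaginary-coherency connectome (range \[0, 1\]) into a
#' correlation-like matrix (range \[-1, 1\]) so it can be stacked with fMRI
#' Pearson connectomes: entry (i, j) is the Pearson correlation between rows
#' i and j of the input, computed over the n - 2 columns that exclude i and j
#' themselves (a matching-index-style similarity; set
#' `exclude = "none"` to correlate full rows).
#'
#' @param c_icoh A `connectome` of modality `"eeg_raw_icoh"` (or plain
#'   symmetric matrix), n >= 4.
#' @param exclude `"pair"` (default) drops columns i and j before
#'   correlating; `"none"` uses all columns.
#' @param permissive If `TRUE`, a zero-variance row yields `NaN` with a
#'   warning instead of an error.
#' @return A `connectome` with modality `"eeg_harmonized"`.
#' @export
harmonize_eeg <- function(c_icoh, exclude = c("pair", "none"), permissive = FALSE) {
  exclude <- match.arg(exclude)
  check_symmetric(unclass(c_icoh), "c_icoh")
  n <- nrow(c_icoh)
  if (n < 4L) abort("harmonization needs at least 4 regions.")
  m <- unclass(c_icoh)
  out <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      keep <- if (exclude == "pair") setdiff(seq_len(n), c(i, j)) else seq_len(n)
      r <- fast_cor(m[i, keep], m[j, keep])
      if (is.na(r)) {
        msg <- sprintf("row %d or %d has zero variance over the retained columns.", i, j)
        if (permissive) {
          warn(msg)
          r <- NaN
        } else {
          abort(msg)
        }
      }
      out[i, j] <- r
      out[j, i] <- r
    }
  }
  connectome(out,
    modality = "eeg_harmonized",
    band = attr(c_icoh, "band") %||% NA_character_,
    subject_id = attr(c_icoh, "subject_id") %||% ""
  )
}
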