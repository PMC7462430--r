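# Internal helpers shared across modules.

# Deterministic sub-seed derived from a base seed and a counter; kept within
# 32-bit integer range so set.seed() always accepts it.
sub_seed <- function(base_seed, counter) {
  as.integer((as.numeric(base_seed) + 100003 * as.numeric(counter)) %% 2147483647L)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name, lower, upper, x))
  }
  invisible(x)
}

check_symmetric <- function(m, name = "matrix", tol = 1e-9) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    abort(sprintf("`%s` must be a square matrix.", name))
  }
  d <- abs(m - t(m))
  d[is.na(d)] <- 0 # NaN entries (permissive undefined values) mirror by construction
  if (max(d) > tol) {
    abort(sprintf("`%s` is not symmetric (tolerance %g).", name, tol))
  }
  invisible(m)
}

# Pearson correlation between two vectors without cor()'s NA handling overhead;
# returns NA if either side is constant.
fast_cor <- function(x, y) {
  if (length(x) < 2L) {
    return(NA_real_)
  }
  sx <- sd(x)
  sy <- sd(y)
  if (sx == 0 || sy == 0) {
    return(NA_real_)
  }
  mean((x - mean(x)) * (y - mean(y))) * length(x) / (length(x) - 1) / (sx * sy)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
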