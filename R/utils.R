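# Internal helpers shared across modules.

# Reverse cumulative sum of a vector or the columns of a matrix: entry i
# holds the sum over rows i..n. Used for Cox risk-set sums on data sorted
# by increasing follow-up time.
revcumsum <- function(x) {
  if (is.matrix(x)) {
    n <- nrow(x)
    out <- apply(x[n:1L, , drop = FALSE], 2L, cumsum)
    if (!is.matrix(out)) out <- matrix(out, nrow = n)
    out[n:1L, , drop = FALSE]
  } else {
    rev(cumsum(rev(x)))
  }
}

# Deterministic substream seeds derived from one user-facing seed, so the
# generator's independent components (covariates, event times, censoring,
# calibration vs. validation draws) are individually reproducible.
# Kept strictly inside 32-bit integer range.
substream_seed <- function(seed, stream, k = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647
  s <- (abs(seed) %% m) * 48271 + stream * 1000003 + k * 7919
  as.integer(s %% m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
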