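#' @useDynLib slscgcnr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd fft mvfft median
#' @importFrom utils write.csv read.csv
NULL

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.  Every stochastic operation in the package funnels through
# this; no function relies on the global seed.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic seed splitting: child k of a master seed.  Linear
# congruential mix keeps results in the 32-bit signed range required by
# set.seed().
split_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647) + 1
  for (i in seq_len(2L)) s <- (s * 48271) %% 2147483647
  as.integer((s + 7919 * as.double(k)) %% 2147483647)
}

stop_if_not_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(x)
}

#' Analytic signal along the columns of a matrix
#'
#' Computes the complex analytic signal (signal + i * Hilbert transform)
#' of each column via the one-sided FFT construction. The magnitude of the
#' analytic signal is the conventional envelope detector for beamformed RF.
#'
#' @param x numeric matrix; columns are treated as time series (depth axis).
#' @return complex matrix of the same dimension.
#' @export
analytic_signal <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  X <- mvfft(x) * h
  mvfft(X, inverse = TRUE) / n
}

# Zero-phase band-pass filter along columns, flat over
# [f0 (1 - bw/2), f0 (1 + bw/2)] with raised-cosine edges. Used to confine
# synthetic element signals to the probe passband.
bandpass_columns <- function(x, fs, f0, fractional_bw = 0.6) {
  x <- as.matrix(x)
  n <- nrow(x)
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)             # two-sided spectrum, symmetric response
  lo <- f0 * (1 - fractional_bw / 2)
  hi <- f0 * (1 + fractional_bw / 2)
  roll <- 0.15 * f0                # transition width
  up <- ramp01((f - (lo - roll)) / roll)
  down <- ramp01(((hi + roll) - f) / roll)
  H <- pmin(up, down)
  Re(mvfft(mvfft(x) * H, inverse = TRUE)) / n
}

ramp01 <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  0.5 - 0.5 * cos(pi * u)
}

# Symmetric Toeplitz matrix from its first row.
toeplitz_psd <- function(first_row) {
  stats::toeplitz(first_row)
}

format_mm <- function(x) sprintf("%.2f mm", x)
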