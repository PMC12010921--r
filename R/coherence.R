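#' Short-lag spatial coherence parameters
#'
#' @param M short-lag cutoff: coherence is summed over element
#'   separations `1..M`. Default 7, i.e. 10% of a 64-element receive
#'   aperture.
#' @param kernel_samples axial correlation kernel length in samples.
#'   The default is one wavelength of two-way RF travel,
#'   `round(2 * fs / f0)` = 6 samples at the default probe.
#' @param probe probe used only to derive the default kernel length.
#' @return an object of class `coherence_params`.
#' @export
coherence_params <- function(M = 7L, kernel_samples = NULL,
                             probe = probe_config()) {
  stop_if_not_scalar_num(M, "M", positive = TRUE)
  if (is.null(kernel_samples))
    kernel_samples <- round(2 * probe$sampling_frequency /
                              probe$center_frequency)
  stop_if_not_scalar_num(kernel_samples, "kernel_samples", positive = TRUE)
  if (M >= probe$n_receive)
    stop("M must be smaller than the receive aperture size", call. = FALSE)
  structure(list(M = as.integer(M),
                 kernel_samples = as.integer(kernel_samples)),
            class = "coherence_params")
}

#' @export
print.coherence_params <- function(x, ...) {
  cat(sprintf("coherence_params: M = %d, kernel = %d samples\n",
              x$M, x$kernel_samples))
  invisible(x)
}

# Kernel rows [n1, n2] centred on pixel row n; errors if outside trace.
kernel_span <- function(n, klen, n_rows) {
  lo <- (klen - 1L) %/% 2L
  n1 <- n - lo
  n2 <- n1 + klen - 1L
  if (n1 < 1L || n2 > n_rows)
    stop("correlation kernel extends outside the trace", call. = FALSE)
  n1:n2
}

#' Spatial coherence function at one pixel
#'
#' The normalised cross-correlation between element pairs separated by
#' lag `m`, averaged over the `N - m` pairs, computed over an axial
#' kernel centred on the pixel. Each element's kernel mean is subtracted
#' first (the coherence is defined on zero-mean signals). Pairs in which
#' either kernel has zero energy contribute 0.
#'
#' @param aligned delay-aligned `channel_data`.
#' @param pixel integer pair `(depth row, scan line)`.
#' @param params a [coherence_params()].
#' @return an object of class `coherence_function`: values `R̂(m)` for
#'   `m = 1..M`, each in `[-1, 1]`.
#' @export
coherence_function <- function(aligned, pixel, params = coherence_params()) {
  stopifnot(inherits(aligned, "channel_data"))
  if (!isTRUE(aligned$aligned))
    stop("coherence_function needs delay-aligned data", call. = FALSE)
  N <- dim(aligned$rf)[2]
  if (N < 2) stop("need at least 2 element channels", call. = FALSE)
  rows <- kernel_span(pixel[1], params$kernel_samples, dim(aligned$rf)[1])
  s <- aligned$rf[rows, , pixel[2], drop = FALSE][, , 1]
  s <- sweep(s, 2, colMeans(s))                 # zero-mean per element
  energy <- colSums(s^2)
  R <- numeric(params$M)
  for (m in seq_len(params$M)) {
    i <- seq_len(N - m)
    den <- energy[i] * energy[i + m]
    num <- colSums(s[, i, drop = FALSE] * s[, i + m, drop = FALSE])
    r <- ifelse(den > 0, num / sqrt(den), 0)
    R[m] <- mean(r)
  }
  structure(list(values = R, M = params$M, pixel = pixel,
                 kernel_samples = params$kernel_samples),
            class = "coherence_function")
}

#' @export
print.coherence_function <- function(x, ...) {
  cat(sprintf("coherence_function at pixel (%d, %d), kernel %d samples:\n",
              x$pixel[1], x$pixel[2], x$kernel_samples))
  print(round(stats::setNames(x$values, paste0("m=", seq_len(x$M))), 4))
  invisible(x)
}

#' Offline SLSC image
#'
#' Per pixel, the spatial coherence function is summed over lags
#' `1..M` and negative pixels are set to zero; pixels therefore lie in
#' `[0, M]`. Operates on real RF with per-kernel mean subtraction (the
#' offline formulation). Edge rows whose kernel does not fit are 0.
#'
#' @param aligned delay-aligned `channel_data`.
#' @param params a [coherence_params()].
#' @return a `beamformed_image` of kind `"slsc_offline"`.
#' @export
slsc_offline <- function(aligned, params = coherence_params()) {
  stopifnot(inherits(aligned, "channel_data"))
  if (!isTRUE(aligned$aligned))
    stop("slsc_offline needs delay-aligned data", call. = FALSE)
  d <- dim(aligned$rf)
  px <- matrix(0, d[1], d[3])
  for (l in seq_len(d[3]))
    px[, l] <- cpp_slsc_offline(aligned$rf[, , l], params$M,
                                params$kernel_samples, TRUE)
  new_beamformed_image(px, "slsc_offline", aligned,
                       params = list(M = params$M,
                                     kernel_samples = params$kernel_samples,
                                     pathway = "offline"))
}

#' Naive reference implementation of the offline SLSC pixel
#'
#' Direct nested-loop transcription of the coherence-function average and
#' short-lag sum, kept deliberately independent of the production code
#' path for oracle-equivalence testing. Slow; use on small fixtures only.
#'
#' @inheritParams slsc_offline
#' @param clip_negative set negative pixels to zero (the display
#'   convention); default TRUE.
#' @return numeric matrix of SLSC pixel values.
#' @export
slsc_offline_reference <- function(aligned, params = coherence_params(),
                                   clip_negative = TRUE) {
  d <- dim(aligned$rf)
  klen <- params$kernel_samples
  lo <- (klen - 1L) %/% 2L
  out <- matrix(0, d[1], d[3])
  for (l in seq_len(d[3])) {
    for (n in seq_len(d[1])) {
      n1 <- n - lo; n2 <- n1 + klen - 1L
      if (n1 < 1L || n2 > d[1]) next
      val <- 0
      for (m in seq_len(params$M)) {
        acc <- 0
        for (i in seq_len(d[2] - m)) {
          si <- aligned$rf[n1:n2, i, l]; si <- si - mean(si)
          sj <- aligned$rf[n1:n2, i + m, l]; sj <- sj - mean(sj)
          den <- sum(si^2) * sum(sj^2)
          if (den > 0) acc <- acc + sum(si * sj) / sqrt(den)
        }
        val <- val + acc / (d[2] - m)
      }
      out[n, l] <- if (clip_negative && val < 0) 0 else val
    }
  }
  out
}

#' Kernel-summed correlation accumulators of the real-time formulation
#'
#' For one scan line, computes the per-depth cross-correlation `C_ij`
#' and the leading/trailing energies `C_ii`, `C_jj` summed over the
#' `N - m` element pairs at each lag, then sums each over the axial
#' kernel. The traces are first converted to analytic signals along
#' depth (the conjugate in the cross term implies complex data); no mean
#' subtraction is applied, matching the real-time formulation.
#'
#' @param aligned delay-aligned `channel_data`.
#' @param pixel_column scan-line index.
#' @param params a [coherence_params()].
#' @return an object of class `lag_sums`: complex matrix `C_ij` and
#'   non-negative matrices `C_ii`, `C_jj`, each `n_depth x M`,
#'   kernel-summed. Rows whose kernel does not fit are NA.
#' @export
lag_sums <- function(aligned, pixel_column, params = coherence_params()) {
  stopifnot(inherits(aligned, "channel_data"))
  if (!isTRUE(aligned$aligned))
    stop("lag_sums needs delay-aligned data", call. = FALSE)
  s <- analytic_signal(aligned$rf[, , pixel_column])
  terms <- cpp_lag_terms(s, params$M)
  klen <- params$kernel_samples
  structure(list(C_ij = kernel_sum(terms$C_ij, klen),
                 C_ii = kernel_sum(terms$C_ii, klen),
                 C_jj = kernel_sum(terms$C_jj, klen),
                 M = params$M, kernel_samples = klen,
                 pixel_column = pixel_column),
            class = "lag_sums")
}

# Centred moving sum of length klen along the rows of a matrix; rows
# where the window does not fit are NA.
kernel_sum <- function(x, klen) {
  n <- nrow(x)
  lo <- (klen - 1L) %/% 2L
  hi <- klen - 1L - lo
  cs <- apply(x, 2, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, ncol = ncol(x))
  out <- matrix(NA_real_, n, ncol(x))
  if (is.complex(x)) out <- matrix(NA_complex_, n, ncol(x))
  rows <- seq(lo + 1L, n - hi)
  top <- cs[rows + hi, , drop = FALSE]
  bot <- rbind(matrix(0, 1, ncol(x)), cs)[rows - lo, , drop = FALSE]
  out[rows, ] <- top - bot
  out
}

#' Real-time (GPU-formulation) SLSC image
#'
#' Per pixel and lag, the kernel-summed cross-correlation is normalised
#' by the geometric mean of the kernel-summed pair energies
#' (sum-then-normalise, the reverse order of the offline formulation),
#' the real part of the ratio is taken, and the ratios are summed over
#' lags `1..M`. Zero denominators yield a 0 term; negative pixels are
#' clipped to 0 so both pathways share the display convention.
#'
#' @param aligned delay-aligned `channel_data`.
#' @param params a [coherence_params()].
#' @return a `beamformed_image` of kind `"slsc_realtime"`.
#' @export
slsc_realtime <- function(aligned, params = coherence_params()) {
  stopifnot(inherits(aligned, "channel_data"))
  if (!isTRUE(aligned$aligned))
    stop("slsc_realtime needs delay-aligned data", call. = FALSE)
  d <- dim(aligned$rf)
  px <- matrix(0, d[1], d[3])
  for (l in seq_len(d[3])) {
    ls <- lag_sums(aligned, l, params)
    den <- sqrt(ls$C_ii * ls$C_jj)
    ratio <- Re(ls$C_ij) / den
    ratio[!is.finite(ratio)] <- 0            # zero denominators / edges
    v <- rowSums(ratio)
    v[v < 0] <- 0
    px[, l] <- v
  }
  new_beamformed_image(px, "slsc_realtime", aligned,
                       params = list(M = params$M,
                                     kernel_samples = params$kernel_samples,
                                     pathway = "realtime"))
}
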