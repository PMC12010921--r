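#' Dynamic receive-focusing delay table for one scan line
#'
#' For a pixel at depth `z` on the scan-line axis, the echo reaches an
#' element offset laterally by `d` after `(z + sqrt(z^2 + d^2)) / c`
#' seconds (focused transmit down the line axis plus the exact return
#' path). Delays are returned in fractional samples at the probe
#' sampling frequency.
#'
#' @param probe a [probe_config()].
#' @param depth_grid strictly increasing positive depths in mm.
#' @param scanline scan-line index (1-based).
#' @return a `delay_table`: matrix `length(depth_grid) x n_receive` of
#'   delays in samples, with the aperture element indices as an attribute.
#' @export
receive_delays <- function(probe, depth_grid, scanline) {
  stopifnot(inherits(probe, "probe_config"))
  if (any(depth_grid <= 0) || any(diff(depth_grid) <= 0))
    stop("depth_grid must be strictly increasing and positive", call. = FALSE)
  idx <- receive_aperture_indices(probe, scanline)
  xl <- scanline_positions(probe)[scanline]
  d <- element_positions(probe)[idx] - xl               # mm
  z <- depth_grid                                       # mm
  c_mm <- probe$sound_speed * 1e3
  tau <- outer(z, d, function(zz, dd) (zz + sqrt(zz^2 + dd^2)) / c_mm)
  delays <- tau * probe$sampling_frequency
  structure(delays, class = c("delay_table", "matrix"),
            aperture_idx = idx, depth_grid = depth_grid,
            scanline = scanline)
}

#' Apply receive-focusing delays to raw channel data
#'
#' Resamples each element's raw trace at its per-depth delay (dynamic
#' receive focusing) with linear interpolation for fractional samples.
#' Raw sample 1 is taken at time 0. Delays falling outside the recorded
#' trace are zero-filled and flagged in the metadata.
#'
#' @param data a raw (`aligned = FALSE`) `channel_data` object.
#' @param delays optional explicit delay table: a matrix
#'   `n_out x n_receive` of absolute arrival positions in fractional
#'   samples (0-based, as returned by [receive_delays()]), applied to
#'   every scan line, or a list of such matrices (one per line). When
#'   `NULL`, geometric dynamic-receive delays are computed per line.
#' @param depth_grid depths (mm) of the output pixel rows; defaults to
#'   one row per RF sample up to the recorded depth. Ignored when
#'   `delays` is supplied (rows then follow the supplied table).
#' @return a delay-aligned `channel_data` whose `rf[n, i, l]` is element
#'   `i`'s contribution to the pixel at `depth_grid[n]` on line `l`.
#' @export
apply_delays <- function(data, delays = NULL, depth_grid = NULL) {
  stopifnot(inherits(data, "channel_data"))
  if (isTRUE(data$aligned))
    stop("channel data are already delay-aligned", call. = FALSE)
  probe <- data$probe
  n_raw <- dim(data$rf)[1]
  n_lines <- dim(data$rf)[3]
  N <- dim(data$rf)[2]
  if (!is.null(delays)) {
    if (is.matrix(delays) || inherits(delays, "delay_table"))
      delays <- rep(list(unclass(delays)), n_lines)
    stopifnot(is.list(delays), length(delays) == n_lines)
    n_out <- nrow(delays[[1]])
    if (is.null(depth_grid)) depth_grid <- seq_len(n_out)  # row index grid
  } else {
    if (is.null(depth_grid)) {
      dz <- probe$sound_speed * 1e3 / (2 * probe$sampling_frequency)  # mm
      zmax <- if (!is.null(data$field_extent))
        data$field_extent$axial[2] else n_raw * dz
      depth_grid <- seq(dz, zmax, by = dz)
    }
    n_out <- length(depth_grid)
  }
  out <- array(0, dim = c(n_out, N, n_lines))
  truncated <- FALSE
  for (l in seq_len(n_lines)) {
    dl <- if (!is.null(delays)) delays[[l]] else
      unclass(receive_delays(probe, depth_grid, l))
    for (i in seq_len(N)) {
      u <- dl[, i]                           # fractional sample, 0-based
      lo <- floor(u)
      w <- u - lo
      ok <- lo >= 0 & lo < (n_raw - 1)
      if (any(!ok)) truncated <- TRUE
      v <- numeric(n_out)
      tr <- data$rf[, i, l]
      v[ok] <- tr[lo[ok] + 1L] * (1 - w[ok]) + tr[lo[ok] + 2L] * w[ok]
      out[, i, l] <- v
    }
  }
  res <- data
  res$rf <- out
  res$aligned <- TRUE
  res$depth_grid <- depth_grid
  res$truncated <- truncated
  res
}

#' Delay-and-sum B-mode image
#'
#' Sums the delay-aligned traces across the receive aperture per pixel,
#' then detects the envelope as the magnitude of the analytic signal
#' along the depth axis.
#'
#' @param aligned a delay-aligned `channel_data`.
#' @return a `beamformed_image` of kind `"bmode_envelope"` (pre-log,
#'   pre-normalisation pixel values).
#' @export
das_bmode <- function(aligned) {
  stopifnot(inherits(aligned, "channel_data"))
  if (!isTRUE(aligned$aligned))
    stop("das_bmode needs delay-aligned channel data; see apply_delays()",
         call. = FALSE)
  summed <- apply(aligned$rf, c(1, 3), sum)
  env <- Mod(analytic_signal(summed))
  new_beamformed_image(env, "bmode_envelope", aligned)
}

new_beamformed_image <- function(pixels, kind, aligned, params = NULL) {
  dz <- if (!is.null(aligned$depth_grid) && length(aligned$depth_grid) > 1)
    diff(aligned$depth_grid[1:2]) else
    aligned$probe$sound_speed * 1e3 / (2 * aligned$probe$sampling_frequency)
  structure(list(pixels = pixels, kind = kind,
                 depth_grid = aligned$depth_grid,
                 lines_x = aligned$lines_x,
                 dz = dz, dx = aligned$probe$pitch,
                 probe = aligned$probe, params = params,
                 seed = aligned$seed),
            class = "beamformed_image")
}

#' @export
print.beamformed_image <- function(x, ...) {
  cat(sprintf("beamformed_image [%s]: %d x %d pixels, dz %.3f mm, dx %.3f mm\n",
              x$kind, nrow(x$pixels), ncol(x$pixels), x$dz, x$dx))
  if (!is.null(x$params) && !is.null(x$params$M))
    cat(sprintf("  SLSC params: M = %d, kernel = %d samples\n",
                x$params$M, x$params$kernel_samples))
  invisible(x)
}

#' @export
plot.beamformed_image <- function(x, dynamic_range = 60, ...) {
  disp <- render_display(x, dynamic_range)
  nz <- nrow(disp$pixels)
  z <- if (!is.null(x$depth_grid)) x$depth_grid else seq_len(nz) * x$dz
  graphics::image(x$lines_x, z, t(disp$pixels[nz:1, , drop = FALSE])[, nz:1],
                  col = grDevices::gray.colors(256, 0, 1), ylim = rev(range(z)),
                  xlab = "lateral (mm)", ylab = "depth (mm)",
                  main = x$kind, useRaster = TRUE, ...)
  invisible(x)
}

#' Log-compressed display image
#'
#' Normalises to the image maximum and log-compresses:
#' `20 log10(pixels / max)`, clipped to `[-dynamic_range, 0]` dB.
#'
#' @param img a `beamformed_image` with non-negative pixels.
#' @param dynamic_range display dynamic range in dB (default 60).
#' @return a `display_image` (dB values in `[-dynamic_range, 0]`).
#' @export
render_display <- function(img, dynamic_range = 60) {
  stopifnot(inherits(img, "beamformed_image"))
  stop_if_not_scalar_num(dynamic_range, "dynamic_range", positive = TRUE)
  px <- img$pixels
  if (any(px < 0)) stop("display rendering expects non-negative pixels",
                        call. = FALSE)
  mx <- max(px)
  if (mx <= 0) stop("cannot render an all-zero image", call. = FALSE)
  db <- 20 * log10(px / mx)
  db[!is.finite(db)] <- -Inf
  db <- pmax(db, -dynamic_range)
  structure(list(pixels = db, dynamic_range = dynamic_range,
                 source_kind = img$kind, depth_grid = img$depth_grid,
                 lines_x = img$lines_x, dz = img$dz, dx = img$dx),
            class = "display_image")
}

#' @export
print.display_image <- function(x, ...) {
  cat(sprintf("display_image: %d x %d pixels, %g dB dynamic range (from %s)\n",
              nrow(x$pixels), ncol(x$pixels), x$dynamic_range, x$source_kind))
  invisible(x)
}

#' 8-bit screenshot surrogate of a display image
#'
#' Linearly maps `[-dynamic_range, 0]` dB to integers `0..255`
#' (round-half-up), emulating the grayscale raster a clinical screenshot
#' would store. Proprietary scanner display filters are deliberately not
#' modelled.
#'
#' @param disp a `display_image`.
#' @return a `screenshot_raster`: integer matrix in `[0, 255]` plus the
#'   display mapping used.
#' @export
render_screenshot <- function(disp) {
  stopifnot(inherits(disp, "display_image"))
  v <- (disp$pixels + disp$dynamic_range) / disp$dynamic_range * 255
  r <- floor(v + 0.5)                         # round half up
  r[r < 0] <- 0; r[r > 255] <- 255
  structure(list(pixels = matrix(as.integer(r), nrow(disp$pixels)),
                 dynamic_range = disp$dynamic_range,
                 source_kind = disp$source_kind,
                 depth_grid = disp$depth_grid, lines_x = disp$lines_x,
                 dz = disp$dz, dx = disp$dx),
            class = "screenshot_raster")
}

#' @export
print.screenshot_raster <- function(x, ...) {
  cat(sprintf("screenshot_raster: %d x %d, 8-bit grayscale (%g dB mapping, from %s)\n",
              nrow(x$pixels), ncol(x$pixels), x$dynamic_range, x$source_kind))
  invisible(x)
}

#' Screenshot grayscale values as double precision
#'
#' Casts the 8-bit raster to real values in `[0, 255]` with no inverse
#' log mapping: the pseudo-real-time gCNR pathway operates directly on
#' screenshot grayscale, as acquired.
#'
#' @param raster a `screenshot_raster`.
#' @return numeric matrix in `[0, 255]`.
#' @export
screenshot_to_intensity <- function(raster) {
  stopifnot(inherits(raster, "screenshot_raster"))
  px <- raster$pixels
  storage.mode(px) <- "double"
  px
}
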