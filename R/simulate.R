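#' Simulate raw RF channel data from a scatterer field
#'
#' Single-scattering simulator for a linear array with a walking receive
#' aperture. Per scan line, each of the `n_receive` aperture elements
#' records the sum over scatterers of a Gaussian-modulated sinusoid placed
#' at the two-way delay (focused-transmit time `z/c` plus the exact
#' element-to-scatterer return path), with transmit weighting by a
#' focused Gaussian beam profile whose width is diffraction-limited at the
#' focus and spreads geometrically away from it. iid electronic noise and
#' a fully element-coherent clutter waveform (per [noise_spec()]) are then
#' added, both scaled relative to the RMS of the clean tissue RF.
#'
#' @param field a [make_phantom()] scatterer field.
#' @param probe a [probe_config()].
#' @param focus_depth transmit focal depth in mm; must lie within the
#'   phantom's axial extent.
#' @param noise a [noise_spec()].
#' @param seed integer seed for the noise draws.
#' @param fractional_bw fractional bandwidth of the transmit pulse.
#' @return an object of class `channel_data`: raw RF array
#'   `rf[sample, element, scanline]` plus geometry metadata
#'   (`aligned = FALSE`).
#' @export
simulate_channel_data <- function(field, probe, focus_depth,
                                  noise = noise_spec(), seed,
                                  fractional_bw = 0.6) {
  stopifnot(inherits(field, "scatterer_field"),
            inherits(probe, "probe_config"),
            inherits(noise, "noise_spec"))
  stop_if_not_scalar_num(focus_depth, "focus_depth", positive = TRUE)
  if (focus_depth < field$extent$axial[1] ||
      focus_depth > field$extent$axial[2])
    stop("focus_depth must lie within the phantom's axial extent",
         call. = FALSE)

  c_mm <- probe$sound_speed * 1e3            # mm/s
  fs <- probe$sampling_frequency
  osr <- 4L                                  # echo-deposition oversampling
  zmax <- field$extent$axial[2]
  aperture_mm <- probe$n_receive * probe$pitch
  # longest two-way path: deepest scatterer to the farthest aperture element
  tmax <- (zmax + sqrt(zmax^2 + aperture_mm^2)) / c_mm
  pulse <- pulse_table(probe, fractional_bw, osr = osr)
  n_samples <- stats::nextn(ceiling(tmax * fs + 2 * pulse$half_len) + 1L,
                            c(2L, 3L, 5L))
  n_over <- n_samples * osr
  # circular pulse kernel centred at index 1 for FFT convolution
  kern <- numeric(n_over)
  hl_over <- (length(pulse$table) - 1L) %/% 2L
  kern[1:(hl_over + 1L)] <- pulse$table[(hl_over + 1L):length(pulse$table)]
  kern[(n_over - hl_over + 1L):n_over] <- pulse$table[1:hl_over]
  kern_f <- fft(kern)
  guard <- ceiling(2 * pulse$half_len)       # wrap-around guard, RF samples

  lines_x <- scanline_positions(probe)
  n_lines <- probe$n_scanlines
  ex_all <- element_positions(probe)
  rf <- array(0, dim = c(n_samples, probe$n_receive, n_lines))
  aperture_idx <- matrix(0L, probe$n_receive, n_lines)

  keep0 <- field$amplitude != 0
  sx0 <- field$x[keep0]; sz0 <- field$z[keep0]; sa0 <- field$amplitude[keep0]
  sigma_z <- tx_beam_sigma(sz0, focus_depth, probe, aperture_mm)

  for (l in seq_len(n_lines)) {
    idx <- receive_aperture_indices(probe, l)
    aperture_idx[, l] <- idx
    dep <- cpp_deposit_echoes(sx0, sz0, sa0, sigma_z, lines_x[l], 0.01,
                              ex_all[idx], c_mm, fs * osr, n_over)
    conv <- Re(mvfft(mvfft(dep) * kern_f, inverse = TRUE)) / n_over
    tr <- conv[seq(1L, n_over, by = osr), , drop = FALSE]
    tr[c(seq_len(guard), seq(n_samples - guard + 1L, n_samples)), ] <- 0
    rf[, , l] <- tr
  }

  tissue_rms <- sqrt(mean(rf^2))
  if (tissue_rms == 0) tissue_rms <- 1       # empty phantom: unit reference
  sigma_n <- tissue_rms * 10^(-noise$electronic_snr_db / 20)
  a_c <- tissue_rms * 10^(noise$clutter_amplitude_db / 20)
  if (sigma_n > 0 || a_c > 0) {
    rf <- rf + with_seed(seed, {
      pert <- array(0, dim = dim(rf))
      if (sigma_n > 0)
        pert <- pert + array(rnorm(length(rf), sd = sigma_n), dim = dim(rf))
      if (a_c > 0) {
        for (l in seq_len(n_lines)) {
          w <- bandpass_columns(matrix(rnorm(n_samples), ncol = 1),
                                fs, probe$center_frequency, fractional_bw)
          w <- w / sqrt(mean(w^2)) * a_c
          pert[, , l] <- pert[, , l] + matrix(w, n_samples, probe$n_receive)
        }
      }
      pert
    })
  }

  structure(list(rf = rf, probe = probe, focus_depth = focus_depth,
                 noise = noise, aligned = FALSE, seed = seed,
                 tissue_rms = tissue_rms, lines_x = lines_x,
                 aperture_idx = aperture_idx,
                 field_extent = field$extent,
                 truncated = FALSE),
            class = "channel_data")
}

# Gaussian-modulated transmit pulse sampled on an oversampled grid
# covering +/- 4 envelope standard deviations (in RF samples).
pulse_table <- function(probe, fractional_bw = 0.6, osr = 16L) {
  f0 <- probe$center_frequency
  fs <- probe$sampling_frequency
  sigma_f <- fractional_bw * f0 / 2.355      # -6 dB FWHM -> Gaussian sd
  sigma_t <- 1 / (2 * pi * sigma_f)
  hl_over <- ceiling(4 * sigma_t * fs * osr) # integer half-length, oversampled
  t <- (-hl_over:hl_over) / (fs * osr)
  list(table = exp(-t^2 / (2 * sigma_t^2)) * cos(2 * pi * f0 * t),
       half_len = hl_over / osr, osr = as.integer(osr), sigma_t = sigma_t)
}

# Lateral sd (mm) of the focused Gaussian transmit beam at depth z:
# diffraction-limited waist at the focus plus geometric convergence of
# the full aperture away from it.
tx_beam_sigma <- function(z, focus_depth, probe, aperture_mm) {
  lambda <- probe_wavelength_mm(probe)
  sigma_f <- lambda * focus_depth / aperture_mm / 2.355
  sigma_geo <- (aperture_mm / 4) * abs(1 - z / focus_depth)
  sqrt(sigma_f^2 + sigma_geo^2)
}

#' @export
print.channel_data <- function(x, ...) {
  d <- dim(x$rf)
  cat(sprintf(
    "channel_data: %d samples x %d elements x %d scan lines (%s)\n",
    d[1], d[2], d[3], if (x$aligned) "delay-aligned" else "raw"))
  cat(sprintf("  fs %.1f MHz, focus %s, seed %s\n",
              x$probe$sampling_frequency / 1e6,
              if (is.null(x$focus_depth)) "-" else format_mm(x$focus_depth),
              format(x$seed)))
  invisible(x)
}

#' Analytic coherence fixture with a prescribed lag profile
#'
#' Generates delay-aligned, zero-mean Gaussian element signals whose
#' cross-element correlation at lag `m` equals `profile[m + 1]`
#' (with `profile[1]` the lag-0 value, normally 1), by factorising the
#' Toeplitz covariance of the profile. Signals are band-limited axially
#' to the probe passband. This is the reference object for validating the
#' coherence estimator against the van Cittert-Zernike expectation
#' (profile `1 - m/N` for diffuse scattering and a rectangular aperture).
#'
#' @param profile numeric vector of target correlations for lags
#'   `0 .. length(profile) - 1` (entry 1 is the lag-0 value, normally 1);
#'   profiles shorter than `n_elements` are continued at their last
#'   value. The implied Toeplitz matrix must be positive semi-definite.
#' @param n_elements number of element channels.
#' @param n_samples axial samples per channel.
#' @param seed integer seed.
#' @param probe a [probe_config()] supplying the passband for the axial
#'   band-limiting.
#' @param fractional_bw width of the axial band-limiting as a fraction
#'   of the center frequency. The default (1.2) models the receive
#'   passband, wider than the 60% transmit pulse; a whiter fixture keeps
#'   more independent samples per correlation kernel, which conditions
#'   the finite-kernel coherence estimate.
#' @return a delay-aligned `channel_data` object with a single scan line.
#' @seealso [vcz_profile()]
#' @export
make_coherence_fixture <- function(profile, n_elements = 64L,
                                   n_samples = 2000L, seed,
                                   probe = probe_config(),
                                   fractional_bw = 1.2) {
  stopifnot(is.numeric(profile), length(profile) >= 1)
  if (length(profile) < n_elements)
    profile <- c(profile, rep(profile[length(profile)],
                              n_elements - length(profile)))
  profile <- profile[seq_len(n_elements)]
  cov <- toeplitz_psd(profile)
  ev <- eigen(cov, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values)))
    stop(sprintf(
      "profile is not a valid correlation sequence: smallest eigenvalue of its Toeplitz matrix is %.3g",
      min(ev$values)), call. = FALSE)
  lam <- pmax(ev$values, 0)
  root <- ev$vectors %*% (sqrt(lam) * t(ev$vectors))   # symmetric sqrt
  z <- with_seed(seed, matrix(rnorm(n_samples * n_elements),
                              n_samples, n_elements))
  s <- z %*% root                                       # cov(s) = Toeplitz
  s <- bandpass_columns(s, probe$sampling_frequency,
                        probe$center_frequency, fractional_bw)
  rf <- array(s, dim = c(n_samples, n_elements, 1L))
  structure(list(rf = rf, probe = probe, focus_depth = NULL,
                 noise = NULL, aligned = TRUE, seed = seed,
                 tissue_rms = sqrt(mean(s^2)), lines_x = 0,
                 aperture_idx = matrix(seq_len(n_elements), ncol = 1),
                 field_extent = NULL, truncated = FALSE),
            class = "channel_data")
}

#' Van Cittert-Zernike triangle coherence profile
#'
#' The theoretical receive-aperture spatial coherence of diffuse
#' scattering at the transmit focus for an unapodized rectangular
#' aperture of `n` elements: `1 - m/n` at element lag `m`.
#'
#' @param n aperture size in elements.
#' @return numeric vector of length `n` (lags `0 .. n-1`), floored at 0.
#' @export
vcz_profile <- function(n) pmax(1 - (0:(n - 1)) / n, 0)

#' Simulate a cohort of masses with known ground-truth content
#'
#' One phantom and one raw channel-data acquisition per mass. Lesion
#' sizes and depths are randomised within configured ranges; solid-mass
#' echogenicity gains are drawn uniformly so that the cohort spans
#' near-isoechoic through markedly hypoechoic solids (the masses that
#' mimic cysts on B-mode); mixed masses are a fluid ellipse containing
#' 1-3 solid septa. The transmit focus is placed at the lesion depth.
#'
#' @param n_fluid,n_solid,n_mixed counts per ground-truth class.
#' @param probe a [probe_config()].
#' @param noise a [noise_spec()].
#' @param seed master integer seed; per-mass seeds are split
#'   deterministically from it.
#' @param semi_axis_range range (mm) for lesion semi-axes.
#' @param depth_range range (mm) for lesion center depths.
#' @param solid_gain_range range of solid echogenicity gains.
#' @param axial_extent axial (depth) extent of each phantom in mm.
#' @return a list with class `mass_cohort`: element `masses` is a list of
#'   `list(channel = channel_data, record = one-row data.frame)`;
#'   element `manifest` is the ground-truth table.
#' @export
make_cohort <- function(n_fluid, n_solid, n_mixed,
                        probe = probe_config(),
                        noise = noise_spec(), seed,
                        semi_axis_range = c(1.8, 3.2),
                        depth_range = c(12, 18),
                        solid_gain_range = c(0.35, 0.85),
                        axial_extent = c(4, 24)) {
  stopifnot(n_fluid >= 0, n_solid >= 0, n_mixed >= 0)
  classes <- c(rep("fluid", n_fluid), rep("solid", n_solid),
               rep("mixed", n_mixed))
  masses <- vector("list", length(classes))
  rows <- vector("list", length(classes))
  for (k in seq_along(classes)) {
    sk <- split_seed(seed, k)
    geom <- with_seed(sk, list(
      a = runif(1, semi_axis_range[1], semi_axis_range[2]),
      b = runif(1, semi_axis_range[1], semi_axis_range[2]),
      cx = runif(1, -2, 2),
      cz = runif(1, depth_range[1], depth_range[2]),
      gain = runif(1, solid_gain_range[1], solid_gain_range[2]),
      n_septa = sample(1:3, 1),
      u = runif(8)))
    les <- switch(classes[k],
      fluid = lesion_spec(c(geom$cx, geom$cz), c(geom$a, geom$b), "fluid"),
      solid = lesion_spec(c(geom$cx, geom$cz), c(geom$a, geom$b),
                          "solid_benign", echogenicity_gain = geom$gain),
      mixed = {
        septa <- lapply(seq_len(geom$n_septa), function(j) {
          ang <- 2 * pi * geom$u[j]
          lesion_spec(c(geom$cx + 0.45 * geom$a * cos(ang),
                        geom$cz + 0.45 * geom$b * sin(ang)),
                      c(geom$a, geom$b) * 0.28, "solid_benign",
                      echogenicity_gain = 0.6)
        })
        lesion_spec(c(geom$cx, geom$cz), c(geom$a, geom$b), "mixed",
                    septa = septa)
      })
    field <- make_phantom(probe, list(les), density = 10,
                          seed = split_seed(sk, 1),
                          axial_extent = axial_extent)
    chan <- simulate_channel_data(field, probe, focus_depth = geom$cz,
                                  noise = noise, seed = split_seed(sk, 2))
    rows[[k]] <- data.frame(mass_id = sprintf("mass%03d", k),
                            content_class = classes[k],
                            center_lat_mm = geom$cx, center_ax_mm = geom$cz,
                            semi_lat_mm = geom$a, semi_ax_mm = geom$b,
                            echogenicity_gain =
                              if (classes[k] == "solid") geom$gain else 0,
                            seed = sk)
    masses[[k]] <- list(channel = chan, lesion = les, record = rows[[k]])
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mass_id = character(), content_class = character(),
               center_lat_mm = numeric(), center_ax_mm = numeric(),
               semi_lat_mm = numeric(), semi_ax_mm = numeric(),
               echogenicity_gain = numeric(), seed = integer())
  structure(list(masses = masses, manifest = manifest, seed = seed),
            class = "mass_cohort")
}

#' @export
print.mass_cohort <- function(x, ...) {
  tab <- table(x$manifest$content_class)
  cat(sprintf("mass_cohort: %d masses (%s), master seed %s\n",
              nrow(x$manifest),
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", "),
              format(x$seed)))
  invisible(x)
}
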