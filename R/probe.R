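#' Linear-array probe and acquisition configuration
#'
#' Describes the transducer and sampling geometry used throughout the
#' package. Defaults emulate a high-frequency linear array with a walking
#' 64-element receive aperture: 128 elements total, 12.5 MHz center
#' frequency, 40 MHz sampling, 1540 m/s sound speed.
#'
#' @param n_elements_total total physical elements in the array.
#' @param n_receive number of elements in the walking receive aperture (N).
#' @param pitch element pitch in mm.
#' @param center_frequency transmit center frequency in Hz.
#' @param sampling_frequency RF sampling frequency in Hz; must exceed twice
#'   the center frequency.
#' @param sound_speed speed of sound in m/s.
#' @param n_scanlines number of receive scan lines per image. The default
#'   (64) is a desk-scale grid; 256 reproduces the full clinical line count.
#'
#' @return an object of class `probe_config`.
#' @examples
#' probe_config()
#' probe_config(n_scanlines = 16)
#' @export
probe_config <- function(n_elements_total = 128L,
                         n_receive = 64L,
                         pitch = 0.3,
                         center_frequency = 12.5e6,
                         sampling_frequency = 40e6,
                         sound_speed = 1540,
                         n_scanlines = 64L) {
  stop_if_not_scalar_num(n_elements_total, "n_elements_total", positive = TRUE)
  stop_if_not_scalar_num(n_receive, "n_receive", positive = TRUE)
  stop_if_not_scalar_num(pitch, "pitch", positive = TRUE)
  stop_if_not_scalar_num(center_frequency, "center_frequency", positive = TRUE)
  stop_if_not_scalar_num(sampling_frequency, "sampling_frequency", positive = TRUE)
  stop_if_not_scalar_num(sound_speed, "sound_speed", positive = TRUE)
  stop_if_not_scalar_num(n_scanlines, "n_scanlines", positive = TRUE)
  if (n_receive > n_elements_total)
    stop("n_receive must not exceed n_elements_total", call. = FALSE)
  if (sampling_frequency <= 2 * center_frequency)
    stop("sampling_frequency must exceed twice the center frequency",
         call. = FALSE)
  structure(list(
    n_elements_total = as.integer(n_elements_total),
    n_receive = as.integer(n_receive),
    pitch = pitch,
    center_frequency = center_frequency,
    sampling_frequency = sampling_frequency,
    sound_speed = sound_speed,
    n_scanlines = as.integer(n_scanlines)
  ), class = "probe_config")
}

#' @export
print.probe_config <- function(x, ...) {
  cat("Linear-array probe configuration\n")
  cat(sprintf("  elements: %d total, %d receive (walking aperture)\n",
              x$n_elements_total, x$n_receive))
  cat(sprintf("  pitch: %s   center: %.1f MHz   sampling: %.1f MHz\n",
              format_mm(x$pitch), x$center_frequency / 1e6,
              x$sampling_frequency / 1e6))
  cat(sprintf("  sound speed: %.0f m/s   scan lines: %d\n",
              x$sound_speed, x$n_scanlines))
  invisible(x)
}

# Wavelength in mm at the probe center frequency.
probe_wavelength_mm <- function(probe) {
  probe$sound_speed / probe$center_frequency * 1e3
}

# Lateral positions (mm) of all physical elements, array centered at 0.
element_positions <- function(probe) {
  (seq_len(probe$n_elements_total) - 1 -
     (probe$n_elements_total - 1) / 2) * probe$pitch
}

# Lateral positions (mm) of the scan lines: the central n_scanlines
# element positions, so every line's walking aperture fits in the array.
scanline_positions <- function(probe) {
  (seq_len(probe$n_scanlines) - 1 -
     (probe$n_scanlines - 1) / 2) * probe$pitch
}

# Indices (into the physical array) of the n_receive elements whose
# aperture is centred on scan line `line`; errors if out of bounds.
receive_aperture_indices <- function(probe, line) {
  xl <- scanline_positions(probe)[line]
  xe <- element_positions(probe)
  ctr <- which.min(abs(xe - xl))
  lo <- ctr - (probe$n_receive %/% 2L) +
    ifelse(probe$n_receive %% 2L == 0L, 1L, 0L)
  idx <- seq(lo, length.out = probe$n_receive)
  if (idx[1] < 1L || idx[probe$n_receive] > probe$n_elements_total)
    stop(sprintf(
      "receive aperture for scan line %d exceeds the array bounds", line),
      call. = FALSE)
  idx
}

#' Specification of an elliptical lesion
#'
#' @param center numeric length-2, (lateral, axial) center in mm.
#' @param semi_axes numeric length-2, (lateral, axial) semi-axes in mm.
#' @param content_class one of `"fluid"`, `"solid_benign"`,
#'   `"solid_malignant"`, `"mixed"`, `"simple_cyst"`.
#' @param echogenicity_gain linear multiplier applied to scatterer
#'   amplitudes inside the lesion; 0 for fluid content (no backscatter).
#' @param septa for `"mixed"` lesions only: a list of solid `lesion_spec`
#'   sub-ellipses embedded in the fluid ellipse.
#' @return an object of class `lesion_spec`.
#' @examples
#' lesion_spec(c(0, 15), c(3, 2), "fluid")
#' lesion_spec(c(2, 12), c(2.5, 2), "solid_benign", echogenicity_gain = 0.4)
#' @export
lesion_spec <- function(center, semi_axes, content_class,
                        echogenicity_gain = if (content_class %in%
                          c("fluid", "simple_cyst", "mixed")) 0 else 0.5,
                        septa = NULL) {
  content_class <- match.arg(content_class,
    c("fluid", "solid_benign", "solid_malignant", "mixed", "simple_cyst"))
  stopifnot(length(center) == 2L, length(semi_axes) == 2L)
  if (any(!is.finite(center)) || any(!is.finite(semi_axes)) ||
      any(semi_axes <= 0))
    stop("lesion center must be finite and semi_axes positive", call. = FALSE)
  stop_if_not_scalar_num(echogenicity_gain, "echogenicity_gain")
  if (echogenicity_gain < 0)
    stop("echogenicity_gain must be >= 0", call. = FALSE)
  if (content_class %in% c("fluid", "simple_cyst") && echogenicity_gain != 0)
    stop("fluid and simple_cyst lesions must have echogenicity_gain = 0",
         call. = FALSE)
  if (!is.null(septa)) {
    stopifnot(is.list(septa))
    lapply(septa, function(s)
      if (!inherits(s, "lesion_spec")) stop("septa must be lesion_spec objects"))
  }
  structure(list(center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes),
                 content_class = content_class,
                 echogenicity_gain = echogenicity_gain,
                 septa = septa),
            class = "lesion_spec")
}

#' @export
print.lesion_spec <- function(x, ...) {
  cat(sprintf("lesion_spec: %s at (%.1f, %.1f) mm, semi-axes (%.1f, %.1f) mm, gain %.2f",
              x$content_class, x$center[1], x$center[2],
              x$semi_axes[1], x$semi_axes[2], x$echogenicity_gain))
  if (!is.null(x$septa)) cat(sprintf(", %d septa", length(x$septa)))
  cat("\n")
  invisible(x)
}

#' Channel noise specification
#'
#' Two additive interference components, both expressed in dB relative to
#' the RMS of the clean tissue RF on a channel: `electronic_snr_db` sets
#' iid per-element thermal noise (a channel SNR of 20 dB means the noise
#' RMS is 10 dB amplitude = 0.1 of the tissue RF RMS), and
#' `clutter_amplitude_db` sets a fully element-coherent interference
#' waveform (identical across elements within a scan line) emulating
#' diffuse acoustic clutter that fills anechoic regions on B-mode.
#'
#' @param electronic_snr_db channel SNR of the iid electronic noise, dB.
#'   `Inf` disables the noise.
#' @param clutter_amplitude_db clutter amplitude relative to tissue RF rms,
#'   dB. `-Inf` disables the clutter.
#' @return an object of class `noise_spec`.
#' @examples
#' noise_spec()                       # defaults: 20 dB SNR, -25 dB clutter
#' noise_spec(electronic_snr_db = Inf, clutter_amplitude_db = -Inf)  # clean
#' @export
noise_spec <- function(electronic_snr_db = 20,
                       clutter_amplitude_db = -25) {
  if (!is.numeric(electronic_snr_db) || length(electronic_snr_db) != 1L ||
      is.na(electronic_snr_db))
    stop("electronic_snr_db must be a numeric scalar", call. = FALSE)
  if (!is.numeric(clutter_amplitude_db) || length(clutter_amplitude_db) != 1L ||
      is.na(clutter_amplitude_db))
    stop("clutter_amplitude_db must be a numeric scalar", call. = FALSE)
  structure(list(electronic_snr_db = electronic_snr_db,
                 clutter_amplitude_db = clutter_amplitude_db),
            class = "noise_spec")
}

#' @export
print.noise_spec <- function(x, ...) {
  cat(sprintf("noise_spec: electronic SNR %s dB, clutter %s dB re tissue rms\n",
              format(x$electronic_snr_db), format(x$clutter_amplitude_db)))
  invisible(x)
}
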