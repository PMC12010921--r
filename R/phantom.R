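#' Diffuse-scatterer resolution cell area
#'
#' The area (mm^2) of one speckle resolution cell, using pulse-echo
#' (two-way) widths: axially the round-trip pulse length c/(4B), and
#' laterally half the one-way diffraction beam width,
#' lambda * z / (2 A), evaluated at depth `depth_mm` for the full
#' receive aperture A. The two-way cell is the correlation cell of the
#' speckle pattern, which is what the scatterers-per-cell criterion for
#' fully developed speckle (>= ~10 per cell) refers to.
#'
#' @param probe a [probe_config()].
#' @param depth_mm reference depth in mm.
#' @param fractional_bw fractional bandwidth of the imaging pulse.
#' @return scalar area in mm^2.
#' @export
resolution_cell_area <- function(probe, depth_mm, fractional_bw = 0.6) {
  axial_mm <- probe$sound_speed /
    (4 * fractional_bw * probe$center_frequency) * 1e3
  aperture_mm <- probe$n_receive * probe$pitch
  lateral_mm <- probe_wavelength_mm(probe) * depth_mm / (2 * aperture_mm)
  axial_mm * lateral_mm
}

#' Generate a random scatterer field for a speckle phantom
#'
#' Scatterer positions are uniform over the phantom rectangle; amplitudes
#' are zero-mean Gaussian with standard deviation given by the
#' echogenicity map: 1 in background tissue, a lesion's
#' `echogenicity_gain` inside that lesion (0 inside fluid), and each
#' septum's gain inside the septa of a mixed lesion.
#'
#' @param probe a [probe_config()].
#' @param lesions list of [lesion_spec()] objects (possibly empty).
#' @param density scatterers per resolution cell; must be >= 10 to keep
#'   the speckle fully developed.
#' @param seed integer seed; identical arguments give bit-identical fields.
#' @param lateral_extent length-2 lateral bounds in mm; defaults to the
#'   scan-line span widened by 3 mm on each side.
#' @param axial_extent length-2 axial (depth) bounds in mm.
#' @return an object of class `scatterer_field` with fields `x`, `z`
#'   (mm), `amplitude`, `extent`, `lesions`, `density`, `seed`.
#' @examples
#' p <- probe_config(n_scanlines = 16)
#' f <- make_phantom(p, list(), density = 10, seed = 1,
#'                   axial_extent = c(8, 12))
#' @export
make_phantom <- function(probe, lesions = list(), density = 10, seed,
                         lateral_extent = NULL, axial_extent = c(4, 24)) {
  stopifnot(inherits(probe, "probe_config"))
  stop_if_not_scalar_num(density, "density", positive = TRUE)
  if (density < 10)
    stop("density must be >= 10 scatterers per resolution cell ",
         "(fully developed speckle)", call. = FALSE)
  if (inherits(lesions, "lesion_spec")) lesions <- list(lesions)
  if (is.null(lateral_extent)) {
    sl <- scanline_positions(probe)
    lateral_extent <- c(min(sl) - 3, max(sl) + 3)
  }
  stopifnot(length(lateral_extent) == 2L, length(axial_extent) == 2L,
            diff(lateral_extent) > 0, diff(axial_extent) > 0)
  for (k in seq_along(lesions)) {
    les <- lesions[[k]]
    if (!inherits(les, "lesion_spec")) stop("lesions must be lesion_spec")
    inside <-
      les$center[1] - les$semi_axes[1] >= lateral_extent[1] &&
      les$center[1] + les$semi_axes[1] <= lateral_extent[2] &&
      les$center[2] - les$semi_axes[2] >= axial_extent[1] &&
      les$center[2] + les$semi_axes[2] <= axial_extent[2]
    if (!inside)
      stop(sprintf("lesion %d (%s) extends outside the phantom extent",
                   k, les$content_class), call. = FALSE)
  }
  area <- diff(lateral_extent) * diff(axial_extent)
  cell <- resolution_cell_area(probe, mean(axial_extent))
  n <- round(density * area / cell)
  field <- with_seed(seed, {
    x <- runif(n, lateral_extent[1], lateral_extent[2])
    z <- runif(n, axial_extent[1], axial_extent[2])
    a <- rnorm(n)
    list(x = x, z = z, a = a)
  })
  gain <- echogenicity_at(field$x, field$z, lesions)
  structure(list(x = field$x, z = field$z,
                 amplitude = field$a * gain,
                 extent = list(lateral = lateral_extent, axial = axial_extent),
                 lesions = lesions, density = density, seed = seed),
            class = "scatterer_field")
}

# Echogenicity map evaluated at scatterer positions. Later lesions
# override earlier ones; septa override their parent fluid ellipse.
echogenicity_at <- function(x, z, lesions) {
  gain <- rep(1, length(x))
  for (les in lesions) {
    inside <- in_ellipse(x, z, les$center, les$semi_axes)
    gain[inside] <- les$echogenicity_gain
    if (!is.null(les$septa)) {
      for (s in les$septa) {
        ins <- inside & in_ellipse(x, z, s$center, s$semi_axes)
        gain[ins] <- s$echogenicity_gain
      }
    }
  }
  gain
}

in_ellipse <- function(x, z, center, semi_axes) {
  ((x - center[1]) / semi_axes[1])^2 + ((z - center[2]) / semi_axes[2])^2 <= 1
}

#' @export
print.scatterer_field <- function(x, ...) {
  cat(sprintf(
    "scatterer_field: %d scatterers, lateral [%.1f, %.1f] mm, axial [%.1f, %.1f] mm, %d lesion(s), seed %d\n",
    length(x$x), x$extent$lateral[1], x$extent$lateral[2],
    x$extent$axial[1], x$extent$axial[2], length(x$lesions),
    as.integer(x$seed)))
  invisible(x)
}
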