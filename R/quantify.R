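#' Place matched mass and tissue ROIs for a lesion
#'
#' The mass ROI is the lesion ellipse shrunk by `margin` so it sits
#' strictly within the mass. The tissue ROI has identical shape, size and
#' depth, offset laterally so the edge-to-edge gap is drawn uniformly
#' from `lateral_gap_range` (0.9-8.2 mm). When no lateral placement fits
#' inside the image, the tissue ROI is instead placed above or below the
#' mass at an edge-to-edge depth gap under `depth_gap_max` (5 mm), and
#' `placement_mode` records the fallback.
#'
#' @param lesion a [lesion_spec()].
#' @param image_grid a `beamformed_image` (or any object with
#'   `lines_x` and `depth_grid` fields) defining the field of view.
#' @param seed integer seed for the gap draw.
#' @param margin shrink factor applied to the lesion semi-axes.
#' @param lateral_gap_range edge-to-edge lateral gap range in mm.
#' @param depth_gap_max maximum edge-to-edge depth gap in mm for the
#'   fallback placement.
#' @return an object of class `roi_pair` with elements `mass_roi`,
#'   `tissue_roi` (each `list(center, semi_axes)` in mm),
#'   `offset_edge_to_edge` and `placement_mode`.
#' @export
place_rois <- function(lesion, image_grid, seed, margin = 0.8,
                       lateral_gap_range = c(0.9, 8.2),
                       depth_gap_max = 5) {
  stopifnot(inherits(lesion, "lesion_spec"))
  lx <- range(image_grid$lines_x)
  zr <- range(image_grid$depth_grid)
  ax <- lesion$semi_axes * margin
  ctr <- lesion$center
  mass <- list(center = ctr, semi_axes = ax)

  draws <- with_seed(seed, list(gap = runif(1, lateral_gap_range[1],
                                            lateral_gap_range[2]),
                                side = sample(c(-1, 1), 1),
                                dgap = runif(1, 0.5, depth_gap_max * 0.9)))
  # lateral placement: try the drawn side first, then the other, then
  # shrink the gap to its minimum before giving up
  for (gap in c(draws$gap, lateral_gap_range[1])) {
    for (side in c(draws$side, -draws$side)) {
      cx <- ctr[1] + side * (2 * ax[1] + gap)
      if (cx - ax[1] >= lx[1] && cx + ax[1] <= lx[2]) {
        return(structure(list(
          mass_roi = mass,
          tissue_roi = list(center = c(cx, ctr[2]), semi_axes = ax),
          offset_edge_to_edge = gap,
          placement_mode = "lateral", seed = seed),
          class = "roi_pair"))
      }
    }
  }
  for (side in c(1, -1)) {
    cz <- ctr[2] + side * (2 * ax[2] + draws$dgap)
    if (cz - ax[2] >= zr[1] && cz + ax[2] <= zr[2]) {
      return(structure(list(
        mass_roi = mass,
        tissue_roi = list(center = c(ctr[1], cz), semi_axes = ax),
        offset_edge_to_edge = draws$dgap,
        placement_mode = "depth_fallback", seed = seed),
        class = "roi_pair"))
    }
  }
  stop(sprintf(
    "no tissue ROI placement fits for the %s lesion at (%.1f, %.1f) mm",
    lesion$content_class, ctr[1], ctr[2]), call. = FALSE)
}

#' @export
print.roi_pair <- function(x, ...) {
  cat(sprintf(
    "roi_pair [%s]: mass at (%.1f, %.1f) mm, semi-axes (%.2f, %.2f) mm; tissue at (%.1f, %.1f) mm; edge gap %.2f mm\n",
    x$placement_mode, x$mass_roi$center[1], x$mass_roi$center[2],
    x$mass_roi$semi_axes[1], x$mass_roi$semi_axes[2],
    x$tissue_roi$center[1], x$tissue_roi$center[2],
    x$offset_edge_to_edge))
  invisible(x)
}

#' Extract the pixel values inside an elliptical ROI
#'
#' Returns all pixel values whose grid centers fall inside the ellipse.
#' For beamformed images these are the pre-normalisation, pre-log values
#' that enter the gCNR; for screenshot intensity matrices they are the
#' grayscale values.
#'
#' @param img a `beamformed_image`, or a plain numeric matrix paired with
#'   `depth_grid` and `lines_x` arguments.
#' @param roi `list(center = c(lateral, axial), semi_axes = c(a, b))`
#'   in mm.
#' @param depth_grid,lines_x pixel-center coordinates (mm); taken from
#'   `img` when it is a `beamformed_image`.
#' @return numeric vector of samples; errors if the ROI covers no pixel
#'   center.
#' @export
extract_roi_samples <- function(img, roi, depth_grid = NULL,
                                lines_x = NULL) {
  if (inherits(img, "beamformed_image")) {
    depth_grid <- img$depth_grid
    lines_x <- img$lines_x
    px <- img$pixels
  } else {
    px <- as.matrix(img)
  }
  if (is.null(depth_grid) || is.null(lines_x))
    stop("depth_grid and lines_x are required for plain matrices",
         call. = FALSE)
  stopifnot(nrow(px) == length(depth_grid), ncol(px) == length(lines_x))
  dz2 <- outer(((depth_grid - roi$center[2]) / roi$semi_axes[2])^2,
               ((lines_x - roi$center[1]) / roi$semi_axes[1])^2, "+")
  inside <- dz2 <= 1
  if (!any(inside)) stop("ROI covers no pixel center", call. = FALSE)
  px[inside]
}

#' Generalized contrast-to-noise ratio
#'
#' `gCNR = 1 - sum_j min(h_mass(x_j), h_tissue(x_j))` over histograms of
#' the two sample sets on shared equal-width bins spanning the pooled
#' min-max. One minus the histogram overlap; 0 for identical
#' distributions, 1 for disjoint supports, bounded in `[0, 1]`.
#'
#' @param mass_samples,tissue_samples numeric sample vectors (non-empty).
#' @param n_bins number of shared histogram bins (default 256).
#' @return scalar gCNR in `[0, 1]`. A degenerate pooled range (all
#'   values identical) returns 0 with a warning.
#' @examples
#' gcnr(rnorm(1e4), rnorm(1e4, mean = 4))
#' @export
gcnr <- function(mass_samples, tissue_samples, n_bins = 256L) {
  if (!length(mass_samples) || !length(tissue_samples))
    stop("both sample sets must be non-empty", call. = FALSE)
  stop_if_not_scalar_num(n_bins, "n_bins", positive = TRUE)
  rng <- range(c(mass_samples, tissue_samples))
  if (diff(rng) == 0) {
    warning("degenerate pooled range (all sample values equal); gCNR = 0")
    return(0)
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  hm <- bin_probs(mass_samples, breaks)
  ht <- bin_probs(tissue_samples, breaks)
  max(0, min(1, 1 - sum(pmin(hm, ht))))
}

# Probability-normalised histogram counts on fixed breaks (values on the
# boundary of the last bin included, as hist() does).
bin_probs <- function(x, breaks) {
  idx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  tabulate(idx, nbins = length(breaks) - 1L) / length(x)
}

#' gCNR of one mass across image pathways
#'
#' Applies the same ROI pair to every supplied image pathway and returns
#' one gCNR per pathway. Screenshot rasters are first cast to double
#' grayscale; all images must share the mass image grid.
#'
#' @param images named list of `beamformed_image` and/or
#'   `screenshot_raster` objects, e.g.
#'   `list(bmode_offline = ..., slsc_offline = ..., slsc_screenshot = ...)`.
#' @param roi an [place_rois()] pair.
#' @param n_bins histogram bins passed to [gcnr()].
#' @return named numeric vector of gCNR values, with the ROI and the
#'   SLSC lag cutoff recorded in attributes.
#' @export
gcnr_for_mass <- function(images, roi, n_bins = 256L) {
  stopifnot(is.list(images), length(images) >= 1, inherits(roi, "roi_pair"))
  grid0 <- NULL
  out <- numeric(0)
  M_used <- NULL
  for (nm in names(images)) {
    img <- images[[nm]]
    if (inherits(img, "screenshot_raster")) {
      px <- screenshot_to_intensity(img)
      dg <- img$depth_grid; lx <- img$lines_x
    } else if (inherits(img, "beamformed_image")) {
      px <- img$pixels
      dg <- img$depth_grid; lx <- img$lines_x
      if (!is.null(img$params$M)) M_used <- img$params$M
    } else stop("images must be beamformed_image or screenshot_raster",
                call. = FALSE)
    if (is.null(grid0)) grid0 <- list(dg = dg, lx = lx)
    else if (length(dg) != length(grid0$dg) ||
             length(lx) != length(grid0$lx) ||
             any(abs(dg - grid0$dg) > 1e-9) ||
             any(abs(lx - grid0$lx) > 1e-9))
      stop("all pathway images must share one grid", call. = FALSE)
    m <- extract_roi_samples(px, roi$mass_roi, dg, lx)
    t <- extract_roi_samples(px, roi$tissue_roi, dg, lx)
    out[nm] <- gcnr(m, t, n_bins)
  }
  attr(out, "roi") <- roi
  attr(out, "M") <- M_used
  out
}
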