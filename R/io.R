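#' Write and read channel data
#'
#' Channel data are serialised with R's native format, carrying the RF
#' array and all acquisition metadata (probe fields, focus depth, seed,
#' delay-aligned flag).
#'
#' @param data a `channel_data` object.
#' @param path file path (conventionally `.rds`).
#' @return `write_channel_data()` returns `path` invisibly;
#'   `read_channel_data()` returns the `channel_data`.
#' @export
write_channel_data <- function(data, path) {
  stopifnot(inherits(data, "channel_data"))
  saveRDS(data, path)
  invisible(path)
}

#' @rdname write_channel_data
#' @export
read_channel_data <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "channel_data"))
    stop("file does not contain channel_data", call. = FALSE)
  x
}

#' Write a screenshot raster as an 8-bit grayscale PNG
#'
#' @param raster a `screenshot_raster`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_screenshot_png <- function(raster, path) {
  stopifnot(inherits(raster, "screenshot_raster"))
  png::writePNG(raster$pixels / 255, path)
  invisible(path)
}

#' Read an 8-bit grayscale PNG back into a raster matrix
#'
#' RGB images are converted to grayscale with Rec. 601 luma weights.
#'
#' @param path PNG path.
#' @return integer matrix in `[0, 255]`.
#' @export
read_screenshot_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) {
    w <- c(0.299, 0.587, 0.114)
    a <- a[, , 1] * w[1] + a[, , 2] * w[2] + a[, , 3] * w[3]
  }
  matrix(as.integer(round(a * 255)), nrow(a))
}

#' Serialise an experiment configuration to YAML
#'
#' @param config an [experiment_config()].
#' @param path YAML file path.
#' @return `path`, invisibly.
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  lst <- list(probe = unclass(config$probe),
              noise = unclass(config$noise),
              cohort = list(n_fluid = config$n_fluid,
                            n_solid = config$n_solid,
                            n_mixed = config$n_mixed),
              coherence = unclass(config$coherence),
              n_bins = config$n_bins,
              thresholds = config$thresholds,
              n_views = config$n_views,
              dynamic_range = config$dynamic_range,
              seed = config$seed,
              outdir = config$outdir)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  lst <- yaml::read_yaml(path)
  probe <- do.call(probe_config, lst$probe)
  experiment_config(probe = probe,
                    noise = do.call(noise_spec, lst$noise),
                    n_fluid = lst$cohort$n_fluid,
                    n_solid = lst$cohort$n_solid,
                    n_mixed = lst$cohort$n_mixed,
                    M = lst$coherence$M,
                    kernel_samples = lst$coherence$kernel_samples,
                    n_bins = lst$n_bins,
                    thresholds = unlist(lst$thresholds),
                    n_views = lst$n_views,
                    dynamic_range = lst$dynamic_range,
                    seed = lst$seed,
                    outdir = lst$outdir)
}

# Write the standard experiment artifacts: cohort manifest and gCNR
# records as CSV, one ROC CSV per pathway, report as CSV + JSON, and the
# decision trace as CSV.
write_experiment <- function(exp, outdir) {
  stopifnot(inherits(exp, "slsc_experiment"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write.csv(exp$manifest, file.path(outdir, "cohort_manifest.csv"),
            row.names = FALSE)
  write.csv(exp$records, file.path(outdir, "gcnr_records.csv"),
            row.names = FALSE)
  for (p in names(exp$roc)) {
    r <- exp$roc[[p]]
    write.csv(data.frame(threshold = r$thresholds,
                         sensitivity = r$sensitivity,
                         one_minus_specificity = r$fpr),
              file.path(outdir, sprintf("roc_%s.csv", sub("^gcnr_", "", p))),
              row.names = FALSE)
  }
  if (!is.null(exp$report))
    write.csv(exp$report, file.path(outdir, "threshold_report.csv"),
              row.names = FALSE)
  if (!is.null(exp$trace))
    write.csv(exp$trace, file.path(outdir, "decision_trace.csv"),
              row.names = FALSE)
  summary_json <- list(
    auc = lapply(exp$roc, function(r) r$auc),
    consistency = exp$consistency,
    failed = exp$failed,
    seed = exp$config$seed)
  jsonlite::write_json(summary_json, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
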