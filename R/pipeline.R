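#' Experiment configuration
#'
#' Bundles every knob of the end-to-end experiment: probe and noise
#' settings, cohort composition, coherence parameters, gCNR binning,
#' decision thresholds, and the master seed from which all per-mass
#' seeds are split. Serialisable to YAML via
#' [write_experiment_config()] with identical round-trip.
#'
#' @param probe a [probe_config()].
#' @param noise a [noise_spec()].
#' @param n_fluid,n_solid,n_mixed cohort composition.
#' @param M,kernel_samples coherence parameters (shared by both SLSC
#'   pathways); `kernel_samples = NULL` uses one wavelength of two-way
#'   travel.
#' @param n_bins gCNR histogram bins.
#' @param thresholds decision thresholds reported on; the first is the
#'   operating threshold used for the decision trace.
#' @param n_views simulated views per mass (1 or 2). With two views the
#'   decision uses the view whose SLSC gCNR is closest to the operating
#'   threshold - the most uncertain orientation.
#' @param dynamic_range display dynamic range (dB) for the screenshot
#'   surrogates.
#' @param seed master integer seed.
#' @param outdir optional output directory for CSV/JSON artifacts.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(probe = probe_config(),
                              noise = noise_spec(),
                              n_fluid = 8L, n_solid = 16L, n_mixed = 0L,
                              M = 7L, kernel_samples = NULL,
                              n_bins = 256L,
                              thresholds = c(0.73, 0.62),
                              n_views = 1L,
                              dynamic_range = 60,
                              seed = 1L,
                              outdir = NULL) {
  stopifnot(inherits(probe, "probe_config"), inherits(noise, "noise_spec"),
            n_views %in% c(1L, 2L), length(thresholds) >= 1)
  structure(list(probe = probe, noise = noise,
                 n_fluid = as.integer(n_fluid),
                 n_solid = as.integer(n_solid),
                 n_mixed = as.integer(n_mixed),
                 coherence = coherence_params(M, kernel_samples, probe),
                 n_bins = as.integer(n_bins),
                 thresholds = thresholds,
                 n_views = as.integer(n_views),
                 dynamic_range = dynamic_range,
                 seed = as.integer(seed), outdir = outdir),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("experiment_config\n")
  cat(sprintf("  cohort: %d fluid, %d solid, %d mixed; %d view(s) per mass\n",
              x$n_fluid, x$n_solid, x$n_mixed, x$n_views))
  cat(sprintf("  coherence: M = %d, kernel = %d samples; gCNR bins = %d\n",
              x$coherence$M, x$coherence$kernel_samples, x$n_bins))
  cat(sprintf("  thresholds: %s; seed %d\n",
              paste(x$thresholds, collapse = ", "), x$seed))
  invisible(x)
}

# All image pathways for one raw acquisition: offline B-mode and both
# SLSC formulations from the RF, plus 8-bit screenshot surrogates of the
# B-mode and real-time SLSC displays (the pseudo-real-time pathway).
beamform_pathways <- function(channel, cohere, dynamic_range = 60) {
  aligned <- apply_delays(channel)
  bmode <- das_bmode(aligned)
  off <- slsc_offline(aligned, cohere)
  rt <- slsc_realtime(aligned, cohere)
  list(bmode_offline = bmode,
       slsc_offline = off,
       slsc_realtime = rt,
       bmode_screenshot = render_screenshot(render_display(bmode,
                                                           dynamic_range)),
       slsc_screenshot = render_screenshot(render_display(rt,
                                                          dynamic_range)))
}

#' Run the end-to-end simulated experiment
#'
#' For every mass in the configured cohort: simulate raw channel data,
#' beamform all pathways (offline B-mode, offline SLSC, real-time-
#' formulation SLSC, and their screenshot surrogates), place one matched
#' ROI pair, compute the gCNR of every pathway with the same ROIs,
#' classify content at each configured threshold, and assemble ROC
#' curves, the threshold report and the per-mass decision trace.
#' Deterministic for a fixed master seed. A failing mass is logged and
#' skipped; the run aborts if more than 10% of masses fail.
#'
#' @param config an [experiment_config()].
#' @param cohort optionally, a pre-built [make_cohort()] result matching
#'   the config (used to avoid re-simulating).
#' @param verbose print per-mass progress lines.
#' @return an object of class `slsc_experiment` with elements `records`
#'   (per-mass, per-view gCNR table), `roc` (per-pathway
#'   [roc_curve()] results on the fluid/solid subset), `report`
#'   (sensitivity/specificity at each threshold and at the ROC-optimal
#'   threshold), `trace` (decision trace), `consistency` (offline vs
#'   real-time pathway agreement), and `config`.
#' @export
run_experiment <- function(config, cohort = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(cohort))
    cohort <- make_cohort(config$n_fluid, config$n_solid, config$n_mixed,
                          probe = config$probe, noise = config$noise,
                          seed = config$seed)
  rows <- list()
  failed <- character(0)
  for (k in seq_along(cohort$masses)) {
    mass <- cohort$masses[[k]]
    rec <- mass$record
    for (v in seq_len(config$n_views)) {
      res <- tryCatch({
        chan <- if (v == 1) mass$channel else {
          # second orthogonal view: fresh speckle realisation of the
          # same lesion geometry
          f2 <- make_phantom(config$probe, list(mass$lesion), density = 10,
                             seed = split_seed(rec$seed, 100 + v))
          simulate_channel_data(f2, config$probe,
                                focus_depth = mass$lesion$center[2],
                                noise = config$noise,
                                seed = split_seed(rec$seed, 200 + v))
        }
        imgs <- beamform_pathways(chan, config$coherence,
                                  config$dynamic_range)
        roi <- place_rois(mass$lesion, imgs$bmode_offline,
                          seed = split_seed(rec$seed, 3))
        g <- gcnr_for_mass(imgs, roi, config$n_bins)
        data.frame(mass_id = rec$mass_id, view = v,
                   ground_truth = simplify_truth(rec$content_class),
                   content_class = rec$content_class,
                   gcnr_bmode_offline = g[["bmode_offline"]],
                   gcnr_slsc_offline = g[["slsc_offline"]],
                   gcnr_slsc_realtime = g[["slsc_realtime"]],
                   gcnr_bmode_screenshot = g[["bmode_screenshot"]],
                   gcnr_slsc_screenshot = g[["slsc_screenshot"]],
                   placement_mode = roi$placement_mode,
                   offset_mm = roi$offset_edge_to_edge)
      }, error = function(e) {
        warning(sprintf("mass %s view %d failed: %s",
                        rec$mass_id, v, conditionMessage(e)))
        NULL
      })
      if (is.null(res)) failed <- c(failed, rec$mass_id)
      else rows[[length(rows) + 1L]] <- res
      if (verbose)
        message(sprintf("  %s view %d %s", rec$mass_id, v,
                        if (is.null(res)) "FAILED" else "ok"))
    }
  }
  if (length(cohort$masses) &&
      length(unique(failed)) > 0.1 * length(cohort$masses))
    stop(sprintf("%d of %d masses failed to process",
                 length(unique(failed)), length(cohort$masses)),
         call. = FALSE)
  records <- do.call(rbind, rows)

  eligible <- records[records$ground_truth %in% c("fluid", "solid") &
                        records$view == 1, , drop = FALSE]
  pathways <- c("gcnr_bmode_offline", "gcnr_slsc_offline",
                "gcnr_slsc_realtime", "gcnr_bmode_screenshot",
                "gcnr_slsc_screenshot")
  roc <- list()
  report <- list()
  if (nrow(eligible) && any(eligible$ground_truth == "fluid") &&
      any(eligible$ground_truth == "solid")) {
    for (p in pathways) {
      r <- roc_curve(eligible, p)
      roc[[p]] <- r
      t_opt <- optimal_threshold(r)
      for (th in unique(c(config$thresholds, t_opt))) {
        cc <- confusion(eligible, p, th)
        report[[length(report) + 1L]] <- data.frame(
          pathway = sub("^gcnr_", "", p), threshold = th,
          optimal = isTRUE(all.equal(th, t_opt)),
          sensitivity = sensitivity(cc), specificity = specificity(cc),
          auc = r$auc)
      }
    }
  }
  report <- if (length(report)) do.call(rbind, report) else NULL

  trace <- decision_trace(records, config)
  consistency <- pathway_consistency(records, config$thresholds[1])

  out <- structure(list(records = records, roc = roc, report = report,
                        trace = trace, consistency = consistency,
                        manifest = cohort$manifest, config = config,
                        failed = unique(failed)),
                   class = "slsc_experiment")
  if (!is.null(config$outdir)) write_experiment(out, config$outdir)
  out
}

# Ground truth for the two-class analysis; mixed and simple cysts keep
# their labels and are excluded from sensitivity/specificity downstream.
simplify_truth <- function(content_class) {
  ifelse(content_class %in% c("solid_benign", "solid_malignant", "solid"),
         "solid", content_class)
}

#' Decide mass content from its SLSC gCNR
#'
#' The automated decision rule: content is fluid when the SLSC-image
#' gCNR is at or above the threshold, solid otherwise. With several
#' views available, the view whose gCNR lies closest to the threshold
#' (the most uncertain orientation) is used.
#'
#' @param record one or more rows (views) of an experiment record for a
#'   single mass, with a `gcnr_slsc_realtime` column.
#' @param threshold decision threshold.
#' @param pathway gCNR column used for the decision.
#' @return one-row data frame: mass id, pathway and gCNR used, view,
#'   threshold, decided content.
#' @export
decide_mass <- function(record, threshold = 0.73,
                        pathway = "gcnr_slsc_realtime") {
  stopifnot(is.data.frame(record), nrow(record) >= 1,
            pathway %in% names(record))
  g <- record[[pathway]]
  if (any(is.na(g))) stop("missing gCNR value for decision", call. = FALSE)
  use <- which.min(abs(g - threshold))
  data.frame(mass_id = record$mass_id[1],
             pathway = sub("^gcnr_", "", pathway),
             view = record$view[use],
             gcnr = g[use],
             threshold = threshold,
             decision = classify_mass(g[use], threshold))
}

decision_trace <- function(records, config) {
  if (is.null(records) || !nrow(records)) return(NULL)
  th <- config$thresholds[1]
  parts <- lapply(split(records, records$mass_id), decide_mass,
                  threshold = th)
  tr <- do.call(rbind, parts)
  tr <- tr[order(tr$mass_id), , drop = FALSE]
  rownames(tr) <- NULL
  truth <- records$ground_truth[match(tr$mass_id, records$mass_id)]
  tr$ground_truth <- truth
  tr$correct <- ifelse(truth %in% c("fluid", "solid"),
                       tr$decision == truth, NA)
  tr
}

# Offline vs real-time pathway agreement on the SLSC gCNR.
pathway_consistency <- function(records, threshold) {
  if (is.null(records) || !nrow(records)) return(NULL)
  d <- abs(records$gcnr_slsc_realtime - records$gcnr_slsc_offline)
  agree <- classify_mass(records$gcnr_slsc_realtime, threshold) ==
    classify_mass(records$gcnr_slsc_offline, threshold)
  list(median_abs_diff = median(d), max_abs_diff = max(d),
       agreement = mean(agree), threshold = threshold)
}

#' @export
print.slsc_experiment <- function(x, ...) {
  cat(sprintf("slsc_experiment: %d masses (%d records), seed %d\n",
              length(unique(x$records$mass_id)), nrow(x$records),
              x$config$seed))
  for (p in names(x$roc))
    cat(sprintf("  AUC %-22s %.3f\n", sub("^gcnr_", "", p), x$roc[[p]]$auc))
  if (!is.null(x$consistency))
    cat(sprintf(
      "  SLSC pathway agreement: median |dgCNR| = %.3f, %.0f%% same call at %.2f\n",
      x$consistency$median_abs_diff, 100 * x$consistency$agreement,
      x$consistency$threshold))
  if (length(x$failed))
    cat(sprintf("  failed masses: %s\n", paste(x$failed, collapse = ", ")))
  invisible(x)
}

#' @export
summary.slsc_experiment <- function(object, ...) {
  print(object)
  if (!is.null(object$report)) {
    cat("\nThreshold report (fluid-vs-solid subset):\n")
    rep <- object$report
    rep$sensitivity <- round(rep$sensitivity, 3)
    rep$specificity <- round(rep$specificity, 3)
    rep$auc <- round(rep$auc, 3)
    print(rep, row.names = FALSE)
  }
  if (!is.null(object$trace)) {
    ok <- object$trace$correct
    cat(sprintf("\nDecision trace: %d/%d fluid/solid masses correct at %.2f\n",
                sum(ok, na.rm = TRUE), sum(!is.na(ok)),
                object$trace$threshold[1]))
  }
  invisible(object)
}
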