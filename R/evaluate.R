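#' Threshold classification of mass content from gCNR
#'
#' A mass is called fluid when its SLSC-image gCNR is at or above the
#' threshold (fluid content suppresses spatial coherence, separating the
#' mass and tissue histograms), solid otherwise. The default threshold
#' 0.73 is the pre-defined clinical operating point; 0.62 is the
#' ROC-derived alternative.
#'
#' @param gcnr_value gCNR in `[0, 1]` (vectorised).
#' @param threshold decision threshold; ties classify as fluid.
#' @return character vector, `"fluid"` or `"solid"`.
#' @examples
#' classify_mass(c(0.80, 0.50))
#' @export
classify_mass <- function(gcnr_value, threshold = 0.73) {
  if (any(gcnr_value < 0 | gcnr_value > 1, na.rm = TRUE))
    stop("gCNR values must lie in [0, 1]", call. = FALSE)
  ifelse(gcnr_value >= threshold, "fluid", "solid")
}

#' Confusion counts for fluid-vs-solid classification
#'
#' TP/FN count fluid-truth masses classified fluid/solid; TN/FP count
#' solid-truth masses classified solid/fluid. Records with mixed or
#' simple-cyst ground truth must be excluded by the caller before this
#' tally (they contain a mixture of TP and TN, or are trivially
#' identified on B-mode).
#'
#' @param records data frame with columns `ground_truth` and a gCNR
#'   column named by `pathway`.
#' @param pathway name of the gCNR column to threshold.
#' @param threshold decision threshold passed to [classify_mass()].
#' @return an object of class `confusion_counts` (fields TP, FN, TN, FP).
#' @export
confusion <- function(records, pathway, threshold = 0.73) {
  stopifnot(is.data.frame(records), pathway %in% names(records),
            "ground_truth" %in% names(records))
  bad <- setdiff(unique(records$ground_truth), c("fluid", "solid"))
  if (length(bad))
    stop(sprintf(
      "records contain ground truth class(es) %s; exclude mixed and simple_cyst before computing confusion counts",
      paste(sQuote(bad), collapse = ", ")), call. = FALSE)
  pred <- classify_mass(records[[pathway]], threshold)
  truth <- records$ground_truth
  structure(list(TP = sum(truth == "fluid" & pred == "fluid"),
                 FN = sum(truth == "fluid" & pred == "solid"),
                 TN = sum(truth == "solid" & pred == "solid"),
                 FP = sum(truth == "solid" & pred == "fluid"),
                 threshold = threshold, pathway = pathway),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion_counts (%s @ %.2f): TP %d, FN %d, TN %d, FP %d\n",
              x$pathway, x$threshold, x$TP, x$FN, x$TN, x$FP))
  cat(sprintf("  sensitivity %.3f, specificity %.3f\n",
              sensitivity(x), specificity(x)))
  invisible(x)
}

#' Sensitivity and specificity
#'
#' Sensitivity is the fraction of fluid masses (complicated cysts)
#' correctly identified as fluid, `TP / (TP + FN)`; specificity is the
#' fraction of solid masses correctly identified as solid,
#' `TN / (TN + FP)`. A zero denominator returns `NA` with a warning.
#'
#' @param c a `confusion_counts` object.
#' @return scalar in `[0, 1]`, or `NA` when undefined.
#' @export
sensitivity <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  if (c$TP + c$FN == 0) {
    warning("sensitivity undefined: no fluid-truth records")
    return(NA_real_)
  }
  c$TP / (c$TP + c$FN)
}

#' @rdname sensitivity
#' @export
specificity <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  if (c$TN + c$FP == 0) {
    warning("specificity undefined: no solid-truth records")
    return(NA_real_)
  }
  c$TN / (c$TN + c$FP)
}

#' ROC curve over the gCNR threshold grid
#'
#' Sweeps the decision threshold from 0 to 1 in steps of 0.01 (101 grid
#' points), computes sensitivity and 1 - specificity at each, and
#' estimates the AUC by trapezoidal integration of the curve sorted by
#' 1 - specificity with (0,0) and (1,1) anchors.
#'
#' @param records data frame with `ground_truth` in
#'   `{"fluid", "solid"}` and a gCNR column named by `pathway`; needs at
#'   least one record of each class.
#' @param pathway name of the gCNR column.
#' @return an object of class `slsc_roc` with fields `thresholds`,
#'   `sensitivity`, `fpr` (1 - specificity), `auc`, `pathway`.
#' @export
roc_curve <- function(records, pathway) {
  stopifnot(is.data.frame(records))
  if (!any(records$ground_truth == "fluid") ||
      !any(records$ground_truth == "solid"))
    stop("roc_curve needs at least one fluid and one solid record",
         call. = FALSE)
  thresholds <- seq(0, 1, by = 0.01)
  sens <- fpr <- numeric(length(thresholds))
  for (k in seq_along(thresholds)) {
    cc <- confusion(records, pathway, thresholds[k])
    sens[k] <- cc$TP / (cc$TP + cc$FN)
    fpr[k] <- cc$FP / (cc$TN + cc$FP)
  }
  pts <- unique(data.frame(fpr = c(0, fpr, 1), sens = c(0, sens, 1)))
  pts <- pts[order(pts$fpr, pts$sens), ]
  auc <- sum(diff(pts$fpr) * (utils::head(pts$sens, -1) +
                                utils::tail(pts$sens, -1)) / 2)
  structure(list(thresholds = thresholds, sensitivity = sens, fpr = fpr,
                 auc = auc, pathway = pathway,
                 n_fluid = sum(records$ground_truth == "fluid"),
                 n_solid = sum(records$ground_truth == "solid")),
            class = "slsc_roc")
}

#' @export
print.slsc_roc <- function(x, ...) {
  cat(sprintf(
    "ROC for %s gCNR: AUC = %.3f (%d fluid vs %d solid, thresholds 0-1 step 0.01)\n",
    x$pathway, x$auc, x$n_fluid, x$n_solid))
  invisible(x)
}

#' @export
plot.slsc_roc <- function(x, ...) {
  graphics::plot(x$fpr, x$sensitivity, type = "s", xlim = c(0, 1),
                 ylim = c(0, 1), xlab = "1 - specificity",
                 ylab = "sensitivity",
                 main = sprintf("%s (AUC = %.3f)", x$pathway, x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Threshold closest to the ideal (0, 1) ROC corner
#'
#' Returns the grid threshold minimising the Euclidean distance from
#' `(1 - specificity, sensitivity)` to `(0, 1)`; ties return the
#' smallest threshold.
#'
#' @param roc an [roc_curve()] result.
#' @return scalar threshold.
#' @export
optimal_threshold <- function(roc) {
  stopifnot(inherits(roc, "slsc_roc"))
  d2 <- roc$fpr^2 + (1 - roc$sensitivity)^2
  roc$thresholds[which.min(d2)]          # which.min takes the first tie
}

#' Fleiss' kappa for multi-rater categorical agreement
#'
#' Standard Fleiss' kappa `(Pbar - Pe) / (1 - Pe)` from an items x
#' categories count table with a constant number of ratings per item,
#' with an interpretation band (Landis-Koch): <=0 poor, <=0.20 slight,
#' <=0.40 fair, <=0.60 moderate, <=0.80 substantial, >0.80 almost
#' perfect.
#'
#' @param mat numeric matrix, `n_items x n_categories`; entry (i, j) is
#'   the number of raters assigning item i to category j. Row sums must
#'   all equal the rater count (>= 2), and there must be >= 2 items.
#' @return an object of class `fleiss_kappa`: fields `kappa`, `band`,
#'   `P_bar`, `P_e`, `n_items`, `n_raters`. When every rating falls in
#'   one category `P_e = 1` and kappa is `NA` with a warning.
#' @examples
#' m <- rbind(c(3, 0), c(0, 3), c(3, 0), c(2, 1))
#' fleiss_kappa(m)
#' @export
fleiss_kappa <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) stop("need at least 2 items", call. = FALSE)
  n_raters <- unique(rowSums(mat))
  if (length(n_raters) != 1)
    stop("all items must have the same number of ratings", call. = FALSE)
  if (n_raters < 2) stop("need at least 2 raters", call. = FALSE)
  n <- nrow(mat)
  P_i <- (rowSums(mat^2) - n_raters) / (n_raters * (n_raters - 1))
  P_bar <- mean(P_i)
  p_j <- colSums(mat) / (n * n_raters)
  P_e <- sum(p_j^2)
  if (P_e >= 1 - .Machine$double.eps * 8) {
    warning("all ratings fall in a single category; kappa undefined")
    kappa <- NA_real_
  } else {
    kappa <- (P_bar - P_e) / (1 - P_e)
  }
  structure(list(kappa = kappa, band = kappa_band(kappa),
                 P_bar = P_bar, P_e = P_e,
                 n_items = n, n_raters = n_raters),
            class = "fleiss_kappa")
}

#' Interpretation band for a kappa value
#'
#' @param kappa scalar agreement statistic (or NA).
#' @return character band label.
#' @export
kappa_band <- function(kappa) {
  if (is.na(kappa)) return(NA_character_)
  if (kappa <= 0) "poor"
  else if (kappa <= 0.20) "slight"
  else if (kappa <= 0.40) "fair"
  else if (kappa <= 0.60) "moderate"
  else if (kappa <= 0.80) "substantial"
  else "almost perfect"
}

#' @export
print.fleiss_kappa <- function(x, ...) {
  cat(sprintf("Fleiss' kappa = %s (%s agreement; %d items, %d raters)\n",
              format(round(x$kappa, 4)), x$band, x$n_items, x$n_raters))
  invisible(x)
}
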