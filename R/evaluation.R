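#' Validation ratio and prevalence
#'
#' Alert-level statistics used when true negatives are unobservable (alerts
#' are confirmed by urinalysis or left not-validated): the validation ratio
#' `rho_val = TV / (TV + NV)` and the prevalence
#' `rho_prev = positives / total_population`. A zero denominator yields an
#' `NA` value with the corresponding `undefined` flag instead of an error.
#'
#' @param tv Truly validated alert count.
#' @param nv Not-validated alert count (not necessarily false).
#' @param positives Condition-positive count (for prevalence), optional.
#' @param total_population Population size (for prevalence), optional.
#' @return List: `rho_val`, `rho_prev`, `total_alerts`, `undefined`
#'   (character vector naming undefined components).
#' @export
validation_metrics <- function(tv, nv, positives = NULL,
                               total_population = NULL) {
  stopifnot(tv >= 0, nv >= 0)
  undefined <- character(0)
  rho_val <- if (tv + nv > 0) tv / (tv + nv) else {
    undefined <- c(undefined, "rho_val")
    NA_real_
  }
  rho_prev <- NA_real_
  if (!is.null(positives) && !is.null(total_population)) {
    if (total_population > 0) {
      rho_prev <- positives / total_population
    } else {
      undefined <- c(undefined, "rho_prev")
    }
  }
  list(rho_val = rho_val, rho_prev = rho_prev,
       total_alerts = tv + nv, undefined = undefined)
}

#' Sensitivity, specificity and accuracy from a confusion matrix
#'
#' `rho_sen = TP / (TP + FN)`, `rho_spe = TN / (TN + FP)`,
#' `rho = (TP + TN) / (TP + FP + FN + TN)`. Zero denominators yield `NA`
#' components with `undefined` flags.
#'
#' @param tp,fp,fn,tn Non-negative confusion counts.
#' @return List: `rho_sen`, `rho_spe`, `rho`, `undefined`.
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  undefined <- character(0)
  rho_sen <- if (tp + fn > 0) tp / (tp + fn) else {
    undefined <- c(undefined, "rho_sen")
    NA_real_
  }
  rho_spe <- if (tn + fp > 0) tn / (tn + fp) else {
    undefined <- c(undefined, "rho_spe")
    NA_real_
  }
  total <- tp + fp + fn + tn
  rho <- if (total > 0) (tp + tn) / total else {
    undefined <- c(undefined, "rho")
    NA_real_
  }
  list(rho_sen = rho_sen, rho_spe = rho_spe, rho = rho, undefined = undefined)
}

#' Assemble a confusion matrix from predicted and reference labels
#'
#' Reference labels may carry a third value, `"not_validated"`, for days
#' whose ground truth could not be confirmed; such days are dropped from
#' the confusion counts (they are neither true nor false) and reported
#' separately.
#'
#' @param predicted Character vector: `"positive"` / `"negative"`.
#' @param reference Character vector: `"positive"` / `"negative"` /
#'   `"not_validated"`.
#' @return List: `tp`, `fp`, `fn`, `tn`, `n_not_validated`.
#' @export
confusion_counts <- function(predicted, reference) {
  stopifnot(length(predicted) == length(reference))
  keep <- reference != "not_validated"
  p <- predicted[keep]
  r <- reference[keep]
  list(
    tp = sum(p == "positive" & r == "positive"),
    fp = sum(p == "positive" & r == "negative"),
    fn = sum(p == "negative" & r == "positive"),
    tn = sum(p == "negative" & r == "negative"),
    n_not_validated = sum(!keep)
  )
}

#' Round metrics for reporting
#'
#' Two-decimal half-up rounding, the printed-report convention.
#'
#' @param x Numeric.
#' @param digits Decimal places, default 2.
#' @return Rounded numeric.
#' @export
report_round <- function(x, digits = 2) {
  round_half_up(x, digits)
}
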