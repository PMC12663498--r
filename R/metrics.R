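#' Confusion matrix constructor
#'
#' @param tp,fp,fn,tn nonnegative cell counts.
#' @return list of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0)) stop_named("confusion-matrix cells must be nonnegative")
  structure(as.list(cells), class = "confusion_matrix")
}

#' Binary classification metrics
#'
#' Sensitivity, specificity, positive and negative predictive values and
#' global accuracy from a 2x2 table. Raw proportions are kept alongside
#' report-style integer percentages (rounded half away from zero). A zero
#' denominator yields `NA` for that metric rather than propagating NaN.
#'
#' @param cm a [confusion_matrix()].
#' @return list of class `classification_metrics` with elements `raw`
#'   (proportions) and `percent` (rounded integers), each containing
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `accuracy`.
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  raw <- c(
    sensitivity = ratio(cm$tp, cm$tp + cm$fn),
    specificity = ratio(cm$tn, cm$tn + cm$fp),
    ppv = ratio(cm$tp, cm$tp + cm$fp),
    npv = ratio(cm$tn, cm$tn + cm$fn),
    accuracy = ratio(cm$tp + cm$tn, cm$tp + cm$fp + cm$fn + cm$tn)
  )
  structure(list(raw = raw, percent = as_pct(raw)),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  p <- x$percent
  cat(sprintf("sensitivity %s%%, specificity %s%%, PPV %s%%, NPV %s%%, accuracy %s%%\n",
              p["sensitivity"], p["specificity"], p["ppv"], p["npv"], p["accuracy"]))
  invisible(x)
}

#' Dichotomize risk categories against observed outcomes
#'
#' Test-positive is HIGH or VERY_HIGH risk; condition-positive is a primary
#' event (status 1) over the full follow-up.
#'
#' @param categories factor/character of risk categories, one per subject.
#' @param outcomes outcome data frame with a `status` column, same order.
#' @return a [confusion_matrix()].
#' @export
dichotomize_and_tabulate <- function(categories, outcomes) {
  if (length(categories) != nrow(outcomes)) stop_named("length mismatch")
  pos <- as.character(categories) %in% c("HIGH", "VERY_HIGH")
  ev <- outcomes$status == 1L
  confusion_matrix(tp = sum(pos & ev), fp = sum(pos & !ev),
                   fn = sum(!pos & ev), tn = sum(!pos & !ev))
}

#' Reconstruct the reference 2x2 table from reported aggregates
#'
#' Rebuilds the confusion matrix of the dichotomized tool (low/moderate vs
#' high/very-high) from aggregate summary statistics of the kind reported by
#' external validations: the four category sizes, the total number of
#' composite events, and the crude event incidences in the two positive
#' strata. Defaults are the reported values from the general-cancer-cohort
#' validation this package emulates (n = 2,290; categories 631/806/785/68;
#' 460 events; positive-stratum incidences 29% and 37%).
#'
#' @param group_sizes named or ordered vector of the four category sizes
#'   (low, moderate, high, very high).
#' @param total_events total composite-event count.
#' @param incidence_high,incidence_very_high crude incidence proportions in
#'   the high and very-high categories.
#' @return a [confusion_matrix()].
#' @export
reference_confusion_matrix <- function(group_sizes = c(low = 631, moderate = 806,
                                                       high = 785, very_high = 68),
                                       total_events = 460,
                                       incidence_high = 0.29,
                                       incidence_very_high = 0.37) {
  tp <- round(incidence_high * group_sizes[[3L]] +
              incidence_very_high * group_sizes[[4L]])
  fn <- total_events - tp
  fp <- group_sizes[[3L]] + group_sizes[[4L]] - tp
  tn <- group_sizes[[1L]] + group_sizes[[2L]] - fn
  confusion_matrix(tp = tp, fp = fp, fn = fn, tn = tn)
}
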