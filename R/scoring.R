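#' Scoring configuration
#'
#' Tunable thresholds of the harmonized HFA-ICOS scoring engine. Defaults
#' mirror the published proforma: strict inequalities at every threshold
#' (blood pressure >140/90 mmHg, BMI >30 kg/m^2, non-HDL cholesterol
#' >3.8 mmol/L, eGFR <60 mL/min/1.73m^2) and age bands \[65,80) / \[80,Inf).
#'
#' @param bp_rule `"either"` (default) flags hypertension when systolic >140
#'   OR diastolic >90; `"systolic_only"` uses the systolic component alone.
#'   Antihypertensive drug use always qualifies.
#' @param valvular_high whether significant valvular disease is a high-risk
#'   factor. Not an explicit row of the harmonized proforma, but category
#'   frequency tables from its external validation show exactly 0% valvular
#'   disease in the low and moderate categories, which is only possible if it
#'   forces at least HIGH; hence default `TRUE`.
#' @param non_hdl_threshold,bmi_threshold,sbp_threshold,dbp_threshold,egfr_threshold
#'   numeric cutpoints (mmol/L, kg/m^2, mmHg, mmHg, mL/min/1.73m^2).
#' @return a list of class `scoring_config`.
#' @export
scoring_config <- function(bp_rule = c("either", "systolic_only"),
                           valvular_high = TRUE,
                           non_hdl_threshold = 3.8,
                           bmi_threshold = 30,
                           sbp_threshold = 140,
                           dbp_threshold = 90,
                           egfr_threshold = 60) {
  structure(list(bp_rule = match.arg(bp_rule),
                 valvular_high = isTRUE(valvular_high),
                 non_hdl_threshold = non_hdl_threshold,
                 bmi_threshold = bmi_threshold,
                 sbp_threshold = sbp_threshold,
                 dbp_threshold = dbp_threshold,
                 egfr_threshold = egfr_threshold),
            class = "scoring_config")
}

#' Four-level risk categories
#' @export
risk_levels <- function() c("LOW", "MODERATE", "HIGH", "VERY_HIGH")

.age_band <- function(age) {
  cut(age, breaks = c(-Inf, 65, 80, Inf), right = FALSE,
      labels = c("under65", "65to79", "80plus"))
}

#' Derive composite predictors from a raw profile
#'
#' Computes the definitions used by the scoring rules: hypertension
#' (antihypertensive use OR blood pressure above 140/90), hyperlipidemia
#' (non-HDL cholesterol = total - HDL above 3.8 mmol/L), chronic kidney
#' disease (eGFR below 60 or a CKD diagnosis), obesity (BMI above 30) and the
#' age band.
#'
#' @param subjects subject data frame (see [cohort-format]).
#' @param config a [scoring_config()].
#' @param strict error (naming subject and field) on any missing field the
#'   rules need; with `strict = FALSE` missing inputs yield `NA` outputs.
#' @return data frame: `subject_id`, `hypertension`, `hyperlipidemia`, `ckd`,
#'   `obesity`, `age_band`, `non_hdl`.
#' @export
derive_predictors <- function(subjects, config = scoring_config(), strict = TRUE) {
  if (strict) {
    needed <- c("age", "systolic_bp", "diastolic_bp", "antihypertensive_use",
                "egfr", "ckd_diagnosis", "bmi", "total_cholesterol",
                "hdl_cholesterol")
    if (config$bp_rule == "systolic_only") needed <- setdiff(needed, "diastolic_bp")
    for (col in needed) {
      i <- which(is.na(subjects[[col]]))
      if (length(i) > 0L) {
        stop_named("missing value in field '%s' for subject %s (strict mode)",
                   col, subjects$subject_id[i[1L]])
      }
    }
  }
  bp_high <- subjects$systolic_bp > config$sbp_threshold
  if (config$bp_rule == "either") {
    bp_high <- bp_high | subjects$diastolic_bp > config$dbp_threshold
  }
  non_hdl <- subjects$total_cholesterol - subjects$hdl_cholesterol
  data.frame(
    subject_id = subjects$subject_id,
    hypertension = subjects$antihypertensive_use | bp_high,
    hyperlipidemia = non_hdl > config$non_hdl_threshold,
    ckd = subjects$egfr < config$egfr_threshold | subjects$ckd_diagnosis,
    obesity = subjects$bmi > config$bmi_threshold,
    age_band = .age_band(subjects$age),
    non_hdl = non_hdl,
    stringsAsFactors = FALSE
  )
}

#' Medium-level risk points
#'
#' Sum of the medium-weight factors: 2 points each for age 65-79 and
#' arrhythmia (AF, flutter, VT); 1 point each for hypertension, diabetes,
#' hyperlipidemia, chronic kidney disease, current smoking, obesity, prior
#' chest/mediastinal radiotherapy and prior non-anthracycline chemotherapy.
#' Age >= 80 contributes no medium points (it is a high-risk factor instead).
#'
#' @param derived output of [derive_predictors()].
#' @param subjects matching subject data frame.
#' @return integer vector of points, one per subject.
#' @export
score_medium_points <- function(derived, subjects) {
  stopifnot(nrow(derived) == nrow(subjects))
  pts <- 2L * (derived$age_band == "65to79") +
    2L * subjects$arrhythmia +
    derived$hypertension +
    subjects$diabetes +
    derived$hyperlipidemia +
    derived$ckd +
    subjects$current_smoker +
    derived$obesity +
    subjects$prior_chest_rt +
    subjects$prior_nonanthracycline_chemo
  as.integer(pts)
}

#' High- and very-high-risk factor flags
#'
#' Very-high: heart failure or cardiomyopathy. High: coronary artery disease
#' (MI, previous revascularization, or stable angina — one input flag),
#' arterial vascular disease (stroke/TIA or peripheral artery disease),
#' previous anthracycline exposure, age >= 80, and (by default, see
#' [scoring_config()]) significant valvular disease.
#'
#' @param subjects subject data frame.
#' @param config a [scoring_config()].
#' @return list with `high` and `very_high`, each a list (one element per
#'   subject) of factor-name character vectors.
#' @export
collect_risk_flags <- function(subjects, config = scoring_config()) {
  n <- nrow(subjects)
  high_mat <- cbind(
    coronary_artery_disease = subjects$coronary_artery_disease,
    arterial_vascular_disease = subjects$cerebrovascular_disease |
      subjects$peripheral_artery_disease,
    prior_anthracycline = subjects$prior_anthracycline,
    age80plus = !is.na(subjects$age) & subjects$age >= 80,
    valvular_disease = if (config$valvular_high) subjects$valvular_disease
                       else rep(FALSE, n)
  )
  high <- lapply(seq_len(n), function(i) colnames(high_mat)[which(high_mat[i, ])])
  very_high <- lapply(subjects$heart_failure, function(hf) {
    if (isTRUE(hf)) "heart_failure" else character(0)
  })
  list(high = high, very_high = very_high)
}

#' Assign the four-level risk category
#'
#' Precedence VERY_HIGH > HIGH > MODERATE > LOW: any very-high factor gives
#' VERY_HIGH; otherwise any high factor or >= 5 medium points gives HIGH;
#' otherwise 2-4 points gives MODERATE and 0-1 points LOW.
#'
#' @param points integer vector of medium points.
#' @param high_factors,very_high_factors lists of factor-name vectors as
#'   returned by [collect_risk_flags()] (logical vectors also accepted).
#' @return factor with levels [risk_levels()].
#' @export
categorize <- function(points, high_factors, very_high_factors) {
  any_of <- function(f) {
    if (is.list(f)) vapply(f, function(x) length(x) > 0L, logical(1)) else as.logical(f)
  }
  vh <- any_of(very_high_factors)
  hi <- any_of(high_factors)
  out <- ifelse(vh, "VERY_HIGH",
         ifelse(hi | points >= 5L, "HIGH",
         ifelse(points >= 2L, "MODERATE", "LOW")))
  factor(out, levels = risk_levels())
}

#' Stratify a cohort into HFA-ICOS risk categories
#'
#' Runs the full engine per subject: derived predictors, medium points, risk
#' flags, category. Scoring needs complete predictor data; missingness is
#' normally resolved upstream by [mice_impute()].
#'
#' @param subjects subject data frame.
#' @param config a [scoring_config()].
#' @param on_missing `"error"` (default; strict mode) or `"drop"`
#'   (complete-case mode: subjects with incomplete scoring inputs are removed
#'   with a warning).
#' @return data frame of class `risk_assessment`: `subject_id`,
#'   `medium_points`, `high_factors` and `very_high_factors` (list columns),
#'   `category`; attribute `counts` holds the category tabulation.
#' @export
stratify_cohort <- function(subjects, config = scoring_config(),
                            on_missing = c("error", "drop")) {
  on_missing <- match.arg(on_missing)
  if (on_missing == "drop") {
    score_cols <- setdiff(names(.subject_cols), "subject_id")
    keep <- stats::complete.cases(subjects[intersect(score_cols, names(subjects))])
    if (!all(keep)) {
      warning(sprintf("complete-case mode: dropping %d incomplete subject(s)",
                      sum(!keep)), call. = FALSE)
      subjects <- subjects[keep, , drop = FALSE]
    }
  }
  if (on_missing == "error") {
    flag_cols <- c("arrhythmia", "diabetes", "current_smoker", "prior_chest_rt",
                   "prior_nonanthracycline_chemo", "coronary_artery_disease",
                   "cerebrovascular_disease", "peripheral_artery_disease",
                   "heart_failure", "valvular_disease", "prior_anthracycline")
    for (col in flag_cols) {
      i <- which(is.na(subjects[[col]]))
      if (length(i) > 0L) {
        stop_named("missing value in field '%s' for subject %s (strict mode)",
                   col, subjects$subject_id[i[1L]])
      }
    }
  }
  derived <- derive_predictors(subjects, config, strict = on_missing == "error")
  pts <- score_medium_points(derived, subjects)
  flags <- collect_risk_flags(subjects, config)
  out <- data.frame(subject_id = subjects$subject_id,
                    medium_points = pts,
                    stringsAsFactors = FALSE)
  out$high_factors <- flags$high
  out$very_high_factors <- flags$very_high
  out$category <- categorize(pts, flags$high, flags$very_high)
  counts <- table(out$category)
  attr(out, "counts") <- counts
  attr(out, "proportions") <- if (nrow(out) > 0L) counts / nrow(out) else counts
  class(out) <- c("risk_assessment", class(out))
  out
}
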