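#' Validation run configuration
#'
#' Either a synthetic-cohort configuration or paths to cohort CSVs, plus the
#' analysis switches: which endpoints to run (composite and/or single-cause),
#' treatment subgroup filters, the sensitivity analyses (metastatic
#' exclusion; 2-year landmark, which removes subjects whose follow-up ended
#' before 2 years), and the follow-up horizon when the cohort does not carry
#' per-subject administrative censoring times.
#'
#' @param synthetic a [synthetic_cohort_config()] (exactly one of
#'   `synthetic` / `subjects_file` must be given).
#' @param subjects_file,events_file cohort CSV paths (see [read_cohort()]).
#' @param horizon fallback administrative horizon in years, used when the
#'   subject table has no `followup_years` column.
#' @param analyses subset of `c("composite", "hf_only", "mi_only")`.
#' @param subgroup `NULL`, `"anthracycline"` (subjects who received
#'   anthracyclines; high and very-high categories merged) or
#'   `"pooled_cardiotoxic"` (anthracycline, HER2, intravenous VEGF inhibitor
#'   or myeloma therapy; same merge).
#' @param exclude_metastatic drop subjects with metastatic disease.
#' @param landmark_years `NULL`, or remove subjects with outcome time below
#'   this landmark before analysis.
#' @param imputation an [impute_spec()] used when the subject table has
#'   missing predictor values.
#' @param seed master seed for every random step of the run.
#' @return list of class `run_config`.
#' @export
run_config <- function(synthetic = NULL, subjects_file = NULL,
                       events_file = NULL, horizon = 17,
                       analyses = c("composite", "hf_only", "mi_only"),
                       subgroup = NULL, exclude_metastatic = FALSE,
                       landmark_years = NULL, imputation = impute_spec(),
                       seed = 1L) {
  if (is.null(synthetic) == is.null(subjects_file)) {
    stop_named("exactly one input source required: synthetic config or subjects_file")
  }
  stopifnot(horizon > 0)
  analyses <- match.arg(analyses, several.ok = TRUE)
  if (!is.null(subgroup)) {
    subgroup <- match.arg(subgroup, c("anthracycline", "pooled_cardiotoxic"))
  }
  structure(list(synthetic = synthetic, subjects_file = subjects_file,
                 events_file = events_file, horizon = horizon,
                 analyses = analyses, subgroup = subgroup,
                 exclude_metastatic = isTRUE(exclude_metastatic),
                 landmark_years = landmark_years, imputation = imputation,
                 seed = as.integer(seed)),
            class = "run_config")
}

.category_dummies <- function(category) {
  lv <- levels(category)
  x <- sapply(lv[-1L], function(l) as.numeric(category == l))
  x <- as.matrix(x)
  keep <- colSums(x) > 0
  x[, keep, drop = FALSE]
}

.predictor_design <- function(subjects, derived) {
  cbind(
    heart_failure = as.numeric(subjects$heart_failure),
    valvular_disease = as.numeric(subjects$valvular_disease),
    coronary_artery_disease = as.numeric(subjects$coronary_artery_disease),
    cerebrovascular_disease = as.numeric(subjects$cerebrovascular_disease),
    peripheral_artery_disease = as.numeric(subjects$peripheral_artery_disease),
    arrhythmia = as.numeric(subjects$arrhythmia),
    hypertension = as.numeric(derived$hypertension),
    diabetes = as.numeric(subjects$diabetes),
    ckd = as.numeric(derived$ckd),
    hyperlipidemia = as.numeric(derived$hyperlipidemia),
    current_smoker = as.numeric(subjects$current_smoker),
    obesity = as.numeric(derived$obesity),
    prior_anthracycline = as.numeric(subjects$prior_anthracycline),
    prior_nonanthracycline_chemo = as.numeric(subjects$prior_nonanthracycline_chemo),
    prior_chest_rt = as.numeric(subjects$prior_chest_rt)
  )
}

.analysis_block <- function(category, outcomes, merge_high = FALSE) {
  if (merge_high) {
    category <- factor(ifelse(as.character(category) %in% c("HIGH", "VERY_HIGH"),
                              "HIGH_VERY_HIGH", as.character(category)),
                       levels = c("LOW", "MODERATE", "HIGH_VERY_HIGH"))
  }
  counts <- table(category)
  events_by <- tapply(outcomes$status == 1L, category, sum)
  events_by[is.na(events_by)] <- 0
  crude <- as.numeric(events_by) / pmax(as.numeric(counts), 1L)
  score <- as.integer(category)
  ev <- as.integer(outcomes$status == 1L)
  conc <- tryCatch(harrell_c(score, outcomes$time, ev),
                   error = function(e) NULL)
  hr_table <- function(fitter, ...) {
    x <- .category_dummies(category)
    if (ncol(x) == 0L) return(NULL)
    tryCatch(fitter(x, ...), error = function(e) NULL)
  }
  cox <- hr_table(function(x, ...) cox_ph_fit(x, outcomes$time, ev))
  fg <- hr_table(function(x, ...) fine_gray_fit(x, outcomes$time, outcomes$status))
  cm <- if (!merge_high) dichotomize_and_tabulate(category, outcomes) else {
    pos <- as.character(category) == "HIGH_VERY_HIGH"
    confusion_matrix(tp = sum(pos & ev == 1L), fp = sum(pos & ev == 0L),
                     fn = sum(!pos & ev == 1L), tn = sum(!pos & ev == 0L))
  }
  list(
    n = length(category),
    category_counts = as.list(counts),
    category_proportions = as.list(round(as.numeric(counts) / length(category), 4)),
    crude_incidence = stats::setNames(as.list(round(crude, 4)), names(counts)),
    crude_incidence_pct = stats::setNames(as.list(as_pct(crude)), names(counts)),
    interval_incidence = interval_incidence(outcomes),
    km = lapply(split(seq_along(score), category), function(i) {
      if (length(i) == 0L) return(NULL)
      kaplan_meier(outcomes$time[i], ev[i])
    }),
    cif = aalen_johansen_cif(outcomes$time, outcomes$status),
    harrell_c = conc,
    cox_vs_low = cox,
    fine_gray_vs_low = fg,
    confusion = cm,
    metrics = classification_metrics(cm)
  )
}

#' Run the full validation pipeline
#'
#' Orchestrates the analysis end to end: obtain the cohort (synthetic or
#' from CSV), impute missing predictors by chained equations and select a
#' single completed dataset, stratify every subject with the scoring engine,
#' build the competing-risk outcomes, apply the configured filters, and
#' compute — per requested endpoint — category counts and crude incidences,
#' 6-month interval incidence, Kaplan-Meier and Aalen-Johansen curves,
#' Harrell's C of the ordinal category (competing deaths censored), Cox and
#' Fine-Gray hazard ratios versus the low-risk category, the dichotomized
#' confusion matrix with its five classification metrics, and per-predictor
#' unadjusted and age/sex-adjusted Fine-Gray subdistribution hazard ratios.
#' Every random step is seeded from the configuration; identical
#' configurations yield identical reports.
#'
#' @param config a [run_config()].
#' @return nested list of class `validation_report`.
#' @export
run_validation <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  if (!is.null(config$synthetic)) {
    cohort <- generate_cohort(config$synthetic)
    subjects <- cohort$subjects
    events <- cohort$events
  } else {
    cohort <- read_cohort(config$subjects_file, config$events_file)
    subjects <- cohort$subjects
    events <- cohort$events
  }
  n_input <- nrow(subjects)

  # imputation precedes scoring; single completed dataset is the analysis input
  imputed_index <- NA_integer_
  score_cols <- setdiff(names(.subject_cols), "subject_id")
  if (anyNA(subjects[score_cols])) {
    imp_in <- subjects[score_cols]
    imp_in$sex <- factor(imp_in$sex)
    mids <- mice_impute(imp_in, config$imputation)
    completed <- select_single_dataset(mids, seed = config$seed + 1L)
    imputed_index <- attr(completed, "index")
    completed$sex <- as.character(completed$sex)
    subjects[score_cols] <- completed
  }

  assessment <- stratify_cohort(subjects)
  horizon <- subjects$followup_years %||% config$horizon
  if (all(is.na(horizon))) horizon <- config$horizon
  outcomes_all <- build_outcomes(events, subjects$subject_id, horizon)

  keep <- rep(TRUE, nrow(subjects))
  filters <- list()
  if (config$exclude_metastatic) {
    keep <- keep & !(subjects$metastatic %in% TRUE)
    filters$exclude_metastatic <- sum(subjects$metastatic %in% TRUE)
  }
  if (!is.null(config$landmark_years)) {
    drop_lm <- outcomes_all$time < config$landmark_years
    filters$landmark_removed <- sum(keep & drop_lm)
    keep <- keep & !drop_lm
  }
  if (!is.null(config$subgroup)) {
    in_sub <- if (config$subgroup == "anthracycline") {
      subjects$received_anthracycline %in% TRUE
    } else {
      (subjects$received_anthracycline %in% TRUE) |
        (subjects$received_her2 %in% TRUE) |
        (subjects$received_vegf_iv %in% TRUE) |
        (subjects$received_myeloma_tx %in% TRUE)
    }
    keep <- keep & in_sub
  }
  subjects <- subjects[keep, , drop = FALSE]
  assessment <- assessment[keep, , drop = FALSE]
  events <- events[events$subject_id %in% subjects$subject_id, , drop = FALSE]
  horizon <- if (length(horizon) > 1L) horizon[keep] else horizon
  merge_high <- !is.null(config$subgroup)

  analyses <- list()
  for (an in config$analyses) {
    cause <- switch(an, composite = NULL, hf_only = "HF_HOSP", mi_only = "MI")
    out <- build_outcomes(events, subjects$subject_id, horizon, cause = cause)
    analyses[[an]] <- .analysis_block(assessment$category, out,
                                      merge_high = merge_high)
  }

  # per-predictor subdistribution hazard ratios (composite endpoint)
  predictor_fits <- NULL
  if ("composite" %in% config$analyses && nrow(subjects) > 30L) {
    out <- build_outcomes(events, subjects$subject_id, horizon)
    derived <- derive_predictors(subjects, strict = FALSE)
    design <- .predictor_design(subjects, derived)
    adj <- cbind(age = subjects$age, male = as.numeric(subjects$sex == "male"))
    predictor_fits <- lapply(colnames(design), function(v) {
      xv <- design[, v, drop = FALSE]
      un <- tryCatch(fine_gray_fit(xv, out$time, out$status),
                     error = function(e) NULL)
      ad <- tryCatch(fine_gray_fit(cbind(xv, adj), out$time, out$status),
                     error = function(e) NULL)
      list(predictor = v,
           unadjusted = if (!is.null(un)) un[c("coef", "se", "hr", "ci_lower", "ci_upper")],
           adjusted = if (!is.null(ad)) lapply(
             ad[c("coef", "se", "hr", "ci_lower", "ci_upper")], function(z) z[1L]))
    })
    names(predictor_fits) <- colnames(design)
  }

  structure(list(
    config = config,
    n_input = n_input,
    n_analyzed = nrow(subjects),
    filters = filters,
    imputed_dataset_index = imputed_index,
    category_counts = as.list(table(assessment$category)),
    analyses = analyses,
    predictor_shr = predictor_fits
  ), class = "validation_report")
}

.jsonable <- function(x) {
  if (inherits(x, c("km_curve", "na_curve", "cif_set"))) return(as.data.frame(x))
  if (inherits(x, "phreg_fit")) {
    return(list(coef = as.list(x$coef), se = as.list(x$se), hr = as.list(x$hr),
                ci_lower = as.list(x$ci_lower), ci_upper = as.list(x$ci_upper),
                loglik = x$loglik, converged = x$converged))
  }
  if (inherits(x, "concordance_result")) {
    return(list(c = x$c, se = x$se, ci = x$ci, comparable = x$comparable))
  }
  if (inherits(x, "confusion_matrix")) return(unclass(x))
  if (inherits(x, "classification_metrics")) {
    return(list(raw = as.list(x$raw), percent = as.list(x$percent)))
  }
  if (inherits(x, "run_config")) return(NULL)
  if (is.list(x) && !is.data.frame(x)) return(lapply(x, .jsonable))
  x
}

#' Write a validation report
#'
#' Serializes a `validation_report` as JSON (full detail) plus a short
#' human-readable markdown summary.
#'
#' @param report output of [run_validation()].
#' @param dir output directory (created if needed).
#' @return invisibly the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(.jsonable(unclass(report)), json_path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  md <- c("# Validation report", "",
          sprintf("- subjects analyzed: %d (of %d input)", report$n_analyzed,
                  report$n_input),
          sprintf("- category counts: %s",
                  paste(names(report$category_counts),
                        unlist(report$category_counts),
                        sep = "=", collapse = ", ")))
  for (an in names(report$analyses)) {
    blk <- report$analyses[[an]]
    md <- c(md, "", sprintf("## %s", an),
            sprintf("- crude incidence (%%): %s",
                    paste(names(blk$crude_incidence_pct),
                          unlist(blk$crude_incidence_pct),
                          sep = "=", collapse = ", ")))
    if (!is.null(blk$harrell_c)) {
      md <- c(md, sprintf("- Harrell C: %.3f (95%% CI %.3f-%.3f)",
                          blk$harrell_c$c, blk$harrell_c$ci[1], blk$harrell_c$ci[2]))
    }
    p <- blk$metrics$percent
    md <- c(md, sprintf(
      "- sensitivity %s%%, specificity %s%%, PPV %s%%, NPV %s%%, accuracy %s%%",
      p["sensitivity"], p["specificity"], p["ppv"], p["npv"], p["accuracy"]))
  }
  md_path <- file.path(dir, "report.md")
  writeLines(md, md_path)
  invisible(c(json_path, md_path))
}
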