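#' @name cohort-format
#' @title Cohort table dialect
#'
#' @description
#' A cohort is a list with two data frames:
#'
#' * `subjects` — one row per subject: baseline predictors (age, sex, blood
#'   pressure, comorbidity flags, lipids, renal function, smoking, BMI, prior
#'   cancer-therapy exposure) plus cancer descriptors (type, metastatic flag,
#'   treatment-received flags) and, when known, the administrative follow-up
#'   time `followup_years`.
#' * `events` — long format, zero or more rows per subject:
#'   `subject_id, event_type, time_years, dx_position`.
#'
#' Times are years from cancer diagnosis (the index date). Missing values use
#' the canonical token `"NA"` on disk (empty cells are also accepted on read);
#' booleans are serialized as 0/1 so files are locale-proof.
NULL

# column registry: name -> type
.subject_cols <- c(
  subject_id = "character",
  age = "numeric",
  sex = "character",
  systolic_bp = "numeric",
  diastolic_bp = "numeric",
  antihypertensive_use = "logical",
  diabetes = "logical",
  coronary_artery_disease = "logical",
  cerebrovascular_disease = "logical",
  peripheral_artery_disease = "logical",
  heart_failure = "logical",
  valvular_disease = "logical",
  arrhythmia = "logical",
  egfr = "numeric",
  ckd_diagnosis = "logical",
  current_smoker = "logical",
  bmi = "numeric",
  total_cholesterol = "numeric",
  hdl_cholesterol = "numeric",
  prior_anthracycline = "logical",
  prior_nonanthracycline_chemo = "logical",
  prior_chest_rt = "logical"
)

.context_cols <- c(
  cancer_type = "character",
  metastatic = "logical",
  received_anthracycline = "logical",
  received_her2 = "logical",
  received_vegf_iv = "logical",
  received_myeloma_tx = "logical",
  received_cardiotoxic_rt = "logical"
)

.optional_cols <- c(followup_years = "numeric")

.event_cols <- c(
  subject_id = "character",
  event_type = "character",
  time_years = "numeric",
  dx_position = "character"
)

#' Eight cancer-diagnosis groups
#' @export
cancer_types <- function() {
  c("gastrointestinal", "lung", "melanoma", "breast", "female_genital",
    "prostate", "lymphoma_hematological", "other_solid")
}

#' Recognized event types
#' @export
event_types <- function() c("HF_HOSP", "MI", "STROKE", "CVD_DEATH", "NONCVD_DEATH")

.parse_col <- function(x, type, col, warn_ctx) {
  x[x %in% c("", "NA")] <- NA_character_
  if (type == "character") return(x)
  if (type == "numeric") {
    out <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & is.na(out)
  } else { # logical, serialized 0/1 (TRUE/FALSE also accepted)
    out <- rep(NA, length(x))
    out[x %in% c("1", "TRUE", "true")] <- TRUE
    out[x %in% c("0", "FALSE", "false")] <- FALSE
    bad <- !is.na(x) & is.na(out)
  }
  if (any(bad)) {
    warning(sprintf("%s: %d unparseable cell(s) in column '%s' set to missing (e.g. '%s')",
                    warn_ctx, sum(bad), col, x[bad][1L]), call. = FALSE)
  }
  out
}

.read_typed_csv <- function(path, required, optional, ctx) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = TRUE,
                         stringsAsFactors = FALSE)
  missing_cols <- setdiff(names(required), names(raw))
  if (length(missing_cols) > 0L) {
    stop_named("%s '%s' is missing mandatory column(s): %s",
               ctx, path, paste(missing_cols, collapse = ", "))
  }
  types <- c(required, optional[names(optional) %in% names(raw)])
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (col in names(types)) {
    out[[col]] <- .parse_col(raw[[col]], types[[col]], col, basename(path))
  }
  out
}

#' Read a cohort from CSV
#'
#' Reads the subject table and (optionally) the long-format event table.
#' Unparseable cells become missing values with a warning; a duplicated
#' `subject_id` or an absent mandatory column is a hard error. No row is ever
#' silently dropped.
#'
#' @param subjects_file path to the subject-level CSV.
#' @param events_file optional path to the events CSV.
#' @return a list with elements `subjects` and `events` (the latter an empty
#'   data frame when no events file is given).
#' @seealso [write_cohort()], [cohort-format]
#' @export
read_cohort <- function(subjects_file, events_file = NULL) {
  subjects <- .read_typed_csv(subjects_file,
                              required = .subject_cols,
                              optional = c(.context_cols, .optional_cols),
                              ctx = "subject file")
  dup <- subjects$subject_id[duplicated(subjects$subject_id)]
  if (length(dup) > 0L) {
    stop_named("duplicate subject_id in '%s': %s",
               subjects_file, paste(unique(dup), collapse = ", "))
  }
  # ensure context columns exist even when absent from file
  for (col in names(.context_cols)) {
    if (is.null(subjects[[col]])) {
      subjects[[col]] <- if (.context_cols[[col]] == "logical") NA else NA_character_
    }
  }
  events <- if (is.null(events_file)) {
    empty_events()
  } else {
    .read_typed_csv(events_file,
                    required = .event_cols[c("subject_id", "event_type", "time_years")],
                    optional = .event_cols["dx_position"],
                    ctx = "events file")
  }
  if (is.null(events$dx_position)) events$dx_position <- NA_character_
  validate_cohort(subjects, events)
  list(subjects = subjects, events = events)
}

#' @keywords internal
#' @noRd
empty_events <- function() {
  data.frame(subject_id = character(0), event_type = character(0),
              time_years = numeric(0), dx_position = character(0),
              stringsAsFactors = FALSE)
}

#' Validate cohort invariants
#'
#' Checks the subject and event tables against the domain invariants:
#' positive age, nonnegative measurements, HDL below total cholesterol,
#' recognized event types, nonnegative event times, at most one death record
#' per subject, and no event after death.
#'
#' @param subjects,events cohort component data frames.
#' @return invisibly `TRUE`; errors name the offending subject or column.
#' @export
validate_cohort <- function(subjects, events = empty_events()) {
  chk <- function(bad, what) {
    if (any(bad, na.rm = TRUE)) {
      ids <- subjects$subject_id[which(bad)]
      stop_named("invalid %s for subject(s): %s", what,
                 paste(utils::head(ids, 5L), collapse = ", "))
    }
  }
  chk(subjects$age <= 0, "age (must be > 0)")
  for (col in c("systolic_bp", "diastolic_bp", "egfr", "bmi",
                "total_cholesterol", "hdl_cholesterol")) {
    chk(subjects[[col]] < 0, sprintf("%s (must be nonnegative)", col))
  }
  chk(subjects$hdl_cholesterol > subjects$total_cholesterol,
      "hdl_cholesterol (exceeds total_cholesterol)")
  bad_sex <- !is.na(subjects$sex) & !subjects$sex %in% c("male", "female")
  if (any(bad_sex)) stop_named("unrecognized sex value '%s'", subjects$sex[bad_sex][1L])

  if (nrow(events) > 0L) {
    bad_type <- !is.na(events$event_type) & !events$event_type %in% event_types()
    if (any(bad_type)) {
      stop_named("unrecognized event_type '%s'", events$event_type[bad_type][1L])
    }
    if (any(events$time_years < 0, na.rm = TRUE)) {
      stop_named("negative event time for subject %s",
                 events$subject_id[which(events$time_years < 0)][1L])
    }
    deaths <- events[events$event_type %in% c("CVD_DEATH", "NONCVD_DEATH"), ]
    dup_death <- deaths$subject_id[duplicated(deaths$subject_id)]
    if (length(dup_death) > 0L) {
      stop_named("more than one death record for subject %s", dup_death[1L])
    }
    if (nrow(deaths) > 0L) {
      death_time <- stats::setNames(deaths$time_years, deaths$subject_id)
      dt <- death_time[events$subject_id]
      after <- !is.na(dt) & events$time_years > dt
      if (any(after)) {
        stop_named("event after death for subject %s",
                   events$subject_id[which(after)][1L])
      }
    }
  }
  invisible(TRUE)
}

.serialize <- function(df) {
  out <- df
  for (col in names(out)) {
    x <- out[[col]]
    if (is.logical(x)) x <- as.integer(x)
    x <- as.character(x)
    x[is.na(x)] <- "NA"
    out[[col]] <- x
  }
  out
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: booleans are written as 0/1 and missing cells
#' as the canonical `"NA"` token, so that a write/read round trip reproduces
#' the cohort exactly.
#'
#' @param cohort list with `subjects` and `events` data frames.
#' @param subjects_file,events_file output paths (`events_file` optional).
#' @return invisibly the paths written.
#' @export
write_cohort <- function(cohort, subjects_file, events_file = NULL) {
  validate_cohort(cohort$subjects, cohort$events %||% empty_events())
  utils::write.csv(.serialize(cohort$subjects), subjects_file,
                   row.names = FALSE, quote = FALSE)
  if (!is.null(events_file)) {
    utils::write.csv(.serialize(cohort$events), events_file,
                     row.names = FALSE, quote = FALSE)
  }
  invisible(c(subjects_file, events_file))
}
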