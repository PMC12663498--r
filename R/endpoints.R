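#' Composite cardiovascular outcome for one subject
#'
#' Scans a subject's event stream for the first qualifying component of the
#' composite endpoint: heart-failure hospitalization with a *primary*
#' discharge diagnosis, nonfatal stroke (primary), nonfatal myocardial
#' infarction (primary *or* secondary), or cardiovascular death. The earliest
#' qualifying event at or before `horizon` gives status 1 at its time;
#' otherwise a non-cardiovascular death at or before `horizon` gives
#' competing status 2; otherwise the subject is censored (status 0) at
#' `horizon`. A qualifying event tied with a death at the identical time
#' resolves to the event ("first occurrence" semantics); an event at exactly
#' the horizon counts.
#'
#' @param events data frame of this subject's event records
#'   (`event_type`, `time_years`, `dx_position`); zero rows allowed.
#' @param horizon administrative follow-up horizon in years (> 0).
#' @return one-row data frame: `time`, `status` (0/1/2), `first_event_type`
#'   (`NA` unless status 1).
#' @export
build_outcome <- function(events, horizon) {
  stopifnot(horizon > 0)
  .build_outcome_impl(events, horizon,
                      qualifying = c("HF_HOSP", "MI", "STROKE", "CVD_DEATH"),
                      competing_types = "NONCVD_DEATH")
}

#' Single-cause outcome (sensitivity analyses)
#'
#' As [build_outcome()] but only the named cause qualifies (the primary-
#' diagnosis rule for HF hospitalization and the primary-or-secondary rule
#' for MI are retained); deaths of *any* cause become the competing event.
#'
#' @param events one subject's event records.
#' @param cause `"HF_HOSP"` or `"MI"`.
#' @param horizon follow-up horizon in years.
#' @return one-row outcome data frame as in [build_outcome()].
#' @export
build_single_cause_outcome <- function(events, cause = c("HF_HOSP", "MI"), horizon) {
  cause <- match.arg(cause)
  stopifnot(horizon > 0)
  .build_outcome_impl(events, horizon, qualifying = cause,
                      competing_types = c("CVD_DEATH", "NONCVD_DEATH"))
}

.qualifies <- function(type, dx_position, qualifying) {
  primary_only <- type %in% c("HF_HOSP", "STROKE")
  type %in% qualifying &
    (!primary_only | (!is.na(dx_position) & dx_position == "primary"))
}

.build_outcome_impl <- function(events, horizon, qualifying, competing_types) {
  if (is.null(events) || nrow(events) == 0L) {
    return(data.frame(time = horizon, status = 0L,
                      first_event_type = NA_character_,
                      stringsAsFactors = FALSE))
  }
  if (any(events$time_years < 0, na.rm = TRUE)) {
    stop_named("negative event time")
  }
  death_t <- events$time_years[events$event_type %in% c("CVD_DEATH", "NONCVD_DEATH")]
  if (length(death_t) > 0L && any(events$time_years > min(death_t))) {
    stop_named("event recorded after death")
  }
  in_window <- events$time_years <= horizon
  qual <- .qualifies(events$event_type, events$dx_position, qualifying) & in_window
  if (any(qual)) {
    i <- which(qual)[which.min(events$time_years[qual])]
    return(data.frame(time = events$time_years[i], status = 1L,
                      first_event_type = events$event_type[i],
                      stringsAsFactors = FALSE))
  }
  comp <- events$event_type %in% competing_types & in_window
  if (any(comp)) {
    return(data.frame(time = min(events$time_years[comp]), status = 2L,
                      first_event_type = NA_character_,
                      stringsAsFactors = FALSE))
  }
  data.frame(time = horizon, status = 0L, first_event_type = NA_character_,
             stringsAsFactors = FALSE)
}

#' Build outcomes for a whole cohort
#'
#' Applies [build_outcome()] (or [build_single_cause_outcome()]) to every
#' subject. `horizon` may be a scalar (common administrative horizon) or a
#' vector parallel to `subject_ids` (per-subject administrative censoring
#' times, e.g. `followup_years` from the synthetic generator).
#'
#' @param events cohort event data frame (see [cohort-format]).
#' @param subject_ids character vector of all subject ids (subjects without
#'   events are censored at their horizon).
#' @param horizon scalar or per-subject numeric vector of years.
#' @param cause `NULL` for the composite endpoint, else `"HF_HOSP"` or `"MI"`.
#' @return data frame: `subject_id`, `time`, `status`, `first_event_type`.
#' @export
build_outcomes <- function(events, subject_ids, horizon, cause = NULL) {
  n <- length(subject_ids)
  horizon <- rep_len(horizon, n)
  by_subject <- if (nrow(events) > 0L) {
    split(events, factor(events$subject_id, levels = subject_ids))
  } else {
    NULL
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ev <- by_subject[[subject_ids[i]]]
    rows[[i]] <- if (is.null(cause)) build_outcome(ev, horizon[i])
                 else build_single_cause_outcome(ev, cause, horizon[i])
  }
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(subject_id = subject_ids, stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}

#' Interval incidence
#'
#' Event rates in consecutive half-open time intervals \[k*bin, (k+1)*bin):
#' `n_at_risk` counts subjects whose outcome time is at or past the interval
#' start, `n_events` the primary events (status 1) inside the interval, and
#' `rate = n_events / n_at_risk`. The default bin of 0.5 years gives the
#' 6-month interval incidence used to visualize event-rate trends.
#'
#' @param outcomes outcome data frame (`time`, `status`).
#' @param bin interval width in years (> 0).
#' @return data frame: `interval_start`, `interval_end`, `n_at_risk`,
#'   `n_events`, `rate`.
#' @export
interval_incidence <- function(outcomes, bin = 0.5) {
  stopifnot(bin > 0)
  if (nrow(outcomes) == 0L) {
    return(data.frame(interval_start = numeric(0), interval_end = numeric(0),
                      n_at_risk = integer(0), n_events = integer(0),
                      rate = numeric(0)))
  }
  k_max <- floor(max(outcomes$time) / bin)
  starts <- bin * (0:k_max)
  n_at_risk <- vapply(starts, function(s) sum(outcomes$time >= s), integer(1))
  idx <- pmin(floor(outcomes$time / bin), k_max)  # event at a bin edge falls in that bin
  ev <- outcomes$status == 1L
  n_events <- vapply(0:k_max, function(k) sum(ev & idx == k), integer(1))
  data.frame(interval_start = starts, interval_end = starts + bin,
             n_at_risk = n_at_risk, n_events = n_events,
             rate = ifelse(n_at_risk > 0, n_events / n_at_risk, NA_real_))
}
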