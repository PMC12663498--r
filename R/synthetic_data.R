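#' Default per-category predictor prevalences
#'
#' Conditional prevalence table used by [generate_cohort()]: for each risk
#' category (LOW, MODERATE, HIGH, VERY_HIGH) the probability of each binary
#' predictor, the mean/SD of the continuous ones, the cancer-type mix and the
#' post-baseline treatment probabilities. Defaults reproduce the category-
#' stratified frequency tables of the external validation cohort this
#' package emulates; note the structural zeros (no established
#' cardiovascular disease, and no prior anthracycline, below HIGH; heart
#' failure only in VERY_HIGH).
#'
#' @return a list of matrices, each with one column per risk category.
#' @export
default_prevalence <- function() {
  cats <- risk_levels()
  binary <- rbind(
    diabetes                    = c(5 / 631, 46 / 806, 119 / 785, 16 / 68),
    coronary_artery_disease     = c(0, 0, 338 / 785, 44 / 68),
    cerebrovascular_disease     = c(0, 0, 188 / 785, 12 / 68),
    peripheral_artery_disease   = c(0, 0, 130 / 785, 16 / 68),
    heart_failure               = c(0, 0, 0, 1),
    valvular_disease            = c(0, 0, 75 / 785, 17 / 68),
    arrhythmia                  = c(0, 44 / 806, 103 / 785, 39 / 68),
    obese                       = c(56 / 631, 255 / 806, 233 / 785, 24 / 68),
    ckd                         = c(0, 33 / 806, 183 / 785, 29 / 68),
    current_smoker              = c(137 / 631, 223 / 806, 185 / 785, 11 / 68),
    antihypertensive_use        = c(52 / 631, 298 / 806, 483 / 785, 49 / 68),
    prior_anthracycline         = c(0, 0, 0.03, 0.04),
    prior_nonanthracycline_chemo = c(0.02, 0.04, 0.05, 0.06),
    prior_chest_rt              = c(0.01, 0.03, 0.04, 0.04),
    male                        = c(279 / 631, 418 / 806, 453 / 785, 44 / 68),
    metastatic                  = c(85 / 631, 141 / 806, 188 / 785, 15 / 68),
    received_anthracycline      = c(127 / 631, 94 / 806, 31 / 785, 3 / 68),
    received_her2               = c(21 / 631, 7 / 806, 0, 1 / 68),
    received_vegf_iv            = c(23 / 631, 19 / 806, 10 / 785, 0),
    received_myeloma_tx         = c(7 / 631, 12 / 806, 18 / 785, 4 / 68),
    received_cardiotoxic_rt     = c(64 / 631, 60 / 806, 49 / 785, 4 / 68)
  )
  colnames(binary) <- cats
  continuous <- list(
    age  = rbind(mean = c(52.6, 66.9, 74.4, 73.9), sd = c(9.2, 8.6, 8.9, 8.5)),
    systolic_bp = rbind(mean = c(127, 142, 141, 133), sd = c(16, 19, 20, 21)),
    total_cholesterol = rbind(mean = c(5.6, 5.8, 5.4, 4.9), sd = c(1.0, 1.1, 1.2, 1.1)),
    hdl_cholesterol = rbind(mean = c(1.4, 1.4, 1.3, 1.2), sd = c(0.3, 0.4, 0.3, 0.3))
  )
  continuous <- lapply(continuous, function(x) { colnames(x) <- cats; x })
  cancer <- rbind(
    gastrointestinal       = c(103, 177, 223, 26),
    lung                   = c(35, 66, 99, 7),
    melanoma               = c(84, 87, 93, 8),
    breast                 = c(130, 93, 44, 6),
    female_genital         = c(52, 47, 31, 3),
    prostate               = c(111, 162, 142, 10),
    lymphoma_hematological = c(47, 62, 63, 7),
    other_solid            = c(69, 112, 90, 1)
  )
  cancer <- sweep(cancer, 2L, colSums(cancer), "/")
  colnames(cancer) <- cats
  list(binary = binary, continuous = continuous, cancer = cancer)
}

#' Synthetic cohort configuration
#'
#' Defines the statistical conditions the generator emulates. Defaults are
#' the reported conditions of the validation cohort: n = 2,290 subjects, a
#' 28/35/34/3% category mix, per-category composite-CVD cumulative incidence
#' of 7/21/29/37% at 6.9 years, all-cause mortality of 32/55/79/89% at 8.7
#' years, administrative censoring Uniform(11, 17) years (diagnosis
#' 2006-2012, follow-up through 2023), and a first-event cause split of
#' 87/161/130/82 (HF hospitalization / MI / stroke / CVD death) out of 460.
#'
#' @param n cohort size.
#' @param seed integer seed; generation is fully deterministic given it.
#' @param category_mix four proportions summing to 1 (LOW..VERY_HIGH).
#' @param prevalence prevalence tables, see [default_prevalence()].
#' @param cvd_targets,cvd_horizon per-category composite cumulative
#'   incidence targets and the anchor time (years).
#' @param death_targets,death_horizon per-category all-cause mortality
#'   targets and anchor.
#' @param hazards optional 4x2 matrix (columns `lambda_cvd`, `lambda_death`)
#'   of per-category cause-specific rates per year; when `NULL` they are
#'   calibrated from the targets via [calibrate_marginal_hazards()].
#' @param censoring_window length-2 vector, administrative censoring is
#'   Uniform(min, max) years.
#' @param cause_split probabilities of the first composite event being an HF
#'   hospitalization, MI, stroke or CVD death.
#' @param mi_secondary_prob probability a generated MI carries a secondary
#'   (rather than primary) discharge position — both qualify.
#' @param secondary_hf_rate rate of nuisance HF hospitalizations with a
#'   *secondary* discharge diagnosis (which must never qualify), inserted to
#'   exercise the endpoint filters.
#' @param missingness_rate per-predictor MCAR missingness applied to the
#'   measured baseline variables (0 = the post-imputation analysis dataset).
#' @return list of class `synthetic_cohort_config`.
#' @export
synthetic_cohort_config <- function(n = 2290L,
                                    seed = 1L,
                                    category_mix = c(0.28, 0.35, 0.34, 0.03),
                                    prevalence = default_prevalence(),
                                    cvd_targets = c(0.07, 0.21, 0.29, 0.37),
                                    cvd_horizon = 6.9,
                                    death_targets = c(0.32, 0.55, 0.79, 0.89),
                                    death_horizon = 8.7,
                                    hazards = NULL,
                                    censoring_window = c(11, 17),
                                    cause_split = c(HF_HOSP = 87, MI = 161,
                                                    STROKE = 130, CVD_DEATH = 82) / 460,
                                    mi_secondary_prob = 0.5,
                                    secondary_hf_rate = 0.05,
                                    missingness_rate = 0) {
  stopifnot(n >= 1L, length(category_mix) == 4L,
            abs(sum(category_mix) - 1) < 1e-8,
            length(censoring_window) == 2L, all(censoring_window > 0),
            censoring_window[2L] >= censoring_window[1L],
            abs(sum(cause_split) - 1) < 1e-8,
            missingness_rate >= 0, missingness_rate < 1)
  # structural consistency: factors that force >= HIGH must have zero
  # prevalence in LOW and MODERATE, heart failure zero below VERY_HIGH
  forcing <- c("coronary_artery_disease", "cerebrovascular_disease",
               "peripheral_artery_disease", "valvular_disease",
               "prior_anthracycline")
  if (any(prevalence$binary[forcing, c("LOW", "MODERATE")] > 0)) {
    stop_named("prevalence table inconsistent: high-risk factor prevalence > 0 in LOW/MODERATE")
  }
  if (any(prevalence$binary["heart_failure", c("LOW", "MODERATE", "HIGH")] > 0)) {
    stop_named("prevalence table inconsistent: heart failure prevalence > 0 below VERY_HIGH")
  }
  if (!is.null(hazards)) {
    hazards <- as.matrix(hazards)
    stopifnot(nrow(hazards) == 4L, ncol(hazards) == 2L, all(hazards >= 0))
    colnames(hazards) <- c("lambda_cvd", "lambda_death")
  }
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 category_mix = category_mix, prevalence = prevalence,
                 cvd_targets = cvd_targets, cvd_horizon = cvd_horizon,
                 death_targets = death_targets, death_horizon = death_horizon,
                 hazards = hazards, censoring_window = censoring_window,
                 cause_split = cause_split,
                 mi_secondary_prob = mi_secondary_prob,
                 secondary_hf_rate = secondary_hf_rate,
                 missingness_rate = missingness_rate),
            class = "synthetic_cohort_config")
}

#' Calibrate competing exponential hazards to two cumulative incidences
#'
#' Under independent exponential cause-specific hazards the cause-k
#' cumulative incidence is F_k(t) = (lambda_k / Lambda) (1 - exp(-Lambda t))
#' with Lambda the total rate. Given both causes' target incidences at a
#' common horizon the solution is unique and available in closed form:
#' Lambda = -log(1 - p1 - p2) / t and lambda_k = p_k Lambda / (p1 + p2).
#'
#' @param target_cif_cvd,target_cif_death target cumulative incidences in
#'   (0, 1) with sum < 1 (either may be 0).
#' @param horizon_years anchor time t.
#' @return named vector `c(lambda_cvd, lambda_death)` (per year).
#' @export
calibrate_exponential_hazards <- function(target_cif_cvd, target_cif_death,
                                          horizon_years) {
  p1 <- target_cif_cvd; p2 <- target_cif_death
  stopifnot(horizon_years > 0, p1 >= 0, p2 >= 0)
  if (p1 + p2 >= 1) stop_named("infeasible targets: cumulative incidences sum to >= 1")
  if (p1 + p2 == 0) return(c(lambda_cvd = 0, lambda_death = 0))
  lambda_total <- -log(1 - p1 - p2) / horizon_years
  c(lambda_cvd = p1 * lambda_total / (p1 + p2),
    lambda_death = p2 * lambda_total / (p1 + p2))
}

#' Calibrate hazards to a CVD incidence and an all-cause mortality target
#'
#' The generator's calibration: composite-CVD cumulative incidence is a
#' competing-risk quantity anchored at `cvd_horizon`, but the mortality
#' target is *all-cause* — it includes subjects whose first CVD event was
#' fatal as well as subjects who died after a nonfatal CVD event — so it
#' constrains the marginal death process, not the competing-death CIF (for
#' high-risk strata the two targets would otherwise be infeasible, summing
#' above 1). With latent independent times T_cvd ~ Exp(lambda_cvd),
#' T_death ~ Exp(lambda_death) and a fatal share q of first CVD events, the
#' system solved (to 1e-10, nested bisection) is
#' \deqn{(\lambda_c/\Lambda)(1 - e^{-\Lambda h_1}) = p_{cvd}}
#' \deqn{(1 - e^{-\lambda_d h_2}) + q e^{-\lambda_d h_2}(1 - e^{-\lambda_c h_2}) = p_{death}}
#'
#' @param target_cif_cvd composite cumulative incidence at `cvd_horizon`.
#' @param cvd_horizon anchor for the CVD target (years).
#' @param target_mortality all-cause mortality at `death_horizon`.
#' @param death_horizon anchor for the mortality target (years).
#' @param fatal_share probability a first composite event is a CVD death.
#' @return named vector `c(lambda_cvd, lambda_death)`.
#' @export
calibrate_marginal_hazards <- function(target_cif_cvd, cvd_horizon,
                                       target_mortality, death_horizon,
                                       fatal_share = 82 / 460) {
  stopifnot(target_cif_cvd > 0, target_cif_cvd < 1,
            target_mortality > 0, target_mortality < 1,
            cvd_horizon > 0, death_horizon > 0,
            fatal_share >= 0, fatal_share <= 1)
  solve_ld <- function(lc) {
    f <- function(ld) {
      (1 - exp(-ld * death_horizon)) +
        fatal_share * exp(-ld * death_horizon) * (1 - exp(-lc * death_horizon)) -
        target_mortality
    }
    stats::uniroot(f, c(1e-12, 50), tol = 1e-12)$root
  }
  resid <- function(lc) {
    ld <- solve_ld(lc)
    tot <- lc + ld
    (lc / tot) * (1 - exp(-tot * cvd_horizon)) - target_cif_cvd
  }
  lc <- stats::uniroot(resid, c(1e-10, 50), tol = 1e-12)$root
  c(lambda_cvd = lc, lambda_death = solve_ld(lc))
}

.category_hazards <- function(config) {
  if (!is.null(config$hazards)) return(config$hazards)
  out <- t(vapply(1:4, function(k) {
    calibrate_marginal_hazards(config$cvd_targets[k], config$cvd_horizon,
                               config$death_targets[k], config$death_horizon,
                               fatal_share = config$cause_split[["CVD_DEATH"]])
  }, numeric(2)))
  rownames(out) <- risk_levels()
  out
}

.rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, pl, pu), mean, sd)
}

# draw raw predictors conditional on intended category (before repair)
.draw_predictors <- function(n, cat_idx, prev) {
  draw_bin <- function(row) stats::runif(n) < prev$binary[row, cat_idx]
  cont <- function(name, lower, upper) {
    par <- prev$continuous[[name]]
    .rtrunc_norm(n, par["mean", cat_idx], par["sd", cat_idx], lower, upper)
  }
  obese <- draw_bin("obese")
  low_egfr <- draw_bin("ckd")
  # a recorded CKD diagnosis accompanies a low eGFR in a subset of cases, so
  # the derived CKD flag prevalence equals the configured one exactly
  ckd_dx <- low_egfr & stats::runif(n) < 0.3
  df <- data.frame(
    subject_id = sprintf("S%05d", seq_len(n)),
    age = round(cont("age", 18, 95), 1),
    sex = ifelse(draw_bin("male"), "male", "female"),
    systolic_bp = round(cont("systolic_bp", 80, 230)),
    diastolic_bp = round(.rtrunc_norm(n, 78, 10, 45, 130)),
    antihypertensive_use = draw_bin("antihypertensive_use"),
    diabetes = draw_bin("diabetes"),
    coronary_artery_disease = draw_bin("coronary_artery_disease"),
    cerebrovascular_disease = draw_bin("cerebrovascular_disease"),
    peripheral_artery_disease = draw_bin("peripheral_artery_disease"),
    heart_failure = draw_bin("heart_failure"),
    valvular_disease = draw_bin("valvular_disease"),
    arrhythmia = draw_bin("arrhythmia"),
    egfr = round(ifelse(low_egfr, .rtrunc_norm(n, 48, 8, 15, 59.4),
                        .rtrunc_norm(n, 85, 14, 60, 130))),
    ckd_diagnosis = ckd_dx,
    current_smoker = draw_bin("current_smoker"),
    bmi = round(ifelse(obese, .rtrunc_norm(n, 33, 2.5, 30.1, 45),
                       .rtrunc_norm(n, 26, 2.5, 17, 30)), 1),
    total_cholesterol = round(cont("total_cholesterol", 2, 10), 1),
    hdl_cholesterol = round(cont("hdl_cholesterol", 0.5, 3), 1),
    prior_anthracycline = draw_bin("prior_anthracycline"),
    prior_nonanthracycline_chemo = draw_bin("prior_nonanthracycline_chemo"),
    prior_chest_rt = draw_bin("prior_chest_rt"),
    stringsAsFactors = FALSE
  )
  df$hdl_cholesterol <- pmin(df$hdl_cholesterol, df$total_cholesterol - 0.5)
  # cancer context
  u <- stats::runif(n)
  cum <- apply(prev$cancer, 2L, cumsum)
  df$cancer_type <- rownames(prev$cancer)[
    vapply(seq_len(n), function(i) 1L + sum(u[i] > cum[, cat_idx[i]]), integer(1))]
  # sex-specific cancers override the independently drawn sex
  df$sex[df$cancer_type == "prostate"] <- "male"
  df$sex[df$cancer_type == "female_genital"] <- "female"
  df$sex[df$cancer_type == "breast" & stats::runif(n) < 0.99] <- "female"
  df$metastatic <- draw_bin("metastatic")
  df$received_anthracycline <- draw_bin("received_anthracycline")
  df$received_her2 <- draw_bin("received_her2")
  df$received_vegf_iv <- draw_bin("received_vegf_iv")
  df$received_myeloma_tx <- draw_bin("received_myeloma_tx")
  df$received_cardiotoxic_rt <- draw_bin("received_cardiotoxic_rt")
  df
}

# minimal repair so the scoring engine maps each subject to its intended
# category; returns list(subjects, log)
.repair_to_category <- function(df, intended, config) {
  log_env <- new.env()
  log_env$counts <- integer(0)
  note <- function(field, n) {
    if (n == 0L) return()
    cur <- log_env$counts
    cur[field] <- (if (field %in% names(cur)) cur[[field]] else 0L) + n
    log_env$counts <- cur
  }
  set_field <- function(mask, field, value) {
    n <- sum(mask)
    if (n > 0L) df[[field]][mask] <<- if (length(value) == 1L) value else value[mask]
    note(field, n)
  }
  low <- intended == "LOW"; mod <- intended == "MODERATE"
  high <- intended == "HIGH"; vh <- intended == "VERY_HIGH"

  # very-high flag
  set_field(vh & !df$heart_failure, "heart_failure", TRUE)
  set_field(!vh & df$heart_failure, "heart_failure", FALSE)
  # strip high factors below HIGH
  for (f in c("coronary_artery_disease", "cerebrovascular_disease",
              "peripheral_artery_disease", "prior_anthracycline")) {
    set_field((low | mod) & df[[f]], f, FALSE)
  }
  set_field((low | mod) & df$valvular_disease, "valvular_disease", FALSE)
  # age constraints: LOW needs < 65 (an age of 65-79 alone is 2 points),
  # MODERATE needs < 80 (>= 80 is a high factor)
  mask <- low & df$age >= 65
  set_field(mask, "age", round(.rtrunc_norm(nrow(df), 52.6, 9.2, 18, 64.9), 1))
  mask <- mod & df$age >= 80
  set_field(mask, "age", round(stats::runif(nrow(df), 65, 79.9), 1))

  recompute <- function() {
    derived <- derive_predictors(df, strict = FALSE)
    score_medium_points(derived, df)
  }
  pts <- recompute()

  # HIGH must fire a flag or reach 5 points
  flags <- collect_risk_flags(df)
  has_high <- vapply(flags$high, length, integer(1)) > 0L
  set_field(high & !has_high & pts < 5L, "coronary_artery_disease", TRUE)

  # cap medium points: LOW <= 1, MODERATE in [2, 4]
  cap <- ifelse(low, 1L, ifelse(mod, 4L, NA_integer_))
  # removal candidates: (field-level action, point value, active test)
  remove_one <- function(mask, what) {
    switch(what,
      arrhythmia = set_field(mask, "arrhythmia", FALSE),
      current_smoker = set_field(mask, "current_smoker", FALSE),
      obesity = set_field(mask, "bmi", round(.rtrunc_norm(nrow(df), 26, 2, 19, 29.5), 1)),
      prior_chest_rt = set_field(mask, "prior_chest_rt", FALSE),
      prior_nonanthracycline_chemo = set_field(mask, "prior_nonanthracycline_chemo", FALSE),
      hyperlipidemia = set_field(mask, "total_cholesterol",
                                 round(df$hdl_cholesterol + 3.3, 1)),
      ckd = { set_field(mask & df$egfr < 60, "egfr", 75)
              set_field(mask & df$ckd_diagnosis, "ckd_diagnosis", FALSE) },
      diabetes = set_field(mask, "diabetes", FALSE),
      hypertension = { set_field(mask & df$antihypertensive_use,
                                 "antihypertensive_use", FALSE)
                       set_field(mask & df$systolic_bp > 140, "systolic_bp", 132)
                       set_field(mask & df$diastolic_bp > 90, "diastolic_bp", 84) }
    )
  }
  candidates <- list(
    list("arrhythmia", 2L, function(d) df$arrhythmia),
    list("current_smoker", 1L, function(d) df$current_smoker),
    list("obesity", 1L, function(d) d$obesity),
    list("prior_chest_rt", 1L, function(d) df$prior_chest_rt),
    list("prior_nonanthracycline_chemo", 1L, function(d) df$prior_nonanthracycline_chemo),
    list("hyperlipidemia", 1L, function(d) d$hyperlipidemia),
    list("ckd", 1L, function(d) d$ckd),
    list("diabetes", 1L, function(d) df$diabetes),
    list("hypertension", 1L, function(d) d$hypertension)
  )
  for (round_i in 1:2) {
    for (cand in candidates) {
      derived <- derive_predictors(df, strict = FALSE)
      pts <- score_medium_points(derived, df)
      excess <- pts - cap
      active <- cand[[3L]](derived)
      # a 2-point factor is only removed when the excess allows it, except
      # in round 2 for LOW where undershoot is harmless
      allow <- !is.na(excess) & excess >= 1L & active &
        (cand[[2L]] <= excess | (round_i == 2L & low))
      if (any(allow)) { remove_one(allow, cand[[1L]]); pts[allow] <- pts[allow] - cand[[2L]] }
    }
  }
  # raise MODERATE subjects with too few points
  for (adder in c("antihypertensive_use", "diabetes", "current_smoker")) {
    derived <- derive_predictors(df, strict = FALSE)
    pts <- score_medium_points(derived, df)
    need <- mod & pts < 2L & !df[[adder]] &
      !(adder == "antihypertensive_use" & derived$hypertension)
    set_field(need, adder, TRUE)
  }
  counts <- log_env$counts
  log <- data.frame(field = names(counts), n_changed = as.integer(counts),
                    row.names = NULL, stringsAsFactors = FALSE)
  list(subjects = df, log = log)
}

#' Generate a synthetic cancer cohort
#'
#' Category-first construction: each subject's intended risk category is
#' drawn from the configured mix, raw predictors are drawn from that
#' category's conditional prevalence table, and the draw is then minimally
#' repaired so the scoring engine maps the subject exactly to the intended
#' category (every repair is counted in the returned log). Latent competing
#' exponential event times with the category's calibrated rates and uniform
#' administrative censoring produce the event stream: first composite events
#' are split into HF hospitalization / MI / stroke / CVD death per the cause
#' split (MIs randomly primary or secondary — both qualify), deaths after a
#' nonfatal event appear as non-CVD death records, and nuisance secondary-
#' diagnosis HF hospitalizations (which must never qualify) are sprinkled in.
#'
#' @param config a [synthetic_cohort_config()].
#' @return list of class `synthetic_cohort`: `subjects` (with
#'   `followup_years` = administrative censoring time), `events`,
#'   `intended_category`, `hazards`, `repair_log`.
#' @export
generate_cohort <- function(config = synthetic_cohort_config()) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  set.seed(config$seed)
  n <- config$n
  cat_idx <- sample.int(4L, n, replace = TRUE, prob = config$category_mix)
  intended <- factor(risk_levels()[cat_idx], levels = risk_levels())
  df <- .draw_predictors(n, cat_idx, config$prevalence)
  rep_out <- .repair_to_category(df, intended, config)
  df <- rep_out$subjects

  hazards <- .category_hazards(config)
  lc <- hazards[cat_idx, 1L]; ld <- hazards[cat_idx, 2L]
  t_cvd <- ifelse(lc > 0, stats::rexp(n) / lc, Inf)
  t_death <- ifelse(ld > 0, stats::rexp(n) / ld, Inf)
  cens <- stats::runif(n, config$censoring_window[1L], config$censoring_window[2L])
  df$followup_years <- cens

  is_event <- t_cvd <= pmin(t_death, cens)
  is_comp <- !is_event & t_death <= cens
  ev_type <- rep(NA_character_, n)
  k <- sum(is_event)
  if (k > 0L) {
    ev_type[is_event] <- sample(names(config$cause_split), k, replace = TRUE,
                                prob = config$cause_split)
  }
  rows <- list()
  add <- function(id, type, time, pos) {
    rows[[length(rows) + 1L]] <<- data.frame(
      subject_id = id, event_type = type, time_years = time,
      dx_position = pos, stringsAsFactors = FALSE)
  }
  i_ev <- which(is_event)
  if (length(i_ev) > 0L) {
    pos <- ifelse(ev_type[i_ev] == "MI",
                  ifelse(stats::runif(length(i_ev)) < config$mi_secondary_prob,
                         "secondary", "primary"),
                  ifelse(ev_type[i_ev] == "CVD_DEATH", NA_character_, "primary"))
    add(df$subject_id[i_ev], ev_type[i_ev], t_cvd[i_ev], pos)
    # death after a nonfatal first event
    later_death <- i_ev[ev_type[i_ev] != "CVD_DEATH" & t_death[i_ev] <= cens[i_ev]]
    if (length(later_death) > 0L) {
      add(df$subject_id[later_death], "NONCVD_DEATH", t_death[later_death],
          NA_character_)
    }
  }
  i_comp <- which(is_comp)
  if (length(i_comp) > 0L) {
    add(df$subject_id[i_comp], "NONCVD_DEATH", t_death[i_comp], NA_character_)
  }
  # nuisance secondary-diagnosis HF hospitalizations (never qualify)
  end_time <- pmin(ifelse(is_event & ev_type == "CVD_DEATH", t_cvd,
                          ifelse(t_death <= cens, t_death, cens)), cens)
  nuis <- which(stats::runif(n) < config$secondary_hf_rate & end_time > 0)
  if (length(nuis) > 0L) {
    add(df$subject_id[nuis], "HF_HOSP",
        stats::runif(length(nuis), 0, end_time[nuis]), "secondary")
  }
  events <- if (length(rows) > 0L) do.call(rbind, rows) else empty_events()
  events <- events[order(events$subject_id, events$time_years), , drop = FALSE]
  rownames(events) <- NULL

  if (config$missingness_rate > 0) {
    for (col in c("systolic_bp", "diastolic_bp", "bmi", "total_cholesterol",
                  "hdl_cholesterol", "egfr", "current_smoker")) {
      hit <- stats::runif(n) < config$missingness_rate
      df[[col]][hit] <- NA
    }
  }
  structure(list(subjects = df, events = events, intended_category = intended,
                 hazards = hazards, repair_log = rep_out$log, config = config),
            class = "synthetic_cohort")
}

#' Generate a cohort plus closed-form expectations
#'
#' Returns the cohort together with the quantities the competing-exponential
#' model implies in closed form, for assertion in tests: per-category crude
#' event/competing-death probabilities under the uniform censoring window
#' (P(status = 1) = (lambda_c/Lambda)(1 - E\[exp(-Lambda C)\]) with
#' E\[exp(-Lambda C)\] = (exp(-Lambda a) - exp(-Lambda b)) / (Lambda (b - a))),
#' the cumulative incidence at the CVD anchor, and expected event counts.
#'
#' @param config a [synthetic_cohort_config()].
#' @return list: `cohort`, `expected` (data frame per category).
#' @export
generate_validation_scenario <- function(config = synthetic_cohort_config()) {
  cohort <- generate_cohort(config)
  hz <- cohort$hazards
  a <- config$censoring_window[1L]; b <- config$censoring_window[2L]
  per_cat <- lapply(1:4, function(k) {
    lc <- hz[k, 1L]; ld <- hz[k, 2L]; tot <- lc + ld
    if (tot == 0) {
      p1 <- p2 <- cif_h <- 0
    } else {
      e_cens <- if (b > a) (exp(-tot * a) - exp(-tot * b)) / (tot * (b - a))
                else exp(-tot * a)
      p1 <- (lc / tot) * (1 - e_cens)
      p2 <- (ld / tot) * (1 - e_cens)
      cif_h <- (lc / tot) * (1 - exp(-tot * config$cvd_horizon))
    }
    data.frame(category = risk_levels()[k],
               p_event = p1, p_competing = p2,
               cif_at_horizon = cif_h,
               expected_events = config$n * config$category_mix[k] * p1)
  })
  expected <- do.call(rbind, per_cat)
  list(cohort = cohort, expected = expected)
}
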