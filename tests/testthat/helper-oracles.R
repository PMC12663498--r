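# independent oracles and fixture builders, used across test files

# O(n^2) brute-force Harrell concordance: every ordered pair examined
brute_force_c <- function(score, time, event) {
  n <- length(score)
  conc <- tied <- comp <- 0
  for (i in seq_len(n)) {
    if (event[i] != 1L) next
    for (j in seq_len(n)) {
      if (j == i || time[j] <= time[i]) next
      comp <- comp + 1
      if (score[i] > score[j]) conc <- conc + 1
      else if (score[i] == score[j]) tied <- tied + 1
    }
  }
  list(c = (conc + 0.5 * tied) / comp, comparable = comp,
       concordant = conc, tied = tied)
}

# naive Breslow log partial likelihood, O(n^2), independent of the package
naive_breslow_loglik <- function(beta, x, time, event) {
  eta <- drop(as.matrix(x) %*% beta)
  ll <- 0
  for (i in which(event == 1L)) {
    risk <- time >= time[i]
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  ll
}

# a complete, clean subject row; override fields as needed
make_subject <- function(id = "S1", ...) {
  base <- data.frame(
    subject_id = id, age = 50, sex = "female",
    systolic_bp = 120, diastolic_bp = 75, antihypertensive_use = FALSE,
    diabetes = FALSE, coronary_artery_disease = FALSE,
    cerebrovascular_disease = FALSE, peripheral_artery_disease = FALSE,
    heart_failure = FALSE, valvular_disease = FALSE, arrhythmia = FALSE,
    egfr = 90, ckd_diagnosis = FALSE, current_smoker = FALSE, bmi = 24,
    total_cholesterol = 4.5, hdl_cholesterol = 1.4,
    prior_anthracycline = FALSE, prior_nonanthracycline_chemo = FALSE,
    prior_chest_rt = FALSE,
    cancer_type = "breast", metastatic = FALSE,
    received_anthracycline = FALSE, received_her2 = FALSE,
    received_vegf_iv = FALSE, received_myeloma_tx = FALSE,
    received_cardiotoxic_rt = FALSE,
    stringsAsFactors = FALSE
  )
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}

make_subjects <- function(...) do.call(rbind, list(...))

make_events <- function(subject_id = character(0), event_type = character(0),
                        time_years = numeric(0), dx_position = NA_character_) {
  if (length(subject_id) == 0L) {
    return(data.frame(subject_id = character(0), event_type = character(0),
                      time_years = numeric(0), dx_position = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(subject_id = subject_id, event_type = event_type,
             time_years = time_years,
             dx_position = rep_len(dx_position, length(subject_id)),
             stringsAsFactors = FALSE)
}

# random complete profile for fuzzing the scoring engine
random_profile <- function(id) {
  make_subject(
    id,
    age = runif(1, 20, 95),
    sex = sample(c("male", "female"), 1),
    systolic_bp = runif(1, 95, 200),
    diastolic_bp = runif(1, 55, 110),
    antihypertensive_use = runif(1) < 0.3,
    diabetes = runif(1) < 0.2,
    coronary_artery_disease = runif(1) < 0.2,
    cerebrovascular_disease = runif(1) < 0.15,
    peripheral_artery_disease = runif(1) < 0.1,
    heart_failure = runif(1) < 0.1,
    valvular_disease = runif(1) < 0.1,
    arrhythmia = runif(1) < 0.15,
    egfr = runif(1, 25, 120),
    ckd_diagnosis = runif(1) < 0.1,
    current_smoker = runif(1) < 0.3,
    bmi = runif(1, 18, 42),
    total_cholesterol = runif(1, 3.5, 8),
    hdl_cholesterol = runif(1, 0.7, 2.2),
    prior_anthracycline = runif(1) < 0.1,
    prior_nonanthracycline_chemo = runif(1) < 0.15,
    prior_chest_rt = runif(1) < 0.1
  )
}

# simulate from a Fine-Gray subdistribution model with true coefficient beta1
# for cause 1 (Fine & Gray 1999 construction, baseline mass p at infinity)
simulate_subdistribution <- function(n, beta1, p = 0.4, cens_max = 6) {
  x <- rbinom(n, 1, 0.5)
  eta <- exp(x * beta1)
  pmax_x <- 1 - (1 - p)^eta
  v <- runif(n)
  cause1 <- v <= pmax_x
  t <- numeric(n)
  # inverse of F1(t|x) = 1 - (1 - p(1 - e^-t))^eta at v
  t[cause1] <- -log(1 - (1 - (1 - v[cause1])^(1 / eta[cause1])) / p)
  t[!cause1] <- rexp(sum(!cause1), rate = 1)
  cens <- runif(n, 0, cens_max)
  time <- pmin(t, cens)
  status <- ifelse(t <= cens, ifelse(cause1, 1L, 2L), 0L)
  list(x = cbind(x = x), time = time, status = status)
}
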