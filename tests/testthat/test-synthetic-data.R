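test_that("single-horizon hazard calibration has the closed-form solutions", {
  one <- calibrate_exponential_hazards(0.5, 0, horizon_years = 1)
  expect_equal(one[["lambda_cvd"]], log(2), tolerance = 1e-10)
  expect_equal(one[["lambda_death"]], 0)

  sym <- calibrate_exponential_hazards(0.2, 0.2, horizon_years = 5)
  expect_equal(sym[["lambda_cvd"]], sym[["lambda_death"]], tolerance = 1e-12)

  expect_error(calibrate_exponential_hazards(0.6, 0.4, 5), "infeasible")

  # round trip: plugging the rates back reproduces both targets
  h <- calibrate_exponential_hazards(0.2, 0.3, horizon_years = 5)
  tot <- sum(h)
  expect_equal((h[["lambda_cvd"]] / tot) * (1 - exp(-tot * 5)), 0.2, tolerance = 1e-10)
  expect_equal((h[["lambda_death"]] / tot) * (1 - exp(-tot * 5)), 0.3, tolerance = 1e-10)
})

test_that("calibrated rates reproduce target CIFs under forward simulation", {
  h <- calibrate_exponential_hazards(0.2, 0.3, horizon_years = 5)
  set.seed(12)
  n <- 1e5
  tc <- rexp(n, h[["lambda_cvd"]]); td <- rexp(n, h[["lambda_death"]])
  expect_lt(abs(mean(tc <= pmin(td, 5)) - 0.2), 0.005)
  expect_lt(abs(mean(td < pmin(tc, 5)) - 0.3), 0.005)
})

test_that("two-horizon marginal calibration hits the CVD CIF and all-cause mortality", {
  q <- 82 / 460
  h <- calibrate_marginal_hazards(0.29, 6.9, 0.79, 8.7, fatal_share = q)
  lc <- h[["lambda_cvd"]]; ld <- h[["lambda_death"]]; tot <- lc + ld
  expect_equal((lc / tot) * (1 - exp(-tot * 6.9)), 0.29, tolerance = 1e-9)
  mort <- (1 - exp(-ld * 8.7)) + q * exp(-ld * 8.7) * (1 - exp(-lc * 8.7))
  expect_equal(mort, 0.79, tolerance = 1e-9)
  # Monte-Carlo round trip of the all-cause mortality semantics
  set.seed(13)
  n <- 1e5
  tc <- rexp(n, lc); td <- rexp(n, ld)
  fatal <- runif(n) < q
  dead <- (td <= 8.7) | (tc <= 8.7 & tc <= td & fatal)
  expect_lt(abs(mean(dead) - 0.79), 0.006)
})

test_that("generated cohorts score exactly to their intended categories", {
  co <- generate_cohort(synthetic_cohort_config(n = 800, seed = 3))
  st <- stratify_cohort(co$subjects)
  expect_identical(as.character(st$category), as.character(co$intended_category))
  # structural zeros hold in every generated cohort
  below <- st$category %in% c("LOW", "MODERATE")
  s <- co$subjects
  expect_false(any(below & (s$coronary_artery_disease | s$cerebrovascular_disease |
                            s$peripheral_artery_disease | s$valvular_disease)))
  expect_true(all(s$heart_failure[st$category == "VERY_HIGH"]))
  expect_false(any(s$heart_failure[st$category != "VERY_HIGH"]))
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- synthetic_cohort_config(n = 150, seed = 21)
  a <- generate_cohort(cfg); b <- generate_cohort(cfg)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$events, b$events)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(list(subjects = a$subjects, events = a$events), f1)
  write_cohort(list(subjects = b$subjects, events = b$events), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("observed category mix tracks the configured mix", {
  cfg <- synthetic_cohort_config(n = 10000, seed = 31)
  co <- generate_cohort(cfg)
  st <- stratify_cohort(co$subjects)
  props <- as.numeric(attr(st, "proportions"))
  expect_true(all(abs(props - cfg$category_mix) < 0.015))
})

test_that("inconsistent prevalence tables are rejected at config time", {
  prev <- default_prevalence()
  prev$binary["coronary_artery_disease", "LOW"] <- 0.1
  expect_error(synthetic_cohort_config(prevalence = prev), "inconsistent")
  prev2 <- default_prevalence()
  prev2$binary["heart_failure", "HIGH"] <- 0.05
  expect_error(synthetic_cohort_config(prevalence = prev2), "heart failure")
})

test_that("crude event proportions match the closed-form expectation", {
  cfg <- synthetic_cohort_config(n = 50000, seed = 41,
                                 category_mix = c(1, 0, 0, 0),
                                 secondary_hf_rate = 0)
  sc <- generate_validation_scenario(cfg)
  out <- build_outcomes(sc$cohort$events, sc$cohort$subjects$subject_id,
                        sc$cohort$subjects$followup_years)
  expect_lt(abs(mean(out$status == 1L) - sc$expected$p_event[1]), 0.005)
  p2 <- sc$expected$p_competing[1]
  expect_lt(abs(mean(out$status == 2L) - p2), 4 * sqrt(p2 * (1 - p2) / 50000))
})

test_that("zero hazards give zero events; doubling the CVD hazard raises incidence", {
  cfg0 <- synthetic_cohort_config(n = 400, seed = 51,
                                  hazards = matrix(0, 4, 2),
                                  secondary_hf_rate = 0)
  co0 <- generate_cohort(cfg0)
  expect_equal(nrow(co0$events), 0L)

  hz1 <- matrix(c(rep(0.05, 4), rep(0, 4)), 4, 2)
  hz2 <- hz1; hz2[, 1] <- 0.10
  p_ev <- sapply(list(hz1, hz2), function(hz) {
    co <- generate_cohort(synthetic_cohort_config(n = 3000, seed = 61, hazards = hz,
                                                  secondary_hf_rate = 0))
    out <- build_outcomes(co$events, co$subjects$subject_id,
                          co$subjects$followup_years)
    mean(out$status == 1L)
  })
  expect_gt(p_ev[2], p_ev[1])
})

test_that("first-event cause mix follows the configured split", {
  co <- generate_cohort(synthetic_cohort_config(n = 8000, seed = 71))
  out <- build_outcomes(co$events, co$subjects$subject_id,
                        co$subjects$followup_years)
  types <- out$first_event_type[out$status == 1L]
  split <- table(factor(types, levels = c("HF_HOSP", "MI", "STROKE", "CVD_DEATH")))
  props <- as.numeric(split) / length(types)
  target <- c(87, 161, 130, 82) / 460
  se <- sqrt(target * (1 - target) / length(types))
  expect_true(all(abs(props - target) < 4 * se + 0.01))
})
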