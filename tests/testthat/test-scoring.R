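test_that("derived predictors follow the documented definitions and boundaries", {
  s <- make_subjects(
    make_subject("P1", systolic_bp = 150),                       # BP above 140 alone
    make_subject("P2", total_cholesterol = 5.6, hdl_cholesterol = 1.3),
    make_subject("P3", egfr = 55),                               # low eGFR, no diagnosis
    make_subject("P4", bmi = 30.0),                              # boundary: strict >
    make_subject("P5", systolic_bp = 140, diastolic_bp = 90),    # boundary BP
    make_subject("P6", antihypertensive_use = TRUE),
    make_subject("P7", diastolic_bp = 95)                        # diastolic-only
  )
  d <- derive_predictors(s)
  expect_true(d$hypertension[1])
  expect_equal(d$non_hdl[2], 4.3)
  expect_true(d$hyperlipidemia[2])
  expect_true(d$ckd[3])
  expect_false(d$obesity[4])
  expect_false(d$hypertension[5])   # 140/90 exactly does not exceed
  expect_true(d$hypertension[6])    # drug use alone qualifies
  expect_true(d$hypertension[7])
  # systolic-only reading drops the diastolic route
  d2 <- derive_predictors(s, scoring_config(bp_rule = "systolic_only"))
  expect_false(d2$hypertension[7])
})

test_that("medium points sum the proforma weights", {
  s <- make_subjects(
    make_subject("Q1", age = 70, antihypertensive_use = TRUE, diabetes = TRUE),
    make_subject("Q2"),
    make_subject("Q3", antihypertensive_use = TRUE, diabetes = TRUE, egfr = 50,
                 current_smoker = TRUE, bmi = 31),
    make_subject("Q4", age = 85),   # age >= 80 is a high factor, 0 medium points
    make_subject("Q5", age = 66, arrhythmia = TRUE)
  )
  pts <- score_medium_points(derive_predictors(s), s)
  expect_identical(pts, c(4L, 0L, 5L, 0L, 4L))
})

test_that("high and very-high flags fire per the proforma", {
  s <- make_subjects(
    make_subject("R1", coronary_artery_disease = TRUE),
    make_subject("R2", heart_failure = TRUE),
    make_subject("R3", age = 81),
    make_subject("R4", peripheral_artery_disease = TRUE),
    make_subject("R5", valvular_disease = TRUE),
    make_subject("R6", prior_anthracycline = TRUE)
  )
  fl <- collect_risk_flags(s)
  expect_true("coronary_artery_disease" %in% fl$high[[1]])
  expect_identical(fl$very_high[[2]], "heart_failure")
  expect_identical(fl$high[[3]], "age80plus")
  expect_true("arterial_vascular_disease" %in% fl$high[[4]])
  expect_true("valvular_disease" %in% fl$high[[5]])
  expect_true("prior_anthracycline" %in% fl$high[[6]])
  # valvular toggle
  fl2 <- collect_risk_flags(s, scoring_config(valvular_high = FALSE))
  expect_length(fl2$high[[5]], 0L)
})

test_that("categorization precedence matches the rule footnote", {
  expect_equal(as.character(categorize(1L, list(character(0)), list(character(0)))), "LOW")
  expect_equal(as.character(categorize(4L, list(character(0)), list(character(0)))), "MODERATE")
  expect_equal(as.character(categorize(5L, list(character(0)), list(character(0)))), "HIGH")
  expect_equal(as.character(categorize(2L, list("PAD"), list(character(0)))), "HIGH")
  expect_equal(as.character(categorize(0L, list("PAD"), list("HF"))), "VERY_HIGH")
})

test_that("stratify_cohort forces 100% very-high when all have heart failure", {
  s <- do.call(rbind, lapply(1:5, function(i) {
    make_subject(paste0("H", i), heart_failure = TRUE, age = 40 + i)
  }))
  st <- stratify_cohort(s)
  expect_true(all(st$category == "VERY_HIGH"))
  expect_equal(as.integer(attr(st, "counts")["VERY_HIGH"]), 5L)
})

test_that("crafted subjects land in LOW, MODERATE, HIGH; empty cohort is empty", {
  s <- make_subjects(
    make_subject("T1"),
    make_subject("T2", antihypertensive_use = TRUE, diabetes = TRUE,
                 current_smoker = TRUE),
    make_subject("T3", coronary_artery_disease = TRUE)
  )
  st <- stratify_cohort(s)
  expect_equal(as.character(st$category), c("LOW", "MODERATE", "HIGH"))
  expect_equal(nrow(stratify_cohort(s[0, ])), 0L)
})

test_that("strict mode names the subject and field; complete-case drops", {
  s <- make_subjects(make_subject("U1"), make_subject("U2", bmi = NA_real_))
  expect_error(stratify_cohort(s), "bmi.*U2")
  expect_warning(st <- stratify_cohort(s, on_missing = "drop"), "dropping 1")
  expect_equal(st$subject_id, "U1")
})

test_that("scoring is total, monotone, and reproduces the structural zeros", {
  set.seed(2024)
  profiles <- do.call(rbind, lapply(1:300, function(i) random_profile(paste0("F", i))))
  st <- stratify_cohort(profiles)
  # exhaustiveness: every complete profile maps to exactly one category
  expect_false(anyNA(st$category))

  # structural zeros: forcing factors never appear below HIGH
  below <- st$category %in% c("LOW", "MODERATE")
  expect_false(any(below & (profiles$coronary_artery_disease |
                            profiles$cerebrovascular_disease |
                            profiles$peripheral_artery_disease |
                            profiles$valvular_disease)))
  expect_false(any(st$category == "LOW" & profiles$arrhythmia))

  # monotonicity: adding any single medium factor never lowers the category,
  # a high factor forces >= HIGH, heart failure always VERY_HIGH
  ord <- function(x) as.integer(factor(x, levels = risk_levels()))
  medium_mods <- list(diabetes = TRUE, current_smoker = TRUE, arrhythmia = TRUE,
                      prior_chest_rt = TRUE, antihypertensive_use = TRUE,
                      bmi = 35, egfr = 40)
  idx <- sample(nrow(profiles), 60)
  for (i in idx) {
    base_cat <- ord(st$category[i])
    for (nm in names(medium_mods)) {
      mod <- profiles[i, , drop = FALSE]
      mod[[nm]] <- medium_mods[[nm]]
      expect_gte(ord(stratify_cohort(mod)$category), base_cat)
    }
    hi <- profiles[i, , drop = FALSE]; hi$coronary_artery_disease <- TRUE
    expect_gte(ord(stratify_cohort(hi)$category), 3L)
    vh <- profiles[i, , drop = FALSE]; vh$heart_failure <- TRUE
    expect_equal(ord(stratify_cohort(vh)$category), 4L)
  }
})
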