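test_that("Kaplan-Meier matches hand-computed product limits exactly", {
  km <- kaplan_meier(c(1, 2, 3), c(1, 1, 0))
  expect_equal(km$time, c(1, 2))
  expect_equal(km$surv, c(2 / 3, 1 / 3))
  expect_equal(km$n_risk, c(3L, 2L))
  # Greenwood variance, exact rational arithmetic
  expect_equal(km$std_err^2,
               c((2 / 3)^2 * (1 / 6), (1 / 3)^2 * (1 / 6 + 1 / 2)))

  # tie handling: d=2 of n=5 at t=1, then d=1 of n=2 at t=4
  km2 <- kaplan_meier(c(1, 1, 2, 4, 5), c(1, 1, 0, 1, 0))
  expect_equal(km2$surv, c(3 / 5, 3 / 10))
})

test_that("all-censored data gives S identically 1 and H identically 0", {
  km <- kaplan_meier(c(1, 2, 3), c(0, 0, 0))
  expect_equal(nrow(km), 0L)
  expect_equal(eval_step(km, c(0.5, 5)), c(1, 1))
  na <- nelson_aalen(c(1, 2), c(0, 0))
  expect_equal(eval_step(na, 5, value = "cumhaz", init = 0), 0)
})

test_that("Kaplan-Meier converges to the exponential survivor function", {
  set.seed(101)
  lambda <- 0.5
  sup_err <- sapply(c(200, 2000), function(n) {
    t <- rexp(n, lambda)
    cens <- runif(n, 0, 6)
    km <- kaplan_meier(pmin(t, cens), as.integer(t <= cens))
    grid <- seq(0.1, 3, by = 0.1)
    max(abs(eval_step(km, grid) - exp(-lambda * grid)))
  })
  expect_lt(sup_err[1], 0.12)
  expect_lt(sup_err[2], sup_err[1])
})

test_that("Nelson-Aalen matches hand computation and bounds the KM", {
  na <- nelson_aalen(c(1, 2), c(1, 1))
  expect_equal(na$cumhaz, c(0.5, 1.5))
  expect_equal(na$std_err^2, c(1 / 4, 1 / 4 + 1))

  set.seed(7)
  t <- rexp(150, 0.4); cens <- runif(150, 0, 5)
  time <- pmin(t, cens); ev <- as.integer(t <= cens)
  km <- kaplan_meier(time, ev)
  na2 <- nelson_aalen(time, ev)
  # classical inequality exp(-H) >= S_KM at every event time
  expect_true(all(exp(-na2$cumhaz) >= km$surv - 1e-12))
})

test_that("Aalen-Johansen matches hand computation and its invariants", {
  aj <- aalen_johansen_cif(c(1, 2, 3), c(1, 2, 0))
  expect_equal(aj$cif1, c(1 / 3, 1 / 3))
  expect_equal(aj$cif2, c(0, 1 / 3))
  expect_equal(aj$surv + aj$cif1 + aj$cif2, rep(1, 2))

  # no competing cause: F1 reduces to 1 - KM exactly
  set.seed(8)
  t <- rexp(100, 0.3); cens <- runif(100, 0, 8)
  time <- pmin(t, cens); ev <- as.integer(t <= cens)
  aj2 <- aalen_johansen_cif(time, ev)
  km <- kaplan_meier(time, ev)
  expect_equal(aj2$cif1, 1 - km$surv)

  # with competing events, 1 - KM overestimates the CIF pointwise
  st <- ev
  st[sample(which(ev == 1L), 25)] <- 2L
  aj3 <- aalen_johansen_cif(time, st)
  km3 <- kaplan_meier(time, as.integer(st == 1L))
  at <- km3$time
  expect_true(all(1 - eval_step(km3, at) >= eval_step(aj3, at, value = "cif1", init = 0) - 1e-12))
  # monotone and summing to one with overall survival
  expect_true(all(diff(aj3$cif1) >= -1e-12))
  expect_equal(aj3$surv + aj3$cif1 + aj3$cif2, rep(1, nrow(aj3)), tolerance = 1e-12)
  expect_error(aalen_johansen_cif(c(1, 2), c(1, 3)), "status")
})

test_that("Harrell C handles the degenerate rankings exactly", {
  perfect <- harrell_c(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1))
  expect_equal(perfect$c, 1)
  expect_equal(perfect$comparable, 3)
  tied <- harrell_c(c(1, 1), c(1, 2), c(1, 1))
  expect_equal(tied$c, 0.5)
  expect_error(harrell_c(c(1, 2), c(1, 1), c(1, 1)), "comparable")
})

test_that("Harrell C equals the brute-force pair count on random data", {
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(20:60, 1)
    score <- sample(1:4, n, replace = TRUE)
    time <- round(rexp(n, 0.3), 2)   # rounding induces ties
    event <- rbinom(n, 1, 0.6)
    if (sum(event[time < max(time)]) == 0) next
    got <- harrell_c(score, time, event)
    want <- brute_force_c(score, time, event)
    expect_identical(got$comparable, want$comparable)
    expect_identical(got$concordant, want$concordant)
    expect_identical(got$tied_score, want$tied)
    expect_equal(got$c, want$c)
  }
})

test_that("concordance CI is sane and jackknife agrees in order of magnitude", {
  set.seed(5)
  n <- 300
  score <- rnorm(n)
  t0 <- rexp(n, exp(0.8 * score))
  cens <- runif(n, 0, 4)
  time <- pmin(t0, cens); ev <- as.integer(t0 <= cens)
  a <- harrell_c(score, time, ev)
  b <- harrell_c(score, time, ev, ci_method = "jackknife")
  expect_true(a$ci[1] < a$c, a$c < a$ci[2])
  expect_true(all(a$ci >= 0 & a$ci <= 1))
  expect_lt(abs(a$se - b$se) / a$se, 0.5)
})
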