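test_that("Nelson-Aalen outcome covariate evaluates H at each subject's time", {
  out <- data.frame(time = c(1, 2), status = c(1L, 1L))
  expect_equal(nelson_aalen_outcome_covariate(out), c(0.5, 1.5))
  cens <- data.frame(time = c(1, 2, 3), status = c(0L, 0L, 0L))
  expect_equal(nelson_aalen_outcome_covariate(cens), c(0, 0, 0))
  # order equivariance
  out3 <- data.frame(time = c(2, 1), status = c(1L, 1L))
  expect_equal(nelson_aalen_outcome_covariate(out3), c(1.5, 0.5))
})

make_imputation_table <- function(n = 150, miss = 0.2, seed = 1) {
  set.seed(seed)
  x1 <- rnorm(n, 10, 2)
  x2 <- 0.5 * x1 + rnorm(n)
  b <- runif(n) < plogis(x1 - 10)
  f <- factor(sample(c("a", "b", "c"), n, TRUE))
  haz <- abs(rnorm(n))
  df <- data.frame(x1 = x1, x2 = x2, b = b, f = f, haz = haz)
  where <- matrix(FALSE, n, 4)
  for (j in 1:4) where[sample(n, round(miss * n)), j] <- TRUE
  df_miss <- df
  df_miss$x1[where[, 1]] <- NA
  df_miss$x2[where[, 2]] <- NA
  df_miss$b[where[, 3]] <- NA
  df_miss$f[where[, 4]] <- NA
  list(full = df, miss = df_miss)
}

test_that("a complete table is returned unchanged, m times", {
  tab <- make_imputation_table()$full
  res <- mice_impute(tab, impute_spec(m = 3, iterations = 2, seed = 5))
  expect_length(res$imputations, 3)
  for (imp in res$imputations) expect_identical(imp, tab)
})

test_that("observed cells are preserved and PMM draws live in the observed support", {
  tabs <- make_imputation_table()
  res <- mice_impute(tabs$miss, impute_spec(m = 2, iterations = 3, seed = 9))
  for (imp in res$imputations) {
    expect_false(anyNA(imp))
    for (col in names(tabs$miss)) {
      obs <- !is.na(tabs$miss[[col]])
      expect_identical(imp[[col]][obs], tabs$miss[[col]][obs])
      # pmm values are members of the observed value set
      if (is.numeric(tabs$miss[[col]])) {
        expect_true(all(imp[[col]][!obs] %in% tabs$miss[[col]][obs]))
      }
    }
    expect_true(is.logical(imp$b))
    expect_true(all(levels(imp$f) == levels(tabs$miss$f)))
  }
})

test_that("seeded imputation runs are fully deterministic", {
  tab <- make_imputation_table()$miss
  spec <- impute_spec(m = 2, iterations = 2, seed = 42)
  r1 <- mice_impute(tab, spec)
  r2 <- mice_impute(tab, spec)
  expect_identical(r1$imputations, r2$imputations)
  expect_identical(r1$diagnostics, r2$diagnostics)
})

test_that("MCAR imputation is approximately unbiased for the mean", {
  devs <- sapply(1:12, function(s) {
    tabs <- make_imputation_table(n = 200, miss = 0.2, seed = s)
    res <- mice_impute(tabs$miss, impute_spec(m = 1, iterations = 3, seed = s))
    mean(res$imputations[[1]]$x1) - mean(tabs$full$x1)
  })
  se_full <- 2 / sqrt(200)
  expect_lt(mean(abs(devs)), 3 * se_full)
  # binary column: prevalence near the observed prevalence
  tabs <- make_imputation_table(n = 300, miss = 0.25, seed = 77)
  res <- mice_impute(tabs$miss, impute_spec(m = 1, iterations = 4, seed = 77))
  obs_prev <- mean(tabs$miss$b, na.rm = TRUE)
  imp_prev <- mean(res$imputations[[1]]$b[is.na(tabs$miss$b)])
  n_miss <- sum(is.na(tabs$miss$b))
  expect_lt(abs(imp_prev - obs_prev), 4 * sqrt(obs_prev * (1 - obs_prev) / n_miss))
})

test_that("invalid imputation inputs error informatively", {
  df <- data.frame(x = c(1, NA, NA, NA, NA, NA, 2, 3, 4, 5), y = 1:10 + 0.5)
  expect_error(mice_impute(df, impute_spec()), ">= 50%")
  df2 <- data.frame(x = c(7, 7, 7, NA, 7, 7, 7, 7, 7, 7), y = rnorm(10))
  expect_error(mice_impute(df2, impute_spec()), "distinct")
  df3 <- data.frame(x = c(1, NA, 3, 4, 5, 6, 7, 8, 9, 10), y = rnorm(10))
  expect_error(mice_impute(df3, impute_spec(methods = c(x = "cart"))), "unknown")
})

test_that("single-dataset selection is seeded, uniform, and index-logged", {
  tabs <- replicate(5, data.frame(x = rnorm(3)), simplify = FALSE)
  a <- select_single_dataset(tabs, seed = 11)
  b <- select_single_dataset(tabs, seed = 11)
  expect_identical(a, b)
  expect_true(attr(a, "index") %in% 1:5)
  expect_identical(select_single_dataset(tabs[1], seed = 2)[["x"]], tabs[[1]]$x)
  idx <- vapply(1:1000, function(s) attr(select_single_dataset(tabs, s), "index"),
                integer(1))
  expect_gt(chisq.test(table(factor(idx, levels = 1:5)))$p.value, 1e-4)
})

test_that("Rubin pooling combines within- and between-imputation variance", {
  coefs <- list(c(b = 0.5), c(b = 0.7), c(b = 0.6))
  vars <- list(c(b = 0.04), c(b = 0.04), c(b = 0.04))
  p <- pool_estimates(coefs, vars)
  expect_equal(p$estimate, 0.6)
  expect_equal(p$between, 0.01)
  expect_equal(p$se^2, 0.04 + (1 + 1 / 3) * 0.01)
})
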