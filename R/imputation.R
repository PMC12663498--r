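#' Imputation specification
#'
#' Configuration of the chained-equations imputer, mirroring the classical
#' MICE setup: `m` completed datasets, a fixed number of chained sweeps per
#' dataset, a method per incomplete column (predictive mean matching for
#' numeric, logistic for binary, polytomous for multi-level factors) and a
#' donor-pool size for PMM.
#'
#' @param m number of completed datasets (default 5).
#' @param iterations chained sweeps per dataset (default 5).
#' @param methods optional named character vector mapping column names to
#'   `"pmm"`, `"logistic"` or `"polytomous"`; unlisted incomplete columns get
#'   a method from their type.
#' @param pmm_donors donor-pool size k for predictive mean matching
#'   (default 5).
#' @param seed integer seed; the whole run is deterministic given the seed.
#' @return list of class `imputation_spec`.
#' @export
impute_spec <- function(m = 5L, iterations = 5L, methods = NULL,
                        pmm_donors = 5L, seed = 1L) {
  stopifnot(m >= 1L, iterations >= 1L, pmm_donors >= 1L)
  structure(list(m = as.integer(m), iterations = as.integer(iterations),
                 methods = methods, pmm_donors = as.integer(pmm_donors),
                 seed = as.integer(seed)),
            class = "imputation_spec")
}

#' Nelson-Aalen outcome covariate
#'
#' The marginal cumulative hazard of the primary event evaluated at each
#' subject's own observation time, H(T_i). Together with the event indicator
#' this is the recommended way to carry a censored outcome into imputation
#' models.
#'
#' @param outcomes outcome data frame (`time`, `status`).
#' @return numeric vector, one value per subject (same order).
#' @export
nelson_aalen_outcome_covariate <- function(outcomes) {
  if (nrow(outcomes) == 0L) return(numeric(0))
  na <- nelson_aalen(outcomes$time, outcomes$status == 1L)
  eval_step(na, outcomes$time, value = "cumhaz", init = 0)
}

.default_method <- function(x) {
  if (is.numeric(x)) return("pmm")
  if (is.logical(x)) return("logistic")
  lv <- if (is.factor(x)) nlevels(x) else length(unique(x[!is.na(x)]))
  if (lv <= 2L) "logistic" else "polytomous"
}

.draw_pmm <- function(y_obs, pred_obs, pred_mis, k) {
  vapply(pred_mis, function(p) {
    d <- abs(pred_obs - p)
    donors <- order(d)[seq_len(min(k, length(d)))]
    y_obs[donors[sample.int(length(donors), 1L)]]
  }, y_obs[1L])
}

.impute_column <- function(y, obs, design, method, k) {
  df_obs <- data.frame(.y = y[obs], design[obs, , drop = FALSE])
  df_mis <- design[!obs, , drop = FALSE]
  if (method == "pmm") {
    fit <- stats::lm(.y ~ ., data = df_obs)
    pred_obs <- stats::predict(fit, newdata = df_obs)
    pred_mis <- stats::predict(fit, newdata = df_mis)
    .draw_pmm(y[obs], pred_obs, pred_mis, k)
  } else if (method == "logistic") {
    yy <- if (is.logical(y)) y[obs] else factor(y[obs])
    df_obs$.y <- yy
    fit <- suppressWarnings(stats::glm(.y ~ ., data = df_obs, family = stats::binomial()))
    p <- stats::predict(fit, newdata = df_mis, type = "response")
    draw <- stats::runif(length(p)) < p
    if (is.logical(y)) draw else {
      lv <- levels(factor(y[obs]))
      out <- ifelse(draw, lv[2L], lv[1L])
      if (is.factor(y)) factor(out, levels = levels(y)) else out
    }
  } else if (method == "polytomous") {
    df_obs$.y <- factor(y[obs])
    fit <- nnet::multinom(.y ~ ., data = df_obs, trace = FALSE)
    p <- stats::predict(fit, newdata = df_mis, type = "probs")
    if (is.null(dim(p))) p <- rbind(p)  # single missing row
    lv <- colnames(p)
    out <- apply(p, 1L, function(pr) sample(lv, 1L, prob = pr))
    if (is.factor(y)) factor(out, levels = levels(y)) else out
  } else {
    stop_named("unknown imputation method '%s'", method)
  }
}

#' Multiple imputation by chained equations
#'
#' Minimal chained-equations imputer: columns are visited in order of
#' ascending missingness; each incomplete column is regressed on all other
#' columns of the current working data (fit on the originally observed rows)
#' and its missing cells redrawn — PMM draws an observed donor value among
#' the `pmm_donors` closest predicted means, logistic/polytomous draw from
#' predicted class probabilities. Observed cells are never altered. Runs are
#' deterministic given `spec$seed`.
#'
#' @param data data frame with missing cells (numeric, logical and factor
#'   columns). Auxiliary covariates such as [nelson_aalen_outcome_covariate()]
#'   and the event indicator should simply be included as (complete) columns.
#' @param spec an [impute_spec()].
#' @return list of class `mice_result`: `imputations` (list of `m` completed
#'   data frames), `where` (logical matrix of originally missing cells),
#'   `methods`, `diagnostics` (per-chain, per-iteration column means of the
#'   imputed cells, for visual convergence checks), `spec`.
#' @export
mice_impute <- function(data, spec = impute_spec()) {
  stopifnot(is.data.frame(data))
  where <- is.na(data)
  frac <- colMeans(where)
  if (any(frac >= 0.5)) {
    stop_named("column '%s' has >= 50%% missingness", names(frac)[frac >= 0.5][1L])
  }
  incomplete <- names(frac)[frac > 0]
  for (col in incomplete) {
    if (length(unique(data[[col]][!is.na(data[[col]])])) < 2L) {
      stop_named("column '%s' has fewer than 2 distinct observed values", col)
    }
  }
  methods <- vapply(incomplete, function(col) {
    spec$methods[[col]] %||% .default_method(data[[col]])
  }, character(1))
  bad <- setdiff(methods, c("pmm", "logistic", "polytomous"))
  if (length(bad)) stop_named("unknown imputation method '%s'", bad[1L])
  visit <- incomplete[order(frac[incomplete])]

  set.seed(spec$seed)
  imputations <- vector("list", spec$m)
  diagnostics <- list()
  for (chain in seq_len(spec$m)) {
    work <- data
    for (col in visit) {  # init: random draws from the observed values
      miss <- where[, col]
      work[[col]][miss] <- sample(data[[col]][!miss], sum(miss), replace = TRUE)
    }
    chain_means <- matrix(NA_real_, spec$iterations, length(visit),
                          dimnames = list(NULL, visit))
    for (it in seq_len(spec$iterations)) {
      for (col in visit) {
        miss <- where[, col]
        design <- work[setdiff(names(work), col)]
        work[[col]][miss] <- .impute_column(data[[col]], !miss, design,
                                            methods[[col]], spec$pmm_donors)
        # work keeps observed cells from `data` by construction
        work[[col]][!miss] <- data[[col]][!miss]
      }
      chain_means[it, ] <- vapply(visit, function(col) {
        v <- work[[col]][where[, col]]
        if (is.numeric(v) || is.logical(v)) mean(v) else mean(v == levels(factor(v))[1L])
      }, numeric(1))
    }
    imputations[[chain]] <- work
    diagnostics[[chain]] <- chain_means
  }
  structure(list(imputations = imputations, where = where,
                 methods = methods, diagnostics = diagnostics, spec = spec),
            class = "mice_result")
}

#' Select one completed dataset
#'
#' The default analysis operates on a single completed dataset drawn
#' uniformly at random from the `m` imputations (Rubin pooling over all `m`
#' is available via [pool_estimates()]).
#'
#' @param imputed a `mice_result` or plain list of data frames.
#' @param seed integer seed for the uniform draw.
#' @return one data frame; attribute `index` records which was selected.
#' @export
select_single_dataset <- function(imputed, seed = 1L) {
  tables <- if (inherits(imputed, "mice_result")) imputed$imputations else imputed
  if (length(tables) == 0L) stop_named("no imputed datasets")
  set.seed(seed)
  idx <- sample.int(length(tables), 1L)
  out <- tables[[idx]]
  attr(out, "index") <- idx
  out
}

#' Pool estimates across imputations (Rubin's rules)
#'
#' Optional reporting mode: combines per-dataset coefficient estimates and
#' variances into pooled estimates with between/within-imputation variance.
#'
#' @param coefs list of numeric coefficient vectors (one per imputation).
#' @param variances list of squared-standard-error vectors, same shape.
#' @return data frame: `estimate`, `se`, `df`, plus the variance components
#'   `within` and `between`.
#' @export
pool_estimates <- function(coefs, variances) {
  m <- length(coefs)
  stopifnot(m >= 1L, length(variances) == m)
  qbar <- Reduce(`+`, coefs) / m
  ubar <- Reduce(`+`, variances) / m
  b <- if (m > 1L) Reduce(`+`, lapply(coefs, function(q) (q - qbar)^2)) / (m - 1)
       else 0 * qbar
  total <- ubar + (1 + 1 / m) * b
  r <- (1 + 1 / m) * b / ubar
  df <- ifelse(b > 0, (m - 1) * (1 + 1 / r)^2, Inf)
  data.frame(estimate = qbar, se = sqrt(total), df = df,
             within = ubar, between = b)
}
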