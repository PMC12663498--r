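#' Kaplan-Meier product-limit estimator
#'
#' Survival curve with Greenwood variance. For the composite-endpoint display
#' competing deaths are passed as censorings by the caller; this function
#' itself is the plain single-event estimator.
#'
#' @param time nonnegative event/censoring times.
#' @param event 0/1 (or logical) event indicator.
#' @param conf_level confidence level for the pointwise interval (plain
#'   normal interval on S, clipped to \[0,1\]).
#' @return object of class `km_curve`: data frame with `time` (distinct event
#'   times, ascending), `n_risk`, `n_event`, `surv`, `std_err`, `lower`,
#'   `upper`; attribute `n` is the sample size.
#' @export
kaplan_meier <- function(time, event, conf_level = 0.95) {
  stopifnot(length(time) == length(event), all(time >= 0))
  if (length(time) == 0L) stop_named("empty input")
  event <- as.integer(as.logical(event))
  tab <- .risk_table(time, event)
  tab <- tab[tab$n_event > 0L, , drop = FALSE]
  s <- cumprod(1 - tab$n_event / tab$n_risk)
  gw <- cumsum(tab$n_event / (tab$n_risk * (tab$n_risk - tab$n_event)))
  se <- s * sqrt(gw)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- data.frame(time = tab$time, n_risk = tab$n_risk, n_event = tab$n_event,
                    surv = s, std_err = se,
                    lower = pmax(0, s - z * se), upper = pmin(1, s + z * se))
  structure(out, n = length(time), class = c("km_curve", "data.frame"))
}

# counts at every distinct observed time (events and censorings)
.risk_table <- function(time, event) {
  ut <- sort(unique(time))
  g <- match(time, ut)
  cnt <- tabulate(g, length(ut))
  n_risk <- length(time) - cumsum(cnt) + cnt
  n_event <- as.integer(tabulate(g[event == 1L], length(ut)))
  data.frame(time = ut, n_risk = n_risk, n_event = n_event)
}

#' Evaluate a step curve
#'
#' Right-continuous evaluation of a `km_curve` (or any data frame with
#' `time` and a value column) at arbitrary times; `left = TRUE` gives the
#' left limit S(t-).
#'
#' @param curve a `km_curve` or data frame.
#' @param t times at which to evaluate.
#' @param value name of the value column.
#' @param left evaluate the left limit instead.
#' @param init value before the first step (1 for survival curves).
#' @return numeric vector.
#' @export
eval_step <- function(curve, t, value = "surv", left = FALSE, init = 1) {
  idx <- findInterval(t, curve$time, left.open = left)
  c(init, curve[[value]])[idx + 1L]
}

#' Nelson-Aalen cumulative hazard estimator
#'
#' H(t) = sum over event times up to t of d_i / n_i, with variance
#' sum d_i / n_i^2.
#'
#' @inheritParams kaplan_meier
#' @return object of class `na_curve`: data frame `time`, `n_risk`,
#'   `n_event`, `cumhaz`, `std_err`.
#' @export
nelson_aalen <- function(time, event) {
  stopifnot(length(time) == length(event), all(time >= 0))
  if (length(time) == 0L) stop_named("empty input")
  event <- as.integer(as.logical(event))
  tab <- .risk_table(time, event)
  tab <- tab[tab$n_event > 0L, , drop = FALSE]
  out <- data.frame(time = tab$time, n_risk = tab$n_risk, n_event = tab$n_event,
                    cumhaz = cumsum(tab$n_event / tab$n_risk),
                    std_err = sqrt(cumsum(tab$n_event / tab$n_risk^2)))
  structure(out, n = length(time), class = c("na_curve", "data.frame"))
}

#' Aalen-Johansen cumulative incidence functions
#'
#' Nonparametric cumulative incidence under competing risks: at each event
#' time, F_k gains S(t-) * d_k / n, where S is the all-cause Kaplan-Meier
#' survival. By construction S(t) + F_1(t) + F_2(t) = 1 at every step.
#'
#' @param time observation times.
#' @param status 0 = censored, 1 = event of interest, 2 = competing event.
#' @return object of class `cif_set`: data frame `time`, `n_risk`, `n_event1`,
#'   `n_event2`, `surv`, `cif1`, `cif2`.
#' @export
aalen_johansen_cif <- function(time, status) {
  stopifnot(length(time) == length(status))
  if (length(time) == 0L) stop_named("empty input")
  if (!all(status %in% 0:2)) stop_named("unknown status code (expected 0, 1, 2)")
  ut <- sort(unique(time[status > 0]))
  n_risk <- length(time) - findInterval(ut, sort(time), left.open = TRUE)
  g <- match(time, ut)  # NA for times not at an event time
  d1 <- as.integer(tabulate(g[status == 1L & !is.na(g)], length(ut)))
  d2 <- as.integer(tabulate(g[status == 2L & !is.na(g)], length(ut)))
  s_all <- cumprod(1 - (d1 + d2) / n_risk)
  s_prev <- c(1, s_all[-length(s_all)])
  cif1 <- cumsum(s_prev * d1 / n_risk)
  cif2 <- cumsum(s_prev * d2 / n_risk)
  out <- data.frame(time = ut, n_risk = n_risk, n_event1 = d1, n_event2 = d2,
                    surv = s_all, cif1 = cif1, cif2 = cif2)
  structure(out, n = length(time), class = c("cif_set", "data.frame"))
}

#' Harrell's concordance index
#'
#' Probability that a randomly chosen comparable pair is correctly ordered by
#' the risk score. A pair (i, j) is comparable when subject i has the event
#' and t_i < t_j (time-tied pairs are excluded); it is concordant when
#' score_i > score_j, and tied scores count one half. Censored subjects
#' (including competing deaths passed as censorings) contribute only as the
#' later member of pairs.
#'
#' @param score numeric risk score, higher = higher predicted risk.
#' @param time observation times.
#' @param event 0/1 event indicator for the endpoint of interest.
#' @param conf_level confidence level.
#' @param ci_method `"normal"` (default): normal approximation with the
#'   delta-method variance from per-subject pair sums; `"jackknife"`:
#'   leave-one-out over the same sums.
#' @return list of class `concordance_result`: `c`, `comparable`,
#'   `concordant`, `tied_score`, `se`, `ci` (length-2), `n`.
#' @export
harrell_c <- function(score, time, event, conf_level = 0.95,
                      ci_method = c("normal", "jackknife")) {
  ci_method <- match.arg(ci_method)
  n <- length(score)
  stopifnot(length(time) == n, length(event) == n)
  event <- as.integer(as.logical(event))
  conc <- tied <- comp <- 0
  a_i <- b_i <- numeric(n)  # per-subject (concordant + 0.5 tied) and comparable sums
  for (i in which(event == 1L)) {
    j <- which(time > time[i])
    if (length(j) == 0L) next
    cij <- score[i] > score[j]
    tij <- score[i] == score[j]
    conc <- conc + sum(cij)
    tied <- tied + sum(tij)
    comp <- comp + length(j)
    aa <- cij + 0.5 * tij
    a_i[i] <- a_i[i] + sum(aa)
    b_i[i] <- b_i[i] + length(j)
    a_i[j] <- a_i[j] + aa
    b_i[j] <- b_i[j] + 1
  }
  if (comp == 0) stop_named("no comparable pairs")
  cstat <- (conc + 0.5 * tied) / comp
  if (ci_method == "normal") {
    infl <- (a_i - cstat * b_i) / comp
    v <- sum(infl^2)
  } else {
    loo <- (conc + 0.5 * tied - a_i) / pmax(comp - b_i, 1)
    v <- (n - 1) / n * sum((loo - mean(loo))^2)
  }
  se <- sqrt(v)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(1, pmax(0, cstat + c(-z, z) * se))
  structure(list(c = cstat, comparable = comp, concordant = conc,
                 tied_score = tied, se = se, ci = ci, n = n,
                 ci_method = ci_method),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Harrell C = %.4f (%.0f%% CI %.4f-%.4f), %d comparable pairs\n",
              x$c, 95, x$ci[1], x$ci[2], x$comparable))
  invisible(x)
}
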