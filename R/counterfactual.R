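# Counterfactual standardization: set the LTU quintile of every area to the
# reference level Q1, predict each condition's rates with the fitted
# coefficients, and convert the rate change to avoided ED visits.

#' Counterfactual design matrix
#'
#' Copies a fitted design and zeroes the quintile-indicator columns, leaving
#' every other column untouched. The default `"q2q5"` mode treats every area
#' as quintile 1; the literal `"q2q4"` mode resets only quintiles 2-4 and
#' leaves quintile 5 areas unchanged.
#'
#' @param X fitted design matrix with columns `Q2`..`Q5`.
#' @param replace `"q2q5"` (default) or `"q2q4"`.
#' @return modified design matrix.
#' @export
counterfactual_design <- function(X, replace = c("q2q5", "q2q4")) {
  replace <- match.arg(replace)
  qcols <- if (replace == "q2q5") paste0("Q", 2:5) else paste0("Q", 2:4)
  missing <- setdiff(qcols, colnames(X))
  if (length(missing))
    stop_input("counterfactual_design: design lacks column(s): %s",
               paste(missing, collapse = ", "))
  X2 <- X
  X2[, qcols] <- 0
  X2
}

#' Predict counterfactual rates under the Q1 scenario
#'
#' Prediction is the counterfactual design row times the fitted coefficient
#' vector, floored at zero (rates cannot be negative). Areas already in
#' quintile 1 keep their factual prediction.
#'
#' @param fit a `condition_fit` (carries its design).
#' @param replace quintile-replacement mode, see [counterfactual_design()].
#' @param X optional design matrix overriding the one stored in `fit`.
#' @return named numeric vector of per-ZCTA counterfactual rates per 1000.
#' @export
simulate_q1 <- function(fit, replace = c("q2q5", "q2q4"), X = fit$X) {
  replace <- match.arg(replace)
  if (!inherits(fit, "condition_fit"))
    stop_input("simulate_q1: 'fit' must be a condition_fit")
  beta <- fit$coefficients$estimate
  if (!identical(colnames(X), fit$coefficients$term))
    stop_input("simulate_q1: design columns do not match the fit's terms")
  X2 <- counterfactual_design(X, replace)
  pred <- drop(X2 %*% beta)
  pmax(pred, 0)
}

#' Convert per-ZCTA rates to a total visit count
#'
#' `total = round(sum(rate x two-year population / 1000))`, rounded half away
#' from zero, applied once to the grand total.
#'
#' @param rates named numeric vector of rates per 1000 (names = ZCTA ids).
#' @param zctas ZCTA table with `zcta_id`, `pop_year1`, `pop_year2`.
#' @return integer-valued total visit count.
#' @export
rates_to_visits <- function(rates, zctas) {
  pop2 <- stats::setNames(zctas$pop_year1 + zctas$pop_year2, zctas$zcta_id)
  if (is.null(names(rates)))
    stop_input("rates_to_visits: 'rates' must be named by zcta_id")
  missing <- setdiff(names(rates), names(pop2))
  if (length(missing))
    stop_input("rates_to_visits: no population for ZCTA '%s'", missing[1])
  round_half_away(sum(rates * pop2[names(rates)] / 1000))
}

#' Assemble a simulation report from its column inputs
#'
#' Computes the derived columns of the status-quo vs counterfactual
#' comparison: rate change (simulated minus status-quo mean), visit-count
#' change (simulated minus status-quo total), and the significance flag
#' (TRUE iff the two 95% confidence intervals are disjoint).
#'
#' @param condition character vector of condition labels.
#' @param status_mean,status_lo,status_hi status-quo mean rate per 1000 and
#'   its 95% CI.
#' @param status_visits status-quo total visit counts.
#' @param sim_mean,sim_lo,sim_hi simulated (counterfactual) mean rate and CI.
#' @param sim_visits simulated total visit counts.
#' @return object of class `simulation_report` (a data.frame) with the input
#'   columns plus `rate_change`, `visit_change`, `significant`.
#' @export
make_simulation_report <- function(condition, status_mean, status_lo,
                                   status_hi, status_visits,
                                   sim_mean, sim_lo, sim_hi, sim_visits) {
  n <- length(condition)
  args <- list(status_mean, status_lo, status_hi, status_visits,
               sim_mean, sim_lo, sim_hi, sim_visits)
  if (any(vapply(args, length, 1L) != n))
    stop_input("make_simulation_report: all columns must have length %d", n)
  if (any(status_lo > status_hi) || any(sim_lo > sim_hi))
    stop_input("make_simulation_report: malformed confidence interval")
  out <- data.frame(
    condition = condition,
    status_mean = status_mean, status_lo = status_lo, status_hi = status_hi,
    status_visits = status_visits,
    sim_mean = sim_mean, sim_lo = sim_lo, sim_hi = sim_hi,
    sim_visits = sim_visits,
    rate_change = sim_mean - status_mean,
    visit_change = sim_visits - status_visits,
    significant = (sim_hi < status_lo) | (status_hi < sim_lo),
    stringsAsFactors = FALSE
  )
  class(out) <- c("simulation_report", "data.frame")
  out
}

#' Status-quo vs counterfactual simulation summary
#'
#' For each fitted condition: the status-quo mean rate is the unweighted mean
#' of the observed ZCTA rates with a t-based 95% CI (`mean +/- t * SD /
#' sqrt(n)`); the simulated mean rate is the unweighted mean of the
#' counterfactual predictions with a delta-method 95% CI from the fit's
#' robust covariance (`SE = sqrt(a' V a)` with `a` the column means of the
#' counterfactual design). Visit totals apply per-ZCTA populations via
#' [rates_to_visits()]; on the status-quo side this reproduces the raw
#' filtered totals exactly.
#'
#' @param panel the observed `rate_panel`.
#' @param zctas ZCTA table.
#' @param fits named list of `condition_fit` objects (as from
#'   [fit_all_conditions()]).
#' @param replace quintile-replacement mode, see [counterfactual_design()].
#' @return a `simulation_report` data.frame, one row per condition.
#' @export
summarize_simulation <- function(panel, zctas, fits,
                                 replace = c("q2q5", "q2q4")) {
  replace <- match.arg(replace)
  conds <- vapply(fits, function(f) f$condition %||% NA_character_, "")
  if (anyNA(conds))
    stop_input("summarize_simulation: every fit must carry its condition label")
  missing <- setdiff(conds, panel$conditions)
  if (length(missing))
    stop_input("summarize_simulation: condition '%s' absent from the panel",
               missing[1])

  rows <- lapply(fits, function(f) {
    ids <- rownames(f$X)
    obs <- stats::setNames(panel$rates[ids, f$condition], ids)
    n <- length(obs)
    tcrit_sq <- stats::qt(0.975, n - 1)
    s_mean <- mean(obs)
    s_se <- stats::sd(obs) / sqrt(n)
    s_visits <- rates_to_visits(obs, zctas)

    pred <- simulate_q1(f, replace)
    X2 <- counterfactual_design(f$X, replace)
    a <- colMeans(X2)
    d_se <- sqrt(drop(t(a) %*% f$vcov %*% a))
    tcrit_sim <- stats::qt(0.975, f$df_resid)
    m <- mean(pred)
    list(condition = f$condition,
         status_mean = s_mean, status_lo = s_mean - tcrit_sq * s_se,
         status_hi = s_mean + tcrit_sq * s_se, status_visits = s_visits,
         sim_mean = m, sim_lo = m - tcrit_sim * d_se,
         sim_hi = m + tcrit_sim * d_se,
         sim_visits = rates_to_visits(pred, zctas))
  })
  g <- function(nm) unname(sapply(rows, `[[`, nm))
  make_simulation_report(
    condition = g("condition"),
    status_mean = g("status_mean"), status_lo = g("status_lo"),
    status_hi = g("status_hi"), status_visits = g("status_visits"),
    sim_mean = g("sim_mean"), sim_lo = g("sim_lo"), sim_hi = g("sim_hi"),
    sim_visits = g("sim_visits")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.simulation_report <- function(x, ...) {
  df <- as.data.frame(x)
  fmt <- function(m, lo, hi) sprintf("%.1f [%.1f, %.1f]", m, lo, hi)
  out <- data.frame(
    condition = df$condition,
    `status quo` = fmt(df$status_mean, df$status_lo, df$status_hi),
    visits = format(df$status_visits, big.mark = ","),
    simulated = fmt(df$sim_mean, df$sim_lo, df$sim_hi),
    sim_visits = format(df$sim_visits, big.mark = ","),
    d_rate = sprintf("%.1f", df$rate_change),
    d_visits = format(df$visit_change, big.mark = ","),
    sig = ifelse(df$significant, "*", ""),
    check.names = FALSE
  )
  print(out, row.names = FALSE)
  invisible(x)
}
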