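# Per-condition ecological regressions: two-year ED visit rate on LTU
# quintile indicators (Q1 reference) plus area covariates, with a
# heteroskedasticity-robust (HC1) variance estimator.

#' Design specification for a condition's rate regression
#'
#' The base covariate set holds the race composition, education, poverty,
#' unemployment, care-access and obesity covariates; the dental flag (on by
#' default only for the teeth condition) adds the county dentist ratio and
#' the share of adults with no dental visit in the past year.
#'
#' @param condition condition label.
#' @param covariates base covariates, default [base_covariates()].
#' @param dental logical; add the two dental covariates. Defaults to `TRUE`
#'   exactly for [dental_condition()].
#' @param covariate_scale `"percent"` (default) leaves percentage covariates
#'   on 0-100; `"proportion"` divides them by 100 in the design.
#' @param hc robust-variance flavor passed to [fit_ols_robust()].
#' @return object of class `design_spec`.
#' @export
design_spec <- function(condition,
                        covariates = base_covariates(),
                        dental = identical(condition, dental_condition()),
                        covariate_scale = c("percent", "proportion"),
                        hc = c("HC1", "HC0", "HC3")) {
  covariate_scale <- match.arg(covariate_scale)
  hc <- match.arg(hc)
  if (!is.character(condition) || length(condition) != 1L)
    stop_input("design_spec: 'condition' must be a single label")
  covs <- covariates
  if (isTRUE(dental)) covs <- c(covs, dental_covariates())
  structure(list(condition = condition, covariates = covs,
                 dental = isTRUE(dental), covariate_scale = covariate_scale,
                 hc = hc),
            class = "design_spec")
}

#' Build the response vector and design matrix for one condition
#'
#' One row per ZCTA, sorted by `zcta_id` for determinism. Columns are the
#' intercept, the quintile indicators Q2-Q5 (quintile 1 is the reference
#' level), and the specification's covariates.
#'
#' @param panel a `rate_panel` containing the condition.
#' @param zctas ZCTA covariate table.
#' @param assignments data.frame with `zcta_id` and `quintile` (from
#'   [assign_quintiles()] or [latent_assignments()]).
#' @param spec a [design_spec()].
#' @return list with `y` (response rates), `X` (design matrix with row names
#'   = ZCTA ids) and `terms` (column names).
#' @export
build_design <- function(panel, zctas, assignments, spec) {
  if (!inherits(spec, "design_spec"))
    stop_input("build_design: 'spec' must be a design_spec")
  if (!spec$condition %in% panel$conditions)
    stop_input("build_design: condition '%s' not in the rate panel",
               spec$condition)
  ids <- sort(names(panel$pop2))
  q <- assignments$quintile[match(ids, assignments$zcta_id)]
  if (anyNA(q))
    stop_input("build_design: no quintile assignment for ZCTA '%s'",
               ids[which(is.na(q))[1]])
  zrow <- match(ids, zctas$zcta_id)
  if (anyNA(zrow))
    stop_input("build_design: ZCTA '%s' missing from the covariate table",
               ids[which(is.na(zrow))[1]])
  for (nm in spec$covariates) {
    if (!nm %in% names(zctas))
      stop_input("build_design: missing covariate column '%s'", nm)
    bad <- which(!is.finite(zctas[[nm]][zrow]))
    if (length(bad))
      stop_input("build_design: ZCTA '%s' has missing covariate '%s'",
                 ids[bad[1]], nm)
  }

  Q <- sapply(2:5, function(k) as.numeric(q == k))
  colnames(Q) <- paste0("Q", 2:5)
  C <- as.matrix(zctas[zrow, spec$covariates, drop = FALSE])
  if (spec$covariate_scale == "proportion") {
    pctcols <- startsWith(colnames(C), "pct_")
    C[, pctcols] <- C[, pctcols] / 100
  }
  X <- cbind(`(Intercept)` = 1, Q, C)
  rownames(X) <- ids
  y <- panel$rates[ids, spec$condition]
  list(y = as.numeric(y), X = X, terms = colnames(X))
}

#' Ordinary least squares with heteroskedasticity-robust variance
#'
#' Fits OLS and reports HC-sandwich standard errors: for HC1 the covariance
#' is `(n/(n-k)) (X'X)^-1 X' diag(e^2) X (X'X)^-1`. Inference uses the t
#' distribution with `n - k` degrees of freedom; the overall test is a
#' robust Wald F on all non-intercept terms. R-squared and adjusted
#' R-squared come from the usual sums of squares.
#'
#' @param y numeric response.
#' @param X numeric design matrix (including the intercept column).
#' @param terms column names; defaults to `colnames(X)`.
#' @param hc `"HC1"` (default), `"HC0"` or `"HC3"`.
#' @param condition optional condition label carried into the result.
#' @return object of class `condition_fit`: a `coefficients` table (term,
#'   estimate, robust SE, t, p, 95% CI), the robust covariance `vcov`,
#'   `r_squared`, `adj_r_squared`, `f_stat`, `f_p`, `n`, `k`, and the fitted
#'   design (`X`, `y`) for downstream prediction.
#' @export
fit_ols_robust <- function(y, X, terms = colnames(X),
                           hc = c("HC1", "HC0", "HC3"), condition = NULL) {
  hc <- match.arg(hc)
  X <- as.matrix(X)
  n <- nrow(X); k <- ncol(X)
  if (length(y) != n)
    stop_input("fit_ols_robust: length(y) != nrow(X)")
  if (n <= k)
    stop_input("fit_ols_robust: n = %d rows cannot identify %d terms", n, k)
  colnames(X) <- terms
  qrX <- qr(X)
  if (qrX$rank < k) {
    aliased <- terms[qrX$pivot[(qrX$rank + 1L):k]]
    stop_input("fit_ols_robust: rank-deficient design; collinear term(s): %s",
               paste(aliased, collapse = ", "))
  }

  dat <- data.frame(.y = y, X, check.names = FALSE)
  fml <- stats::as.formula(paste(".y ~ 0 +",
                                 paste(sprintf("`%s`", terms), collapse = " + ")))
  fit <- stats::lm(fml, data = dat)
  beta <- stats::setNames(stats::coef(fit), terms)
  # vcovHC consults summary.lm, which complains about interpolating fits;
  # a zero-residual fit legitimately has zero robust variance
  V <- withCallingHandlers(
    sandwich::vcovHC(fit, type = hc),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  dimnames(V) <- list(terms, terms)

  se <- sqrt(diag(V))
  df <- n - k
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df)
  crit <- stats::qt(0.975, df)
  coefs <- data.frame(term = terms, estimate = unname(beta),
                      se = unname(se), t = unname(tval), p = unname(pval),
                      ci_lo = unname(beta - crit * se),
                      ci_hi = unname(beta + crit * se),
                      stringsAsFactors = FALSE)

  res <- stats::residuals(fit)
  has_int <- "(Intercept)" %in% terms
  tss <- if (has_int) sum((y - mean(y))^2) else sum(y^2)
  rss <- sum(res^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  adj <- if (tss > 0) 1 - (1 - r2) * (n - has_int) / df else 1

  test_terms <- setdiff(terms, "(Intercept)")
  if (length(test_terms) && all(is.finite(se[test_terms])) &&
      all(se[test_terms] > 0)) {
    b <- beta[test_terms]
    Vb <- V[test_terms, test_terms, drop = FALSE]
    fstat <- drop(t(b) %*% solve(Vb, b)) / length(test_terms)
    fp <- stats::pf(fstat, length(test_terms), df, lower.tail = FALSE)
  } else {
    fstat <- Inf; fp <- 0
  }

  structure(
    list(condition = condition, coefficients = coefs, vcov = V,
         r_squared = r2, adj_r_squared = adj, f_stat = fstat, f_p = fp,
         n = n, k = k, df_resid = df, hc = hc,
         X = X, y = y, residuals = as.numeric(res),
         fitted = as.numeric(stats::fitted(fit))),
    class = "condition_fit"
  )
}

#' @export
print.condition_fit <- function(x, digits = 3, ...) {
  if (!is.null(x$condition)) cat("Condition:", x$condition, "\n")
  cat(sprintf("OLS with %s robust SEs, n = %d, %d terms\n", x$hc, x$n, x$k))
  tab <- x$coefficients
  tab[-1] <- lapply(tab[-1], function(v) round(v, digits))
  print(tab, row.names = FALSE)
  cat(sprintf("R-squared = %.4f; Adj R-squared = %.4f; robust F p = %.4g\n",
              x$r_squared, x$adj_r_squared, x$f_p))
  invisible(x)
}

#' Fit the rate regression for every condition in a panel
#'
#' Convenience wrapper: builds the design and fits the robust OLS model for
#' each condition, applying the dental covariates to [dental_condition()].
#'
#' @inheritParams build_design
#' @param conditions conditions to fit; defaults to all panel conditions.
#' @param covariate_scale,hc passed to [design_spec()].
#' @return named list of `condition_fit` objects.
#' @export
fit_all_conditions <- function(panel, zctas, assignments,
                               conditions = panel$conditions,
                               covariate_scale = "percent", hc = "HC1") {
  fits <- lapply(conditions, function(cond) {
    spec <- design_spec(cond, covariate_scale = covariate_scale, hc = hc)
    d <- build_design(panel, zctas, assignments, spec)
    fit_ols_robust(d$y, d$X, d$terms, hc = hc, condition = cond)
  })
  stats::setNames(fits, conditions)
}

#' Summarize quintile effects across conditions
#'
#' Extracts the Q2-Q5 coefficients of every fit with confidence intervals
#' and significance stars (* p < 0.10, ** p < 0.05, *** p < 0.01), and
#' counts how many of the quintile coefficients are positive and how many
#' are significant at the 0.05 level.
#'
#' @param fits list of `condition_fit` objects.
#' @return object of class `quintile_summary`: data.frame with one row per
#'   condition x quintile term, plus attributes `n_total`, `n_positive`,
#'   `n_significant_05`.
#' @export
summarize_quintile_effects <- function(fits) {
  if (length(fits) == 0L)
    stop_input("summarize_quintile_effects: no fits supplied")
  rows <- lapply(fits, function(f) {
    co <- f$coefficients
    co <- co[co$term %in% paste0("Q", 2:5), , drop = FALSE]
    data.frame(condition = if (is.null(f$condition)) NA_character_ else f$condition,
               term = co$term, estimate = co$estimate,
               ci_lo = co$ci_lo, ci_hi = co$ci_hi, p = co$p,
               stars = ifelse(co$p < 0.01, "***",
                              ifelse(co$p < 0.05, "**",
                                     ifelse(co$p < 0.10, "*", ""))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_total") <- nrow(out)
  attr(out, "n_positive") <- sum(out$estimate > 0)
  attr(out, "n_significant_05") <- sum(out$p < 0.05)
  class(out) <- c("quintile_summary", "data.frame")
  out
}

#' @export
print.quintile_summary <- function(x, digits = 2, ...) {
  df <- as.data.frame(x)
  df$estimate <- round(df$estimate, digits)
  df$ci_lo <- round(df$ci_lo, digits)
  df$ci_hi <- round(df$ci_hi, digits)
  df$p <- signif(df$p, 2)
  print(df, row.names = FALSE)
  cat(sprintf("\n%d of %d quintile coefficients positive; %d significant at 0.05\n",
              attr(x, "n_positive"), attr(x, "n_total"),
              attr(x, "n_significant_05")))
  invisible(x)
}
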