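# LTU concentration index: an area-level propensity score for containing
# long-term-uninsured residents, built from five deprivation-linked
# covariates, then cut into quintiles Q1 (lowest) .. Q5 (highest).

#' Fit the LTU propensity model
#'
#' The default specification is a fractional-response logistic regression:
#' the outcome is the area share of uninsured adults aged 18-64 (on `[0,1]`),
#' the predictors are the remaining five LTU characteristics (Hispanic share,
#' low education, unemployment, non-family households, poverty). The
#' alternative `"median-binary"` specification dichotomizes the outcome at
#' its sample median and fits an ordinary logistic regression. Estimation is
#' iteratively reweighted least squares with relative tolerance `1e-8` and at
#' most 100 iterations.
#'
#' @param zctas ZCTA covariate table (data.frame), needing
#'   `pct_uninsured_18_64` and the [ltu_predictors()] columns.
#' @param spec `"fractional"` (default) or `"median-binary"`.
#' @param predictors character vector of predictor columns; defaults to
#'   [ltu_predictors()].
#' @return object of class `propensity_model`: coefficients, covariance,
#'   fitted scores, the specification and convergence information.
#' @export
fit_propensity <- function(zctas, spec = c("fractional", "median-binary"),
                           predictors = ltu_predictors()) {
  spec <- match.arg(spec)
  need <- c("zcta_id", "pct_uninsured_18_64", predictors)
  missing <- setdiff(need, names(zctas))
  if (length(missing))
    stop_input("fit_propensity: missing column(s): %s",
               paste(missing, collapse = ", "))
  p <- length(predictors)
  if (nrow(zctas) < p + 2L)
    stop_input("fit_propensity: need at least %d ZCTAs for %d predictors",
               p + 2L, p)
  for (nm in predictors) {
    if (length(unique(zctas[[nm]])) == 1L)
      stop_input("fit_propensity: predictor '%s' is constant across ZCTAs", nm)
  }
  X <- as.matrix(zctas[, predictors, drop = FALSE])
  qrX <- qr(cbind(1, X))
  if (qrX$rank < p + 1L) {
    aliased <- c("(Intercept)", predictors)[qrX$pivot[(qrX$rank + 1L):(p + 1L)]]
    stop_input("fit_propensity: collinear predictor(s): %s",
               paste(aliased, collapse = ", "))
  }

  u <- zctas$pct_uninsured_18_64
  y <- if (max(u) > 1) u / 100 else u
  fam <- if (spec == "fractional") {
    stats::quasibinomial(link = "logit")
  } else {
    y <- as.numeric(y > stats::median(y))
    stats::binomial(link = "logit")
  }
  dat <- data.frame(.y = y, zctas[, predictors, drop = FALSE])
  fit <- stats::glm(stats::reformulate(predictors, response = ".y"),
                    family = fam, data = dat,
                    control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  if (!fit$converged)
    stop_input("fit_propensity: IRLS did not converge within %d iterations (deviance %.6g)",
               fit$iter, fit$deviance)

  structure(
    list(coefficients = stats::coef(fit),
         vcov = stats::vcov(fit),
         predictors = predictors, spec = spec,
         iterations = fit$iter, converged = fit$converged,
         fitted = stats::setNames(stats::fitted(fit), zctas$zcta_id)),
    class = "propensity_model"
  )
}

#' @export
print.propensity_model <- function(x, ...) {
  cat(sprintf("LTU propensity model (%s logistic), %d IRLS iterations\n",
              x$spec, x$iterations))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Score ZCTAs with a fitted propensity model
#'
#' Computes `plogis(intercept + X beta)` for every area: a score in `(0, 1)`,
#' higher meaning more likely to contain long-term-uninsured residents.
#'
#' @param model a `propensity_model`.
#' @param zctas ZCTA covariate table with the model's predictor columns.
#' @return data.frame with `zcta_id` and `score`.
#' @export
score_propensity <- function(model, zctas) {
  if (!inherits(model, "propensity_model"))
    stop_input("score_propensity: 'model' must be a propensity_model")
  for (nm in model$predictors) {
    if (!nm %in% names(zctas))
      stop_input("score_propensity: missing predictor column '%s'", nm)
    bad <- which(!is.finite(zctas[[nm]]))
    if (length(bad))
      stop_input("score_propensity: ZCTA '%s' has missing predictor '%s'",
                 zctas$zcta_id[bad[1]], nm)
  }
  X <- as.matrix(zctas[, model$predictors, drop = FALSE])
  eta <- drop(cbind(1, X) %*% model$coefficients)
  data.frame(zcta_id = zctas$zcta_id, score = invlogit(eta),
             stringsAsFactors = FALSE)
}

#' Classify scored ZCTAs into LTU quintiles
#'
#' Rank-based partition: areas are sorted by ascending score (ties broken by
#' `zcta_id`, so permuting the input never changes an assignment) and split
#' into five groups as equal as possible, any remainder going to the lowest
#' quintiles first (392 areas give sizes 79/79/78/78/78). Quintile 5 holds
#' the highest scores. A warning is emitted when tied scores straddle a
#' quintile boundary, since the split is then driven by the identifier
#' tie-break alone.
#'
#' @param scores data.frame with `zcta_id` and `score`.
#' @return data.frame with `zcta_id`, `score`, `quintile` (1-5), in the
#'   original input order.
#' @export
assign_quintiles <- function(scores) {
  if (!all(c("zcta_id", "score") %in% names(scores)))
    stop_input("assign_quintiles: 'scores' needs columns zcta_id and score")
  n <- nrow(scores)
  if (n < 5L)
    stop_input("assign_quintiles: need at least 5 scored ZCTAs (got %d)", n)
  ord <- order(scores$score, scores$zcta_id)
  sizes <- quintile_sizes(n)
  q_sorted <- rep.int(1:5, sizes)
  boundary <- cumsum(sizes)[1:4]
  s <- scores$score[ord]
  if (any(s[boundary] == s[boundary + 1L]))
    warning("assign_quintiles: tied scores straddle a quintile boundary; ",
            "assignment there is determined by the zcta_id tie-break",
            call. = FALSE)
  quintile <- integer(n)
  quintile[ord] <- q_sorted
  out <- data.frame(zcta_id = scores$zcta_id, score = scores$score,
                    quintile = quintile, stringsAsFactors = FALSE)
  out
}
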