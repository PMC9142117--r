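#' Configuration for the synthetic-data generator
#'
#' Bundles everything the generator needs: the number of areas, the seed, the
#' per-quintile covariate calibration, the per-condition effect specification,
#' the annual population range, and the share of generated encounter records
#' that must fail the inclusion filters (the "noise" records emulating
#' insured, out-of-age-range or invalid-area encounters).
#'
#' @param n_zcta number of ZCTAs to generate (>= 5; default 392, the study
#'   population size).
#' @param seed integer seed; all pseudo-random streams derive from it.
#' @param covariate_calibration named list of per-quintile `mean`/`sd`
#'   vectors, as [default_covariate_calibration()].
#' @param effect_spec data.frame with columns `condition`, `intercept`,
#'   `q2`..`q5`, `resid_sd`, as [default_effect_spec()].
#' @param covariate_slopes optional numeric matrix of true covariate effects
#'   (rows = conditions in `effect_spec` order, columns named after
#'   covariates); default `NULL` means all covariate slopes are zero.
#' @param population_range length-2 numeric, min/max annual population aged
#'   18-64 per ZCTA. The default (500-14000) makes total visit counts for the
#'   top conditions land at the scale of the study's two-year totals.
#' @param noise_fraction share of all generated encounters that fail the
#'   inclusion filters, in `[0, 1)`. The default 0.739 reproduces the study's
#'   exclusion flow (1,062,418 of 4,076,200 encounters retained).
#' @param noise_model `"lognormal"` (default) for mean-one multiplicative
#'   residual noise on the rate scale, or `"normal"` for additive noise
#'   truncated at zero. The lognormal default keeps expected rates equal to
#'   the linear predictor (no truncation bias) and makes residual variance
#'   grow with the mean, the heteroskedasticity the robust variance estimator
#'   is there for.
#' @param count_draw `"poisson"` (default) draws visit counts from a Poisson
#'   law; `"expected"` uses the rounded expectation (deterministic counts,
#'   useful for exactness checks).
#' @param years integer study years (default 2012:2013).
#' @param uninsured_payer_split probability that a qualifying record is
#'   self-pay rather than indigent/charitable.
#' @param covariate_scale `"percent"` (default) stores percentage covariates
#'   on the 0-100 scale; `"proportion"` rescales them to 0-1.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_zcta = 392L,
                             seed = 1L,
                             covariate_calibration = default_covariate_calibration(),
                             effect_spec = default_effect_spec(),
                             covariate_slopes = NULL,
                             population_range = c(500, 14000),
                             noise_fraction = 0.739,
                             noise_model = c("lognormal", "normal"),
                             count_draw = c("poisson", "expected"),
                             years = c(2012L, 2013L),
                             uninsured_payer_split = 0.85,
                             covariate_scale = c("percent", "proportion")) {
  noise_model <- match.arg(noise_model)
  count_draw <- match.arg(count_draw)
  covariate_scale <- match.arg(covariate_scale)

  if (!is_count(n_zcta) || n_zcta < 5L)
    stop_input("generator_config: 'n_zcta' must be an integer >= 5 (got %s)",
               format(n_zcta))
  if (!is_count(seed))
    stop_input("generator_config: 'seed' must be a single integer")
  if (!is.list(covariate_calibration) || is.null(names(covariate_calibration)))
    stop_input("generator_config: 'covariate_calibration' must be a named list")
  for (nm in names(covariate_calibration)) {
    cc <- covariate_calibration[[nm]]
    if (!is.list(cc) || length(cc$mean) != 5L || length(cc$sd) != 5L)
      stop_input("generator_config: 'covariate_calibration$%s' needs mean and sd of length 5", nm)
    if (any(cc$sd < 0))
      stop_input("generator_config: 'covariate_calibration$%s' has a negative sd", nm)
  }
  req <- c("condition", "intercept", "q2", "q3", "q4", "q5", "resid_sd")
  if (!is.data.frame(effect_spec) || !all(req %in% names(effect_spec)))
    stop_input("generator_config: 'effect_spec' must have columns %s",
               paste(req, collapse = ", "))
  if (anyDuplicated(effect_spec$condition))
    stop_input("generator_config: 'effect_spec' has duplicated conditions")
  if (any(effect_spec$resid_sd < 0))
    stop_input("generator_config: 'effect_spec' has a negative resid_sd")
  if (length(population_range) != 2L || population_range[1] < 1 ||
      population_range[2] < population_range[1])
    stop_input("generator_config: 'population_range' must be c(min, max) with min >= 1")
  if (!is.numeric(noise_fraction) || noise_fraction < 0 || noise_fraction >= 1)
    stop_input("generator_config: 'noise_fraction' must lie in [0, 1)")
  if (!is.null(covariate_slopes)) {
    if (!is.matrix(covariate_slopes) || is.null(colnames(covariate_slopes)) ||
        nrow(covariate_slopes) != nrow(effect_spec))
      stop_input("generator_config: 'covariate_slopes' must be a matrix with one row per condition and named columns")
  }
  if (!is.numeric(uninsured_payer_split) || uninsured_payer_split <= 0 ||
      uninsured_payer_split >= 1)
    stop_input("generator_config: 'uninsured_payer_split' must lie in (0, 1)")

  structure(
    list(n_zcta = as.integer(n_zcta), seed = as.integer(seed),
         covariate_calibration = covariate_calibration,
         effect_spec = effect_spec, covariate_slopes = covariate_slopes,
         population_range = as.numeric(population_range),
         noise_fraction = noise_fraction, noise_model = noise_model,
         count_draw = count_draw, years = as.integer(years),
         uninsured_payer_split = uninsured_payer_split,
         covariate_scale = covariate_scale),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic-data generator configuration\n")
  cat(sprintf("  ZCTAs: %d   seed: %d   years: %s\n", x$n_zcta, x$seed,
              paste(x$years, collapse = ", ")))
  cat(sprintf("  conditions: %d   noise fraction: %.3f   noise model: %s\n",
              nrow(x$effect_spec), x$noise_fraction, x$noise_model))
  cat(sprintf("  annual population range: [%g, %g]\n",
              x$population_range[1], x$population_range[2]))
  invisible(x)
}
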