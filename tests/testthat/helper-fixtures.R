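# Shared fixtures, built in code at test time.

# A small, fast generator configuration.
small_config <- function(n_zcta = 40, seed = 11, noise_fraction = 0.25, ...) {
  generator_config(n_zcta = n_zcta, seed = seed,
                   noise_fraction = noise_fraction,
                   population_range = c(500, 3000), ...)
}

# Calibration with strong quintile separation and small spread, for
# recovery tests of the LTU index chain.
separated_calibration <- function() {
  cal <- default_covariate_calibration()
  sep <- list(
    pct_uninsured_18_64 = c(5, 15, 25, 35, 45),
    pct_hispanic = c(2, 6, 10, 14, 18),
    pct_less_hs = c(5, 12, 19, 26, 33),
    pct_unemployed_16plus = c(4, 9, 14, 19, 24),
    pct_nonfamily_households = c(15, 22, 29, 36, 43),
    pct_below_200fpl = c(8, 16, 24, 32, 40)
  )
  for (nm in names(sep)) cal[[nm]] <- list(mean = sep[[nm]], sd = rep(0.8, 5))
  cal
}

# One-condition effect spec with known coefficients.
one_condition_spec <- function(intercept = 6.1, effects = c(1.96, 3.40, 2.40, 2.74),
                               resid_sd = 5.82, condition = "Abdominal pain") {
  data.frame(condition = condition, intercept = intercept,
             q2 = effects[1], q3 = effects[2], q4 = effects[3],
             q5 = effects[4], resid_sd = resid_sd,
             stringsAsFactors = FALSE)
}

# Minimal condition_fit with known coefficients, for counterfactual units.
stub_fit <- function(beta, X, condition = "stub", vcov = NULL) {
  X <- as.matrix(X)
  if (is.null(vcov)) vcov <- diag(0, ncol(X))
  dimnames(vcov) <- list(colnames(X), colnames(X))
  structure(
    list(condition = condition,
         coefficients = data.frame(term = colnames(X), estimate = beta,
                                   se = sqrt(diag(vcov)), t = NA_real_,
                                   p = NA_real_, ci_lo = NA_real_,
                                   ci_hi = NA_real_, stringsAsFactors = FALSE),
         vcov = vcov, r_squared = NA_real_, adj_r_squared = NA_real_,
         f_stat = NA_real_, f_p = NA_real_, n = nrow(X), k = ncol(X),
         df_resid = nrow(X) - ncol(X), hc = "HC1", X = X,
         y = as.numeric(X %*% beta),
         residuals = rep(0, nrow(X)), fitted = as.numeric(X %*% beta)),
    class = "condition_fit"
  )
}

# Run generator -> filter -> rates -> latent-quintile design for one
# condition; returns the fit plus the planted truth.
recover_fit <- function(seed, effect_spec = one_condition_spec(),
                        n_zcta = 392, population_range = c(500, 14000)) {
  cfg <- generator_config(n_zcta = n_zcta, seed = seed,
                          effect_spec = effect_spec, noise_fraction = 0,
                          population_range = population_range)
  g <- generate_zcta_table(cfg)
  v <- generate_visits(g$zcta, g$truth, cfg)
  flt <- filter_encounters(v$visits, g$zcta$zcta_id)
  panel <- compute_rates(flt$records, g$zcta, effect_spec$condition)
  d <- build_design(panel, g$zcta, latent_assignments(v$truth),
                    design_spec(effect_spec$condition, dental = FALSE))
  fit <- fit_ols_robust(d$y, d$X, d$terms, condition = effect_spec$condition)
  list(fit = fit, truth = v$truth, zcta = g$zcta, panel = panel)
}
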