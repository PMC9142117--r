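small_panel <- function(seed = 13, n_zcta = 40) {
  cfg <- small_config(n_zcta = n_zcta, seed = seed, noise_fraction = 0)
  g <- generate_zcta_table(cfg)
  v <- generate_visits(g$zcta, g$truth, cfg)
  flt <- filter_encounters(v$visits, g$zcta$zcta_id)
  panel <- compute_rates(flt$records, g$zcta, top_conditions())
  list(panel = panel, zcta = g$zcta, truth = v$truth,
       assignments = latent_assignments(v$truth))
}

test_that("design uses reference coding with quintile 1 as baseline", {
  s <- small_panel()
  d <- build_design(s$panel, s$zcta, s$assignments, design_spec("Headache"))
  expect_equal(d$terms[1:5], c("(Intercept)", "Q2", "Q3", "Q4", "Q5"))
  expect_equal(rownames(d$X), sort(s$zcta$zcta_id))
  q <- s$assignments$quintile[match(rownames(d$X), s$assignments$zcta_id)]
  expect_true(all(d$X[q == 1, c("Q2", "Q3", "Q4", "Q5")] == 0))
  q4rows <- d$X[q == 4, c("Q2", "Q3", "Q4", "Q5"), drop = FALSE]
  expect_true(all(apply(q4rows, 1, identical, c(Q2 = 0, Q3 = 0, Q4 = 1, Q5 = 0))))
  expect_true(all(rowSums(d$X[, c("Q2", "Q3", "Q4", "Q5")]) == (q > 1)))
})

test_that("the dental specification adds exactly two columns", {
  s <- small_panel()
  d_base <- build_design(s$panel, s$zcta, s$assignments,
                         design_spec("Headache"))
  d_teeth <- build_design(s$panel, s$zcta, s$assignments,
                          design_spec(dental_condition()))
  expect_equal(ncol(d_teeth$X), ncol(d_base$X) + 2L)
  expect_true(all(c("dentist_ratio_per_1000", "pct_no_dental_visit")
                  %in% d_teeth$terms))
  expect_false(any(dental_covariates() %in% d_base$terms))
})

test_that("proportion scaling rescales percentage columns only", {
  s <- small_panel()
  d_pct <- build_design(s$panel, s$zcta, s$assignments,
                        design_spec(dental_condition(), covariate_scale = "percent"))
  d_prop <- build_design(s$panel, s$zcta, s$assignments,
                         design_spec(dental_condition(), covariate_scale = "proportion"))
  expect_equal(d_prop$X[, "pct_white"], d_pct$X[, "pct_white"] / 100)
  expect_equal(d_prop$X[, "dentist_ratio_per_1000"],
               d_pct$X[, "dentist_ratio_per_1000"])
})

test_that("exact linear data is interpolated with zero robust SEs", {
  x <- 1:10
  y <- 2 + 3 * x
  X <- cbind(`(Intercept)` = 1, x = x)
  fit <- fit_ols_robust(y, X)
  expect_equal(fit$coefficients$estimate, c(2, 3), tolerance = 1e-10)
  expect_equal(fit$residuals, rep(0, 10), tolerance = 1e-10)
  expect_equal(fit$coefficients$se, c(0, 0), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)
})

test_that("coefficients and HC1 covariance match the brute-force sandwich", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(20:60, 1)
    k <- sample(2:8, 1)
    d <- random_design(n, k, seed = seed + 100)
    fit <- fit_ols_robust(d$y, d$X, hc = "HC1")
    oracle <- brute_ols_hc(d$y, d$X, type = "HC1")
    expect_lt(rel_err(fit$coefficients$estimate, oracle$beta), 1e-8)
    expect_lt(rel_err(fit$vcov, oracle$vcov), 1e-8)
  }
  # HC0 flavor too
  d <- random_design(45, 5, seed = 9)
  fit0 <- fit_ols_robust(d$y, d$X, hc = "HC0")
  expect_lt(rel_err(fit0$vcov, brute_ols_hc(d$y, d$X, "HC0")$vcov), 1e-8)
})

test_that("HC1 equals the classical covariance under constant-magnitude residuals", {
  # residuals c(1,-1,-1,1) are orthogonal to both columns of the design,
  # so they are the OLS residuals; with |e_i| constant, diag(e^2) = e^2 I and
  # HC1 = (n/(n-k)) e^2 (X'X)^-1 = sigma2_hat (X'X)^-1 exactly, while
  # HC0 = classical x (n-k)/n
  x <- 1:4
  e <- c(1, -1, -1, 1)
  y <- 2 + 3 * x + e
  X <- cbind(`(Intercept)` = 1, x = x)
  fit1 <- fit_ols_robust(y, X, hc = "HC1")
  fit0 <- fit_ols_robust(y, X, hc = "HC0")
  classical <- sum(e^2) / (4 - 2) * solve(t(X) %*% X)
  expect_equal(fit1$vcov, classical, ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(fit0$vcov, classical * (4 - 2) / 4, ignore_attr = TRUE,
               tolerance = 1e-10)
})

test_that("degenerate designs raise estimation errors, never silent fits", {
  d <- random_design(30, 4, seed = 2)
  Xz <- cbind(d$X, zero_cov = 0)
  expect_error(fit_ols_robust(d$y, Xz), "zero_cov")
  Xc <- cbind(d$X, dup = 2 * d$X[, 2])
  expect_error(fit_ols_robust(d$y, Xc), "collinear")
  expect_error(fit_ols_robust(d$y[1:3], d$X[1:3, ]), "identify")
})

test_that("coefficients are invariant to row permutation", {
  d <- random_design(50, 6, seed = 77)
  fit <- fit_ols_robust(d$y, d$X)
  set.seed(1); perm <- sample(50)
  fit2 <- fit_ols_robust(d$y[perm], d$X[perm, ])
  expect_equal(fit2$coefficients$estimate, fit$coefficients$estimate,
               tolerance = 1e-10)
  expect_equal(fit2$vcov, fit$vcov, tolerance = 1e-8)
})

test_that("fit statistics are internally consistent", {
  d <- random_design(60, 5, seed = 4)
  fit <- fit_ols_robust(d$y, d$X)
  expect_lte(fit$adj_r_squared, fit$r_squared)
  expect_gt(fit$n, fit$k)
  co <- fit$coefficients
  crit <- qt(0.975, fit$df_resid)
  expect_equal(co$ci_lo, co$estimate - crit * co$se, tolerance = 1e-12)
  expect_equal(co$ci_hi, co$estimate + crit * co$se, tolerance = 1e-12)
  expect_equal(co$p, 2 * pt(-abs(co$estimate / co$se), fit$df_resid),
               tolerance = 1e-12)
})

test_that("quintile summary stars, counts and the 60-coefficient total", {
  s <- small_panel(seed = 29)
  fits <- fit_all_conditions(s$panel, s$zcta, s$assignments)
  summ <- summarize_quintile_effects(fits)
  expect_equal(nrow(summ), 60L)   # 15 conditions x Q2..Q5
  expect_equal(attr(summ, "n_total"), 60L)
  expect_equal(attr(summ, "n_positive"), sum(summ$estimate > 0))
  expect_equal(attr(summ, "n_significant_05"), sum(summ$p < 0.05))
  expect_true(all(summ$stars[summ$p < 0.01] == "***"))
  expect_true(all(summ$stars[summ$p >= 0.01 & summ$p < 0.05] == "**"))
  expect_true(all(summ$stars[summ$p >= 0.05 & summ$p < 0.10] == "*"))
  expect_true(all(summ$stars[summ$p >= 0.10] == ""))

  # threshold rule on a constructed fit
  mock <- stub_fit(beta = c(1, 0.5, 0.2, 0.1, 0), X = {
    X <- cbind(`(Intercept)` = 1, Q2 = c(0, 1, 0, 0, 0, 0, 1),
               Q3 = c(0, 0, 1, 0, 0, 0, 0), Q4 = c(0, 0, 0, 1, 0, 0, 0),
               Q5 = c(0, 0, 0, 0, 1, 0, 0)); X
  })
  mock$coefficients$p <- c(0.5, 0.04, 0.009, 0.09, 0.5)
  sm <- summarize_quintile_effects(list(mock))
  expect_equal(sm$stars, c("**", "***", "*", ""))
})
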