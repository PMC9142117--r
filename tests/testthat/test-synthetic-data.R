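test_that("config validation names the offending field", {
  expect_error(generator_config(n_zcta = 3), "n_zcta")
  expect_error(generator_config(noise_fraction = 1), "noise_fraction")
  expect_error(generator_config(population_range = c(0, 10)), "population_range")
  cal <- default_covariate_calibration()
  cal$pct_white$sd[2] <- -1
  expect_error(generator_config(covariate_calibration = cal), "pct_white")
  es <- default_effect_spec()
  es$resid_sd[1] <- -0.1
  expect_error(generator_config(effect_spec = es), "resid_sd")
})

test_that("latent quintiles partition areas near-equally", {
  g5 <- generate_zcta_table(small_config(n_zcta = 5))
  expect_equal(unname(table(g5$truth$latent_quintile)), rep(1L, 5),
               ignore_attr = TRUE)
  g392 <- generate_zcta_table(small_config(n_zcta = 392))
  sizes <- as.integer(table(g392$truth$latent_quintile))
  expect_equal(sizes, c(79L, 79L, 78L, 78L, 78L))
  for (n in c(7, 23, 101, 395)) {
    s <- as.integer(table(generate_zcta_table(small_config(n_zcta = n))$truth$latent_quintile))
    expect_lte(max(s) - min(s), 1L)
    expect_equal(sum(s), n)
  }
})

test_that("zero-noise covariates hit the configured quintile means exactly", {
  cal <- default_covariate_calibration()
  for (nm in names(cal)) cal[[nm]]$sd <- rep(0, 5)
  g <- generate_zcta_table(small_config(n_zcta = 25, covariate_calibration = cal))
  q <- g$truth$latent_quintile[g$zcta$zcta_id]
  for (nm in names(cal)) {
    expect_equal(g$zcta[[nm]], cal[[nm]]$mean[q], ignore_attr = TRUE)
  }
})

test_that("percentage covariates are clamped to [0, 100]", {
  cal <- default_covariate_calibration()
  cal$pct_hispanic <- list(mean = rep(1, 5), sd = rep(30, 5))
  cal$pct_white <- list(mean = rep(97, 5), sd = rep(30, 5))
  g <- generate_zcta_table(small_config(n_zcta = 200, covariate_calibration = cal))
  expect_true(all(g$zcta$pct_hispanic >= 0 & g$zcta$pct_hispanic <= 100))
  expect_true(all(g$zcta$pct_white >= 0 & g$zcta$pct_white <= 100))
  expect_true(all(g$zcta$dentist_ratio_per_1000 >= 0))
})

test_that("default calibration reproduces the stratified poverty pattern", {
  # pooled over replicate generations so the Monte-Carlo standard error is
  # small; the reference is the clamped-normal mean implied by the
  # calibration (closed form: E[max(X,0)] = mu*pnorm(mu/sd) + sd*dnorm(mu/sd))
  target_mean <- c(12, 16, 18, 22, 29)
  target_sd <- c(8, 6, 6, 7, 7)
  expected <- target_mean * pnorm(target_mean / target_sd) +
    target_sd * dnorm(target_mean / target_sd)
  pooled <- vector("list", 20)
  for (s in 1:20) {
    g <- generate_zcta_table(generator_config(n_zcta = 392, seed = s))
    q <- g$truth$latent_quintile[g$zcta$zcta_id]
    pooled[[s]] <- data.frame(q = q, x = g$zcta$pct_below_200fpl)
  }
  pooled <- do.call(rbind, pooled)
  for (k in 1:5) {
    x <- pooled$x[pooled$q == k]
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - expected[k]), 4 * se)
  }
  # monotone stratification within a single generation
  g1 <- generate_zcta_table(generator_config(n_zcta = 392, seed = 1))
  q1 <- g1$truth$latent_quintile[g1$zcta$zcta_id]
  expect_true(all(diff(tapply(g1$zcta$pct_below_200fpl, q1, mean)) > 0))
  expect_true(all(diff(tapply(g1$zcta$pct_white, q1, mean)) < 0))
})

test_that("generation is deterministic and noise draws leave covariates alone", {
  cfg <- small_config(seed = 99)
  g1 <- generate_zcta_table(cfg)
  g2 <- generate_zcta_table(cfg)
  expect_identical(g1, g2)
  v1 <- generate_visits(g1$zcta, g1$truth, cfg)
  v2 <- generate_visits(g2$zcta, g2$truth, cfg)
  expect_identical(v1$visits, v2$visits)

  # same seed, different noise fraction: qualifying records unchanged
  cfg0 <- small_config(seed = 99, noise_fraction = 0)
  v0 <- generate_visits(g1$zcta, g1$truth, cfg0)
  K <- v0$truth$qualifying_count
  expect_identical(v0$visits[, -1], v1$visits[seq_len(K), -1])

  # byte-identical files
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_visit_table(v1$visits, f1, seed = 99)
  write_visit_table(v2$visits, f2, seed = 99)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("zero effect specification generates zero qualifying visits", {
  es <- one_condition_spec(intercept = 0, effects = rep(0, 4), resid_sd = 0)
  cfg <- small_config(effect_spec = es, noise_fraction = 0)
  g <- generate_zcta_table(cfg)
  v <- generate_visits(g$zcta, g$truth, cfg)
  expect_equal(nrow(v$visits), 0L)
  expect_equal(v$truth$qualifying_count, 0L)
})

test_that("noise record count follows round(K * nf / (1 - nf))", {
  cfg <- small_config(seed = 5, noise_fraction = 0.5)
  g <- generate_zcta_table(cfg)
  v <- generate_visits(g$zcta, g$truth, cfg)
  K <- v$truth$qualifying_count
  expect_equal(v$truth$noise_count, as.integer(round(K * 0.5 / 0.5)))
  expect_equal(nrow(v$visits), 2L * K)

  cfg2 <- small_config(seed = 5, noise_fraction = 0.2)
  v2 <- generate_visits(g$zcta, g$truth, cfg2)
  expect_equal(v2$truth$noise_count, as.integer(round(v2$truth$qualifying_count * 0.25)))
})

test_that("qualifying records all pass the filter and noise records all fail", {
  cfg <- small_config(seed = 21, noise_fraction = 0.4)
  g <- generate_zcta_table(cfg)
  v <- generate_visits(g$zcta, g$truth, cfg)
  K <- v$truth$qualifying_count
  qual <- v$visits[seq_len(K), ]
  noise <- v$visits[-seq_len(K), ]

  fq <- filter_encounters(qual, g$zcta$zcta_id)
  expect_equal(fq$tally$kept, K)
  expect_equal(fq$tally$kept, fq$tally$input)

  fn <- filter_encounters(noise, g$zcta$zcta_id)
  expect_equal(fn$tally$kept, 0L)
  expect_equal(fn$tally$payer + fn$tally$age + fn$tally$area, nrow(noise))

  # full stream: kept equals the planted qualifying count exactly
  fall <- filter_encounters(v$visits, g$zcta$zcta_id)
  expect_equal(fall$tally$kept, K)
})

test_that("expected counts with zero residual SD reproduce the linear predictor", {
  es <- one_condition_spec(intercept = 5, effects = c(1, 2, 3, 4), resid_sd = 0)
  cfg <- generator_config(n_zcta = 20, seed = 2, effect_spec = es,
                          noise_fraction = 0, count_draw = "expected",
                          population_range = c(500, 500))
  g <- generate_zcta_table(cfg)
  v <- generate_visits(g$zcta, g$truth, cfg)
  flt <- filter_encounters(v$visits, g$zcta$zcta_id)
  panel <- compute_rates(flt$records, g$zcta, es$condition)
  expect_equal(panel$rates[, 1], v$truth$expected_rates[, 1])
})

test_that("regressing generated rates on the design recovers planted effects", {
  r <- recover_fit(seed = 314)
  co <- r$fit$coefficients
  truth <- c(Q2 = 1.96, Q3 = 3.40, Q4 = 2.40, Q5 = 2.74)
  for (nm in names(truth)) {
    row <- co[co$term == nm, ]
    expect_lt(abs(row$estimate - truth[[nm]]), 3 * row$se)
  }
})
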