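# Synthetic-data generator: area covariate tables and episode-level ED
# encounter records with known ground truth. Real encounter data for this
# design is restricted, so every downstream stage is exercised on generated
# inputs whose true quintile structure and regression coefficients are known.

#' Generate a synthetic ZCTA covariate table
#'
#' Draws areas latent-quintile-first: each ZCTA is assigned a latent LTU
#' quintile (five near-equal groups, remainder to the lowest quintiles), then
#' its covariates are drawn independently from the per-quintile normal
#' calibration, and percentage covariates are clamped to `[0, 100]`
#' (the dentist ratio only to nonnegative values). Annual populations aged
#' 18-64 are drawn uniformly within `config$population_range`.
#'
#' @param config a [generator_config()].
#' @return list with components:
#'   \describe{
#'     \item{zcta}{data.frame, one row per ZCTA: `zcta_id`, `pop_year1`,
#'       `pop_year2`, and all covariate columns.}
#'     \item{truth}{object of class `ground_truth` holding the latent
#'       quintile of every ZCTA and the configured effect specification;
#'       [generate_visits()] adds planted visit counts and expected rates.}
#'   }
#' @seealso [generate_visits()], [latent_assignments()]
#' @export
generate_zcta_table <- function(config) {
  if (!inherits(config, "generator_config"))
    stop_input("generate_zcta_table: 'config' must be a generator_config")
  n <- config$n_zcta
  sizes <- quintile_sizes(n)
  latent <- rep.int(1:5, sizes)
  ids <- sprintf("Z%04d", seq_len(n))

  set.seed(substream_seed(config$seed, 1L))
  zcta <- data.frame(
    zcta_id = ids,
    pop_year1 = round(stats::runif(n, config$population_range[1],
                                   config$population_range[2])),
    pop_year2 = round(stats::runif(n, config$population_range[1],
                                   config$population_range[2])),
    stringsAsFactors = FALSE
  )
  for (nm in names(config$covariate_calibration)) {
    cc <- config$covariate_calibration[[nm]]
    x <- stats::rnorm(n, mean = cc$mean[latent], sd = cc$sd[latent])
    if (startsWith(nm, "pct_")) {
      x <- clamp(x, 0, 100)
      if (config$covariate_scale == "proportion") x <- x / 100
    } else {
      x <- pmax(x, 0)
    }
    zcta[[nm]] <- x
  }

  truth <- structure(
    list(latent_quintile = stats::setNames(as.integer(latent), ids),
         quintile_sizes = sizes,
         effect_spec = config$effect_spec,
         covariate_slopes = config$covariate_slopes,
         expected_rates = NULL, planted_counts = NULL,
         qualifying_count = NULL, noise_count = NULL),
    class = "ground_truth"
  )
  list(zcta = zcta, truth = truth)
}

# Linear predictor of expected rates (per 1000, two-year), one column per
# condition, truncated at zero. Rates cannot be negative; configurations that
# push the linear predictor below zero are floored.
expected_rate_matrix <- function(zcta, truth, config) {
  es <- config$effect_spec
  latent <- truth$latent_quintile[zcta$zcta_id]
  qeff <- rbind(0, t(as.matrix(es[, c("q2", "q3", "q4", "q5")])))  # 5 x ncond
  lp <- matrix(es$intercept, nrow = nrow(zcta), ncol = nrow(es), byrow = TRUE) +
    qeff[latent, , drop = FALSE]
  if (!is.null(config$covariate_slopes)) {
    covs <- colnames(config$covariate_slopes)
    missing <- setdiff(covs, names(zcta))
    if (length(missing))
      stop_input("generate_visits: covariate_slopes names unknown covariate(s): %s",
                 paste(missing, collapse = ", "))
    lp <- lp + as.matrix(zcta[, covs, drop = FALSE]) %*% t(config$covariate_slopes)
  }
  dimnames(lp) <- list(zcta$zcta_id, es$condition)
  pmax(lp, 0)
}

#' Generate episode-level ED encounter records
#'
#' For every ZCTA x condition cell, a qualifying visit count is drawn from a
#' Poisson law with mean `rate x two-year population / 1000`, where the rate
#' is the configured linear predictor (quintile effect plus any covariate
#' slopes) perturbed by residual noise and floored at zero. Qualifying
#' records carry an uninsured payer, an age in 18-64 and a valid area. A
#' `noise_fraction` share of the output additionally violates exactly one
#' inclusion criterion (insured payer, age outside 18-64, or invalid area);
#' the noise count is `round(qualifying x nf / (1 - nf))` so that noise
#' records make up `nf` of the total. Separate pseudo-random streams are used
#' for covariates, counts and noise so that adding noise never perturbs the
#' qualifying draws.
#'
#' @param zcta ZCTA table from [generate_zcta_table()].
#' @param truth the matching `ground_truth`.
#' @param config the same [generator_config()].
#' @return list with `visits` (data.frame: `encounter_id`, `zcta_id`, `age`,
#'   `payer`, `condition`, `year`) and `truth` updated with
#'   `expected_rates`, `planted_counts` (ZCTA x condition matrix),
#'   `qualifying_count` and `noise_count`.
#' @export
generate_visits <- function(zcta, truth, config) {
  if (!inherits(config, "generator_config"))
    stop_input("generate_visits: 'config' must be a generator_config")
  if (!inherits(truth, "ground_truth"))
    stop_input("generate_visits: 'truth' must be a ground_truth")
  if (nrow(zcta) == 0L)
    stop_input("generate_visits: empty ZCTA table")

  es <- config$effect_spec
  base_lp <- expected_rate_matrix(zcta, truth, config)
  pop2 <- zcta$pop_year1 + zcta$pop_year2
  n <- nrow(zcta)
  ncond <- nrow(es)

  set.seed(substream_seed(config$seed, 2L))
  # residual noise on the rate scale
  if (config$noise_model == "lognormal") {
    # sigma chosen per condition so the rate SD at the condition's reference
    # mean (intercept + average quintile effect) equals resid_sd
    ref <- es$intercept + rowMeans(cbind(0, es$q2, es$q3, es$q4, es$q5))
    cv2 <- ifelse(ref > 0, (es$resid_sd / ref)^2, 0)
    sdlog <- sqrt(log1p(cv2))
    z <- matrix(stats::rnorm(n * ncond), n, ncond)
    fac <- exp(sweep(z, 2, sdlog, `*`) - matrix(sdlog^2 / 2, n, ncond, byrow = TRUE))
    mu_rate <- pmax(base_lp * fac, 0)
  } else {
    eps <- matrix(stats::rnorm(n * ncond, sd = rep(es$resid_sd, each = n)), n, ncond)
    mu_rate <- pmax(base_lp + eps, 0)
  }
  mu_count <- mu_rate * pop2 / 1000
  counts <- if (config$count_draw == "poisson") {
    matrix(stats::rpois(n * ncond, mu_count), n, ncond)
  } else {
    matrix(round_half_away(mu_count), n, ncond)
  }
  dimnames(counts) <- dimnames(base_lp)

  K <- sum(counts)
  cond_rep <- rep(rep(es$condition, each = n), times = as.vector(counts))
  zcta_rep <- rep(rep(zcta$zcta_id, times = ncond), times = as.vector(counts))
  qual <- data.frame(
    zcta_id = zcta_rep,
    age = if (K) sample(18:64, K, replace = TRUE) else integer(0),
    payer = if (K) {
      sample(uninsured_payers(), K, replace = TRUE,
             prob = c(config$uninsured_payer_split,
                      1 - config$uninsured_payer_split))
    } else character(0),
    condition = cond_rep,
    year = if (K) sample(config$years, K, replace = TRUE) else integer(0),
    stringsAsFactors = FALSE
  )

  set.seed(substream_seed(config$seed, 3L))
  nf <- config$noise_fraction
  n_noise <- as.integer(round_half_away(K * nf / (1 - nf)))
  if (n_noise > 0L) {
    type <- sample(c("payer", "age", "area"), n_noise, replace = TRUE)
    insured <- setdiff(payer_levels(), uninsured_payers())
    bad_age <- c(0:17, 65:95)
    noise <- data.frame(
      zcta_id = sample(zcta$zcta_id, n_noise, replace = TRUE),
      age = sample(18:64, n_noise, replace = TRUE),
      payer = sample(uninsured_payers(), n_noise, replace = TRUE,
                     prob = c(config$uninsured_payer_split,
                              1 - config$uninsured_payer_split)),
      condition = sample(es$condition, n_noise, replace = TRUE),
      year = sample(config$years, n_noise, replace = TRUE),
      stringsAsFactors = FALSE
    )
    noise$payer[type == "payer"] <- sample(insured, sum(type == "payer"),
                                           replace = TRUE)
    noise$age[type == "age"] <- sample(bad_age, sum(type == "age"),
                                       replace = TRUE)
    noise$zcta_id[type == "area"] <- "invalid"
    visits <- rbind(qual, noise)
  } else {
    visits <- qual
  }
  visits <- cbind(encounter_id = sprintf("E%08d", seq_len(nrow(visits))),
                  visits, stringsAsFactors = FALSE)

  truth$expected_rates <- base_lp
  truth$planted_counts <- counts
  truth$qualifying_count <- K
  truth$noise_count <- n_noise
  list(visits = visits, truth = truth)
}

#' Ground-truth quintile assignments
#'
#' Recasts the generator's latent quintiles as a propensity-assignment table,
#' for building regression designs against the planted truth (bypassing the
#' estimated LTU index).
#'
#' @param truth a `ground_truth`.
#' @return data.frame with `zcta_id`, `score` (quintile midpoint on `[0,1]`),
#'   `quintile`.
#' @export
latent_assignments <- function(truth) {
  if (!inherits(truth, "ground_truth"))
    stop_input("latent_assignments: 'truth' must be a ground_truth")
  data.frame(zcta_id = names(truth$latent_quintile),
             score = (truth$latent_quintile - 0.5) / 5,
             quintile = as.integer(truth$latent_quintile),
             stringsAsFactors = FALSE)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Synthetic ground truth\n")
  cat(sprintf("  ZCTAs: %d in quintiles of sizes %s\n",
              length(x$latent_quintile),
              paste(x$quintile_sizes, collapse = "/")))
  cat(sprintf("  conditions: %d\n", nrow(x$effect_spec)))
  if (!is.null(x$qualifying_count))
    cat(sprintf("  planted qualifying visits: %d (+%d noise)\n",
                x$qualifying_count, x$noise_count))
  invisible(x)
}
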