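# Default calibration of the synthetic-data generator.
#
# The study population is South Carolina ZCTAs, 2012-2013: 392 areas split
# into five quintiles of long-term-uninsured (LTU) concentration. Per-quintile
# covariate means/SDs follow published descriptive statistics for that
# population; quintile effects on per-condition ED visit rates (per 1000
# population aged 18-64, over two years) follow the published regression
# estimates, with quintile 1 as the reference level.

#' Condition labels for the top ED minor diagnostic categories
#'
#' The fifteen most frequent minor diagnostic categories among ED visits by
#' uninsured adults (ages 18-64) in the study population, most frequent first.
#'
#' @return character vector of length 15.
#' @export
top_conditions <- function() {
  c("Abdominal pain",
    "Chest pain",
    "Cellulitis and abscess",
    "Diseases of the teeth and supporting structures",
    "Contusions with intact skin surfaces",
    "Other symptoms, signs and ill-defined conditions",
    "Other dorsopathies",
    "Headache",
    "Other sprains and strains of the back",
    "Urinary tract infection, site not specified",
    "Other injuries",
    "Derangements and other unspecified joint disorders",
    "Acute bronchitis and bronchiolitis",
    "Sprains and strains of the neck",
    "Other rheumatism excluding back")
}

#' Condition receiving the two dental covariates
#' @return character scalar.
#' @export
dental_condition <- function() "Diseases of the teeth and supporting structures"

#' Names of the LTU propensity-model predictors
#'
#' The five area characteristics used (besides the uninsured share itself,
#' which is the model outcome) to predict long-term-uninsured concentration:
#' ethnic minority share, low education, unemployment, non-family households,
#' and poverty.
#'
#' @return character vector of covariate names.
#' @export
ltu_predictors <- function() {
  c("pct_hispanic", "pct_less_hs", "pct_unemployed_16plus",
    "pct_nonfamily_households", "pct_below_200fpl")
}

#' Base covariate set of the per-condition rate regressions
#' @return character vector of covariate names.
#' @export
base_covariates <- function() {
  c("pct_white", "pct_black", "pct_less_hs", "pct_below_200fpl",
    "pct_unemployed_16plus", "pct_delayed_care_cost",
    "pct_no_usual_source", "pct_obese")
}

#' Extra covariates for the dental condition
#' @return character vector of covariate names.
#' @export
dental_covariates <- function() {
  c("dentist_ratio_per_1000", "pct_no_dental_visit")
}

#' Default per-quintile covariate calibration
#'
#' Each element gives the mean and standard deviation of one area covariate
#' within each LTU quintile (quintile 1 = lowest concentration). The white
#' population share decreases with LTU concentration; the deprivation-linked
#' covariates increase. The uninsured share, Hispanic share and non-family
#' household share have no published quintile breakdown; their defaults are
#' plausible South Carolina-scale monotone profiles.
#'
#' @return named list; each element has numeric `mean` and `sd`, length 5
#'   (quintile 1 to 5).
#' @export
default_covariate_calibration <- function() {
  list(
    pct_white = list(mean = c(81, 72, 66, 58, 49), sd = c(16, 20, 20, 22, 24)),
    pct_black = list(mean = c(18, 26, 32, 40, 48), sd = c(16, 20, 20, 22, 25)),
    pct_less_hs = list(mean = c(13, 17, 19, 23, 26), sd = c(9, 7, 6, 8, 6)),
    pct_below_200fpl = list(mean = c(12, 16, 18, 22, 29), sd = c(8, 6, 6, 7, 7)),
    pct_unemployed_16plus = list(mean = c(7.7, 10.7, 13.1, 13.8, 18.5),
                                 sd = c(3.7, 4.3, 4.6, 4.5, 7.6)),
    pct_delayed_care_cost = list(mean = c(17, 18, 19, 19, 20), sd = c(3, 2, 3, 4, 4)),
    pct_no_usual_source = list(mean = c(18, 19, 18, 18, 18), sd = c(3, 4, 4, 4, 5)),
    pct_obese = list(mean = c(29, 30, 32, 33, 34), sd = c(5, 5, 5, 6, 7)),
    pct_no_dental_visit = list(mean = c(34, 36, 39, 39, 41), sd = c(7, 5, 6, 7, 7)),
    dentist_ratio_per_1000 = list(mean = c(0.43, 0.43, 0.35, 0.35, 0.35),
                                  sd = c(0.22, 0.21, 0.18, 0.21, 0.19)),
    pct_uninsured_18_64 = list(mean = c(14, 18, 21, 24, 28), sd = c(4, 4, 4, 4, 5)),
    pct_hispanic = list(mean = c(3, 4, 5, 6, 7), sd = c(2, 2, 3, 3, 4)),
    pct_nonfamily_households = list(mean = c(26, 29, 31, 33, 36), sd = c(6, 6, 6, 6, 7))
  )
}

#' Default per-condition effect specification
#'
#' For each condition: the quintile-1 baseline rate (intercept, per 1000
#' population over two years), the quintile 2-5 effects on that rate relative
#' to quintile 1, and the residual standard deviation of the rate around the
#' linear predictor. Baselines are the quintile-1 mean rates of the study
#' population; effects are the published per-condition regression
#' coefficients; residual SDs average the published within-quintile rate SDs.
#' The contusions row has no published quintile-1 mean or SDs; its baseline is
#' backed out from the overall mean rate and its effects, its SD set to a
#' typical value.
#'
#' @return data.frame with columns `condition`, `intercept`, `q2`, `q3`,
#'   `q4`, `q5`, `resid_sd`.
#' @export
default_effect_spec <- function() {
  data.frame(
    condition = top_conditions(),
    intercept = c(6.1, 6.3, 4.8, 4.5, 7.4, 4.2, 3.9, 2.5, 2.7, 3.3,
                  3.1, 2.8, 2.5, 2.4, 1.8),
    q2 = c(1.96, 0.8, 1.1, 0.99, -0.03, 0.5, 1.63, 1.7, 0.9, -0.08,
           0.8, -0.04, 0.2, -0.3, 0.4),
    q3 = c(3.40, 1.4, 3.7, 2.8, 1.2, 1.1, 1.7, 1.0, 1.3, 0.5,
           1.3, 0.6, 1.3, 0.4, 1.0),
    q4 = c(2.40, 1.9, 2.4, 2.7, 0.4, 0.7, 1.9, 1.4, 0.7, 1.1,
           0.5, -0.01, 0.5, 0.0, 0.8),
    q5 = c(2.74, 1.5, 1.7, 1.3, -1.2, 1.4, 2.2, 0.6, 0.2, 0.5,
           1.0, 0.02, 0.4, -0.1, 0.8),
    resid_sd = c(5.82, 5.36, 6.52, 4.50, 4.00, 3.48, 3.46, 3.64, 3.06, 3.46,
                 3.10, 3.02, 3.08, 2.60, 1.84),
    stringsAsFactors = FALSE
  )
}

#' Payer categories of the encounter records
#'
#' @return character vector of the eight primary-payer categories.
#' @export
payer_levels <- function() {
  c("self_pay", "indigent_charitable", "medicare", "medicaid",
    "commercial", "workers_comp", "other_government", "hmo")
}

#' Payer categories treated as uninsured
#'
#' Encounters billed as self-pay or to an indigent/charitable organization
#' are classified as uninsured; all other payers count as insured.
#'
#' @return character vector of length 2.
#' @export
uninsured_payers <- function() {
  c("self_pay", "indigent_charitable")
}
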