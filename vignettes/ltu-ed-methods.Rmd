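---
title: "Methods: area-level LTU concentration and ED use by the uninsured"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: area-level LTU concentration and ED use by the uninsured}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Long-term uninsured (LTU) adults — roughly, people without health insurance
for a year or more — rely on emergency departments (EDs) for conditions that
primary or dental care would handle better and more cheaply. No survey
estimates the LTU share at small geographies, so the concentration of the
LTU in a ZIP Code Tabulation Area (ZCTA) has to be *constructed* from area
characteristics that predict long-term uninsurance. This package implements
that construction and the downstream ecological analysis:

1. **LTU index.** A fractional-response logistic regression predicts each
   ZCTA's uninsured share (ages 18–64, on $[0,1]$) from five
   deprivation-linked covariates: % Hispanic, % with less than high-school
   education, % unemployed (16+), % non-family households, and % living
   below 200% of the federal poverty level. The fitted score
   $\hat p_i = \mathrm{logit}^{-1}(x_i^\top\hat\beta)$ is a propensity-like
   index in $(0,1)$; ZCTAs are ranked and cut into quintiles Q1 (lowest
   LTU concentration) to Q5 (highest).
2. **Outcome construction.** Episode-level ED encounters are filtered to
   the uninsured analytic sample — payer is self-pay or indigent/charitable,
   age 18–64, valid billing ZCTA — the top *k* = 15 minor diagnostic
   categories ("conditions") are selected by frequency, and each condition's
   two-year visit rate per 1000 population is
   $r_{ic} = 1000\, n_{ic} / (P_{i,2012} + P_{i,2013})$.
3. **Association.** Per condition, OLS of $r_{ic}$ on quintile indicators
   Q2–Q5 (Q1 reference) plus area covariates (% white, % black, education,
   poverty, unemployment, delayed care due to cost, no usual source of care,
   obesity; plus dentist ratio and no-dental-visit share for the teeth
   condition), with an HC1 heteroskedasticity-robust covariance
   $\widehat V = \frac{n}{n-k}(X^\top X)^{-1} X^\top \mathrm{diag}(e^2) X (X^\top X)^{-1}$.
4. **Counterfactual standardization.** Every ZCTA's quintile indicators are
   set to zero (all areas treated as Q1), rates are re-predicted with the
   fitted coefficients, floored at zero, and converted to visit counts with
   per-ZCTA populations. The report compares status-quo and simulated mean
   rates (with 95% CIs) and visit totals.

Real encounter data of this kind is restricted, so the package ships a
synthetic-data generator that emulates both input tables with known ground
truth; every stage is tested against that truth.

## The synthetic generator

Generation is latent-quintile-first: each ZCTA draws a latent quintile
(five near-equal groups, remainder to the lowest quintiles), then covariates
conditional on it. This makes the stratified descriptive pattern — poverty,
low education and unemployment rising monotonically from Q1 to Q5, % white
falling — hold by construction, and gives recovery tests an unambiguous
target.

**Covariate calibration.** Per-quintile means/SDs for ten covariates follow
the published descriptive statistics of the 392-ZCTA South Carolina study
population (e.g. % below poverty 12(8), 16(6), 18(6), 22(7), 29(7) across
quintiles). Three covariates used by the index but lacking a published
quintile breakdown (% uninsured 18–64, % Hispanic, % non-family households)
get plausible SC-scale monotone defaults, chosen once: uninsured
14/18/21/24/28 (SD 4–5), Hispanic 3–7 (SD 2–4), non-family households 26–36
(SD 6–7). Draws are independent normals clamped to $[0,100]$ (percentages)
or $[0,\infty)$ (dentist ratio); clamping shifts a mean by at most a few
tenths of a point at these calibrations, and the tests compare against the
clamped-normal expectation in closed form.

**Visit counts.** For ZCTA $i$ and condition $c$ the qualifying count is
Poisson with mean $\mu_{ic} = \max(0, \lambda_{ic})\, P_i / 1000$, where the
rate-scale linear predictor $\lambda_{ic}$ is the condition's intercept (its
Q1 mean rate) plus the planted quintile effect (the published per-condition
regression coefficients, e.g. 1.96/3.40/2.40/2.74 for abdominal pain) plus
optional covariate slopes (zero by default) times a residual noise term.

**Residual noise is multiplicative lognormal by default.** Additive normal
noise at the calibrated SDs (≈ 2–6 rate units) would be truncated at zero
often enough to bias low-quintile means upward and distort effect recovery.
The default instead multiplies the linear predictor by a mean-one lognormal
factor whose $\sigma$ is set per condition so the rate SD at the condition's
reference mean equals the calibrated residual SD. This keeps
$E[r_{ic}\,|\,X] $ exactly equal to the linear predictor (OLS stays
unbiased) and makes residual variance grow with the mean — precisely the
heteroskedasticity the robust variance estimator exists for.
`noise_model = "normal"` restores the literal additive reading, truncated at
zero.

**Populations and filter noise.** Annual 18–64 populations are uniform on
[500, 14000], chosen so the implied two-year totals for the top conditions
land at the published scale (≈ 53,000 abdominal-pain visits across 392
ZCTAs). A `noise_fraction` (default 0.739, the published exclusion share)
of all records violates exactly one inclusion criterion — insured payer, age
outside 18–64, or invalid area — with the noise count defined as
$\mathrm{round}(K\, f/(1-f))$ for $K$ qualifying records. Covariates, counts
and noise use separate pseudo-random streams derived from the single seed,
so switching noise on or off never perturbs the qualifying draws.

**What the generator does not emulate.** Spatial autocorrelation between
neighbouring ZCTAs, correlation between covariates within a quintile, ICD
codes, charges, patient identities, repeat visitors ("frequent flyers"),
and secular trends between the two study years. Passing tests therefore
demonstrate that the estimation machinery is correct and calibrated under
the stated sampling model — not that the published coefficients would be
recovered from the restricted real data.

## Design choices in ambiguous territory

- **Propensity-model outcome.** The source design fits "a logistic
  regression model" at the area level without stating its outcome. The only
  index covariate that can play the outcome role is the uninsured share, so
  the default is a fractional-response logit of that share on the other
  five covariates (quasi-binomial IRLS, tolerance `1e-8`, max 100
  iterations). A `median-binary` option dichotomizes the share at its
  median and fits an ordinary logistic model instead.
- **Quintile rule.** Rank-based equal-size partition, ties broken by
  `zcta_id` (so assignment is permutation-invariant), remainder allocated
  to the lowest quintiles: 392 areas give sizes 79/79/78/78/78. The
  published group sizes (80/78/79/77/78) follow no stated reproducible
  rule, so a deterministic documented one is used. A warning flags ties
  that straddle a boundary.
- **Robust variance flavor.** "Robust variance estimator" is implemented
  as HC1 — the default of the major commercial statistics package this
  kind of analysis is usually run in — with HC0/HC3 available.
- **Covariate scale.** The published coefficient table mixes percentage
  scales (0.29 for % white vs 18.46 for % less-than-high-school implies
  some covariates entered as proportions). The package uses one consistent
  scale, 0–100 by default with a `proportion` switch, and makes no attempt
  to reproduce the published covariate coefficient magnitudes.
- **Quintile replacement in the simulation.** The narrative says quintiles
  Q2–Q4 are reset to Q1 while the results table says *all* areas are set
  to Q1; only the latter is consistent with the published totals, so
  `replace = "q2q5"` is the default and `"q2q4"` gives the literal reading.
- **Simulated CI.** How the published simulated CI was formed is unstated.
  The package uses the delta method on the mean counterfactual prediction:
  $SE = \sqrt{a^\top \widehat V a}$ with $a$ the column means of the
  counterfactual design and $\widehat V$ the robust covariance, with a
  $t_{n-k}$ critical value. Status-quo CIs are plain $t$ intervals on the
  observed ZCTA rates. Significance of a condition's change is flagged iff
  the two 95% CIs are disjoint — a conservative criterion, as in the
  source design.
- **Rounding.** Visit totals round half away from zero, once, on the grand
  total. Rate-to-count back-conversion is float-exact only to 1 ulp, so
  count recovery uses nearest-integer rounding; with counts this is exact.
- **Exclusion attribution.** Filter exclusions are attributed to the first
  failed criterion in the fixed order payer → age → area (plus an
  `unparseable` bucket), making tallies deterministic and conservation
  (`input = kept + sum of exclusions`) machine-checkable.
- **Negative predictions.** Both generated rates and counterfactual
  predictions are floored at zero; rates are nonnegative quantities.

## Numerical and testing choices

Estimation degeneracies raise errors, never silent fits: constant or
collinear predictors are named; `n <= k` is rejected; a rank-deficient
design lists its aliased terms. OLS and the HC sandwich are verified against
an independent brute-force recomputation (explicit matrix products sharing
no code with the implementation) to `1e-8` relative error on random designs.
Under constant-magnitude residuals HC1 coincides with the classical
covariance exactly (and HC0 with classical × $(n-k)/n$); the test suite
asserts that identity analytically.

Monte-Carlo calibration runs at the study size: 392 ZCTAs, the abdominal-
pain effect vector, 500 replicate worlds. Each true quintile coefficient
must fall in its 95% robust CI in 92–98% of replicates, with estimator bias
below 5% of the effect size. Smaller structural tests use 40–100 ZCTAs and
annual populations of 500–3000 to keep the default suite under a minute for
everything except the coverage block.

## Limitations

The analysis is ecological: quintile coefficients describe areas, not
people, and carry no individual-level causal interpretation. The
counterfactual holds all non-quintile covariates fixed while zeroing the
quintile indicators, which is a strong no-interference assumption. The
index inherits whatever misclassification the propensity model produces —
with the default (realistically overlapping) calibration the estimated
quintiles disagree with the latent ones for many areas, attenuating
downstream effect estimates relative to fits on the planted truth; the
recovery tests therefore use the latent assignments. No spatial modelling,
weighting, or multiple-testing correction is applied, matching the source
design.
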