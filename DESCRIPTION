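Package: uninsuredED
Title: Area-Level Long-Term-Uninsured Concentration and Emergency
    Department Use by the Uninsured
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how the area-level concentration of the
    long-term uninsured relates to emergency department (ED) use by
    uninsured patients. Builds a ZIP-Code-Tabulation-Area (ZCTA) propensity
    index for long-term-uninsured concentration from area covariates via
    fractional-response logistic regression, classifies areas into
    quintiles, computes per-condition two-year ED visit rates per 1000
    population from episode-level encounter records, fits per-condition
    ordinary-least-squares models with heteroskedasticity-robust (HC1)
    variance, and runs a counterfactual standardization that sets every
    area to the lowest-concentration quintile and converts the predicted
    rate reduction into avoided ED visits. Includes a calibrated synthetic
    data generator (encounter records are restricted in the real study) so
    the whole pipeline is testable end to end, with parameter-recovery
    checks against the planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    sandwich,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite,
    optparse
Config/testthat/edition: 3
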