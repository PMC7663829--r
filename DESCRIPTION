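Package: apctrends
Title: Bayesian Age-Period-Cohort Analysis of Aggregated Biomarker Trends
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits a Bayesian age-period-cohort (APC) model to aggregated
    health-survey biomarker means observed on an unequal-interval Lexis grid
    (10-year age groups, 1-year survey periods, 1-year-shift birth cohorts).
    The model places a normal likelihood on cell means, first-order
    random-walk smoothing priors on the age, period and cohort effects, and
    sum-to-zero constraints for identifiability; inference is by blocked
    Gibbs sampling with an exact closed-form Gaussian posterior available at
    fixed variances for validation. Includes grid input/output for
    long-format survey tables, a synthetic-data generator with known ground
    truth, direct age standardization, convergence diagnostics (split-chain
    R-hat, effective sample size), posterior effect-curve summaries with 95
    percent credible intervals, and estimated biomarker values per age,
    period and cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ggplot2,
    patchwork
Suggests:
    testthat (>= 3.0.0),
    withr,
    coda
Config/testthat/edition: 3
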