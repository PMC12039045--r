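Package: rxits
Title: Segmented Poisson Interrupted Time Series Analysis of Monthly
    Prescribing
Version: 1.0.0
Authors@R:
    person("Robin", "Ellison", , "robin.ellison@example.org", role = c("aut", "cre"))
Description: Tools for interrupted time series analysis (ITSA) of monthly
    prescribing counts in a registered primary-care population: a
    patient-level synthetic-data generator with a known segmented
    log-linear rate model, cohort aggregation into prevalent and new
    (incident, 24-month washout) prescribing series with statistical
    disclosure control, a segmented Poisson regression with log-population
    offset, Fourier seasonal adjustment, outlier dummies and Newey-West
    heteroscedasticity-and-autocorrelation-consistent standard errors, and
    effect summaries against a no-interruption counterfactual: monthly
    relative risks, geometric-mean average relative risk with confidence
    interval, and rate differences via the delta method.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    sandwich,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
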