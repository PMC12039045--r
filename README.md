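# rxits

Segmented Poisson interrupted time series analysis (ITSA) of monthly
prescribing counts in a registered primary-care population.

`rxits` is aimed at pharmacoepidemiologists and health-services
researchers who want to quantify how an interruption — here, pandemic
restrictions starting March 2020 and a recovery phase starting March
2021 — changed population prescribing, using each population as its own
control. It covers the full path from patient-level prescription events
to effect estimates:

* a **synthetic-data generator** producing registration records and
  prescription events whose monthly aggregates follow a known segmented
  log-linear rate model, so every downstream stage can be verified
  against ground truth (real primary-care extracts in the same tabular
  schema can be supplied instead);
* **cohort aggregation** into monthly prevalent prescribing (distinct
  patients with at least one issue in the month) and new/incident
  prescribing (no issue in the previous 24 months, rates per 1000
  antidepressant-naive patients), with statistical disclosure control
  (counts of 5 or fewer suppressed, the rest rounded to the nearest 10)
  for published outputs;
* the **segmented Poisson model** with log-population offset and
  Newey-West robust errors;
* **effect summaries** against a no-interruption counterfactual.

## The model

Monthly counts `y_t` of prescribed patients, with registered population
`N_t`, are modelled as

    y_t ~ Poisson(mu_t)
    log mu_t = log N_t + b0 + b1 t
               + b2 1[t >= T1] + b3 max(0, t - T1 + 1)
               + b4 1[t >= T2] + b5 max(0, t - T2 + 1)
               + g1 sin(2 pi t / 12) + g2 cos(2 pi t / 12)
               + sum_m d_m 1[t = m]

where `T1`, `T2` are the two interruption months, the `b2`/`b4` terms
are level shifts, `b3`/`b5` slope changes, `g1`, `g2` one Fourier pair
for seasonality, and `d_m` dummies absorb extreme outlier months (the
March/April 2020 analogues). Coefficients are estimated by IRLS;
standard errors use the Newey-West
heteroscedasticity-and-autocorrelation-consistent sandwich with a lag
of 2 (Bartlett weights).

The **counterfactual** sets the step, slope-change and outlier columns
to zero; effect summaries are the monthly relative risk
`RR_t = mu_t / mu_cf,t`, the geometric-mean average RR over a window
(whose log is the linear functional `mean(c_t)' b` of the
coefficients, giving an exact normal-theory CI under the HAC
covariance), and the per-1000 rate difference at a named month with a
delta-method CI.

## Worked example

```r
library(rxits)

cal <- study_calendar()                  # Jan 2018 - Dec 2022,
                                         # interruptions 2020-03 / 2021-03
truth <- simulation_truth(
  population_start = 50000, population_growth = 55,
  step_restriction = log(0.8), slope_restriction = log(1.005),
  outlier_effects = c("2020-03" = -0.35, "2020-04" = -0.2),
  seed = 42
)
patients  <- simulate_patients(truth, cal)
events    <- simulate_prescriptions(patients, truth, cal)
prevalent <- monthly_prevalent_counts(events, patients, cal)
fit <- fit_poisson_itsa(build_design_matrix(cal, prevalent), lag = 2)
fit
#> <itsa_fit> segmented Poisson, 60 months, 10 coefficients
#>   converged in 4 iterations; logLik -318.428; Newey-West lag 2
#>   Pre-interruption monthly slope      0.4% (0.2% to 0.5%)
#>   Restrictions level shift          -17.3% (-18.9% to -15.7%)
#>   Restrictions slope change          -0.0% (-0.2% to 0.2%)
#>   Recovery level shift               -2.0% (-3.0% to -1.0%)
#>   Recovery slope change               0.6% (0.4% to 0.8%)

average_rr(fit)        # post-restriction geometric-mean RR
#>   window_start window_end n_months    rr ci_low ci_high
#> 1 2020-03      2022-12          34 0.857  0.826   0.888

rate_difference(fit)   # per-1000 deficit at the study end
#>   month   rate_difference ci_low ci_high
#> 1 2022-12           -6.32  -11.2   -1.43
```

The fitted table reads as in a segmented-regression report: prescribing
was rising 0.4%/month before the interruption; the restrictions cut the
level by 17% (the configured initiation step of −20% damped by
repeat-prescription persistence); averaged over March 2020 to December
2022 prescribing ran at 0.86 of its no-interruption counterfactual,
i.e. 6.3 fewer prescribed patients per 1000 in the final month.
`autoplot(fit)` draws the standard ITSA figure (observed points, fitted
line, dashed counterfactual); `tidy(fit)` and `glance(fit)` give
broom-style summaries; `monthly_new_counts()` feeds the same model for
incident prescribing; `fit_subgroup_models()` fits fully separate
models per subgroup; `descriptive_table()` produces a
disclosure-controlled census-month table; `run_pipeline()` drives the
whole chain from one configuration and writes CSVs plus a
reproducibility manifest.

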