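---
title: "Methods: segmented Poisson ITSA of monthly prescribing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmented Poisson ITSA of monthly prescribing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxits)
```

This vignette is the package's account of its statistical methods: the
model and its assumptions, the synthetic data-generating process and
what it does and does not emulate, the numerical and design choices
that were genuinely open, and known limitations.

## Study design

The analysis follows the classic three-period interrupted time series
design for population prescribing: a pre-interruption phase
establishing trend and seasonality, a restrictions phase beginning at a
first interruption point, and a recovery phase beginning at a second.
The default `study_calendar()` spans the 60 months January 2018 to
December 2022 with interruptions in March 2020 (`t = 26`) and March
2021 (`t = 38`) and outlier dummies for March and April 2020, months in
which prescribing behaviour was transiently extreme. Each population
acts as its own control: the counterfactual is the model's own
projection of pre-interruption trend and seasonality.

Two outcomes are counted from event-level records:

* **prevalent prescribing** — distinct registered patients with at
  least one prescription issue in the month (multiple issues in one
  month count once);
* **new (incident) prescribing** — prevalent patients with no issue in
  the 24 calendar months strictly before the index month, over the
  denominator of antidepressant-naive registered patients (no issue in
  that window). "Previous 2 years" is interpreted as 24 whole months
  because the data model is monthly; a days-based washout would need
  issue dates. The naive denominator is the default because incident
  rates are conventionally expressed per 1000 at-risk patients; the
  all-registered alternative is a switch (`naive_denominator = FALSE`).

## The model

With `y_t` the monthly count, `N_t` the (naive or registered)
population, `T1 < T2` the interruptions:

$$\log \mu_t = \log N_t + \beta_0 + \beta_1 t
  + \beta_2\,[t \ge T_1] + \beta_3 \max(0, t - T_1 + 1)
  + \beta_4\,[t \ge T_2] + \beta_5 \max(0, t - T_2 + 1)
  + \gamma_1 \sin\tfrac{2\pi t}{12} + \gamma_2 \cos\tfrac{2\pi t}{12}
  + \textstyle\sum_m \delta_m [t = m]$$

and `y_t ~ Poisson(mu_t)` as the working likelihood. The log-population
offset makes coefficients act on rates. One Fourier pair captures
annual seasonality; the number of pairs is configurable
(`fourier_pairs`) but one is the default for a 5-year monthly series —
higher harmonics are rarely identifiable and invite overfitting. A
squared-time column is available behind `quadratic_trend = TRUE` as a
curvature probe, off by default.

**Slope coding.** The slope-change regressor is
`max(0, t - T + 1)` ("inclusive"): it equals 1 in the interruption
month itself, so the step coefficient is the level shift *at* the
interruption month and the slope change accrues from that month. The
alternative `max(0, t - T)` ("exclusive") delays the slope by one
month and makes the step the full shift at `T` before any slope
accrual. Both are common in segmented regression and the package
exposes the choice (`slope_coding`); estimates differ only in how the
first post-interruption month is attributed between step and slope.

**Outlier dummies.** Each outlier month's dummy absorbs that
observation exactly (its residual is zero). The dummies partially
overlap the restriction step; both are kept, so the step coefficient is
interpreted net of the dummied months.

## Estimation and robust errors

The Poisson likelihood is maximised by iteratively reweighted least
squares (Fisher scoring; identical to Newton-Raphson for the canonical
log link): each iteration solves
`X' diag(mu) X step = X'(y - mu)`. Convergence is declared when the
score max-norm falls below `1e-8 * max(1, sum(y))` or the step
max-norm below `1e-8`. The score tolerance is *relative to the count
scale*: an absolute `1e-8` is below floating-point accumulation error
once monthly counts reach hundreds of thousands, while on toy fixtures
the relative and absolute criteria coincide. Failure modes are
explicit errors: rank-deficient designs, all-zero counts (the log-rate
MLE diverges), and non-convergence within 100 iterations (with the
score trace attached).

Monthly counts of a slowly mixing prescribing process are
autocorrelated and can be over- or under-dispersed relative to
Poisson, so all inference uses the Newey-West
heteroscedasticity-and-autocorrelation-consistent sandwich
`V = B M B`, with bread `B = (X' diag(mu) X)^{-1}` and Bartlett-weighted
meat accumulating score cross-products up to lag 2. Lag 0 reduces to
the HC0 sandwich, which the tests assert exactly. Confidence intervals
use normal quantiles (1.96); no small-sample adjustment is applied (see
Limitations).

## Counterfactual and effect summaries

The no-interruption counterfactual evaluates the fitted coefficients
with the step, slope-change and outlier columns set to zero, keeping
intercept, trend, seasonality and the offset. Because pre-interruption
rows have those columns identically zero, `RR_t = mu_t / mu_cf,t = 1`
exactly before `T1` — asserted on every fit.

* **Monthly RR**: `log RR_t = c_t' beta` where `c_t` keeps only the
  pandemic-type columns of row `t`; `Var = c_t' V c_t`.
* **Average RR**: the geometric mean of the monthly ratios over a
  window. Since each ratio is `exp(c_t' beta)`, the log of the
  geometric mean is `mean(c_t)' beta` — a linear functional of the
  coefficients — so its CI is the exact normal-theory interval under
  the HAC covariance. This is the construction the package uses for
  the "overall post-restriction effect" summary. A single-month window
  reduces to the monthly RR, and the estimate is invariant to
  rescaling the population (offset equivariance); both are tested.
* **Rate difference**: `(mu_t - mu_cf,t)/N_t * 1000` at a named month
  (by default the last), with a delta-method CI from the gradient
  `(mu_t x_t - mu_cf,t x_cf,t)/N_t * 1000`. The delta CIs are checked
  against 2000-draw parametric bootstraps.

The averaging window is an explicit argument. The default runs from
the first interruption to the study end; whether a "post-restriction"
average should instead start at the recovery point is a reporting
choice, not a statistical one, so the package makes it a parameter
rather than a convention. Outlier months are included (their dummies
contribute to the contrast) unless `exclude_outliers = TRUE`.

Subgroup analyses fit fully separate models per subgroup — no
interaction terms — mirroring the practice of stratified reporting;
a failure in one stratum (e.g. an all-zero series after subsetting) is
captured per stratum and does not abort the others.

## The synthetic data-generating process

No patient-level prescribing data can ship with the package, so the
generator produces records whose aggregates have a known truth. The
design goal was the *simplest* process that makes prevalent and
incident prescribing genuinely different outcomes; the choice is a
two-state per-patient chain:

* a patient **not** prescribed in month `t - 1` initiates with
  probability
  `i_t = baseline_rate * monthly_trend^t * exp(seasonal + step/slope/outlier terms)`;
* a patient prescribed in `t - 1` is prescribed again with probability
  `repeat_persistence` (rho).

High persistence means most prescribed patients are repeaters who fail
the washout, so incident prescribing responds to the interruption terms
while prevalent prescribing is a damped, lagged transform of them —
exactly the qualitative structure that makes the two outcomes worth
analysing separately. The exact expected prevalence is the recursion
`pi_t = pi_{t-1} rho + (1 - pi_{t-1}) i_t` from zero at the start of
burn-in, exposed as `truth_expected_rate()` (the stationary fixed point
`i/(i + 1 - rho)` is available as `method = "stationary"`). Note the
chain is not exactly log-linear in its own parameters: at
`rho = 0` the marginal is `(1 - pi_{t-1}) i_t`, a few percent below
`i_t`, because a just-prescribed patient cannot repeat.

Defaults were chosen once to emulate the study conditions at desk
scale: 25,000 registered patients at the window start (a 1/1000-scale
stand-in for a ~24M population), linear net growth of 29/month so the
end/start ratio matches the ~6.9% growth of the real denominator over
59 months, baseline initiation 0.02/month with persistence 0.75
(stationary prevalence ~80 per 1000, matching the observed overall
rate), trend 1.003/month (+0.3%/month, the observed pre-interruption
slope), a mild Fourier pair, subgroup prevalences of 0.6% (learning
disability), 1.0% (autism), 0.7% (care home) with multiplicative rate
modifiers 2.3 and 1.5 reproducing the higher prescribing of the
learning-disability and autism groups, and all interruption effects
zero — effects are switched on per experiment. Burn-in of 30 months
(> the 24-month washout) makes incident status decidable from the
first study month.

What the generator does **not** emulate: prescription durations beyond
one month, dosage, dispensing vs issuing, mortality or
de-registration churn (registration ends only if configured),
sub-month registration timing, and correlated subgroup membership
(flags are independent). Passing tests therefore demonstrate
correctness of the pipeline's logic and calibration of its inference
under a clean segmented process — not robustness to every messiness of
real electronic health records.

`simulate_monthly_counts()` complements the patient-level path for
replicated calibration studies: it draws `y_t ~ Binomial(N_t, p_t)`
directly from the segmented log-linear probability — the exact process
the ITSA model assumes, with a known coefficient vector — making
200-replicate recovery and coverage studies run in seconds.

## Disclosure control

Published outputs suppress counts of 5 or fewer (read literally, so 0
is also suppressed; `redact_le` is configurable) and round surviving
counts to the nearest 10 with ties away from zero (15 becomes 20; the
convention is configurable and documented because rounding rules are
often left unstated). Published rates are computed *from the rounded
counts*, so a reader can reproduce them from the published table. The
operation is pure and idempotent. Disclosure control is never applied
to model input — `build_design_matrix()` refuses redacted or rounded
series — mirroring the separation between analysis inside a secure
environment and its published outputs. Secondary suppression of
next-smallest cells is not implemented; complete age/sex flags are
required instead, which is how the source setting avoided it.

## Calibration design and problem sizes

The package's own calibration studies (in the test suite and the
acceptance script) use:

* parameter recovery and CI coverage: 200 replicates of 60-month
  series at population 100,000 (growth 110/month), with effects
  spanning realistic interruption magnitudes (level shifts −25% and
  +10%; slope changes +1% and −3%/month; outlier effects −26% and
  −14%), via the count-level simulator;
* null calibration: the same at all interruption effects zero,
  checking the average-RR point estimates centre on 1.00 and counting
  CI coverage of 1;
* the generator oracle: one 200,000-patient, zero-growth patient-level
  simulation compared to `truth_expected_rate()` within 3 binomial
  standard errors at every month;
* delta-method CIs vs 2000-draw parametric bootstraps; IRLS vs an
  independent BFGS/Newton maximiser to 1e-8; cohort counting vs
  brute-force scans at 200-500 patients.

## Known limitations

* **Newey-West CIs are anti-conservative on a 60-month segmented
  design.** With ~10 regressors and 60 observations the empirical
  sandwich meat is biased downward (leverage concentrates in the
  step/slope columns and the Bartlett-weighted terms are estimated
  from fitted residuals), and the package's own calibration study
  measures ~0.79-0.85 coverage for nominal 95% intervals on the
  step/slope coefficients and the average RR. This is a property of
  the plain Newey-West method at this series length — an independent
  implementation reproduces it — not of the code; the package reports
  the conventional estimator, with normal quantiles and no
  small-sample adjustment, because that is the standard practice it
  implements. Interval estimates on 5-year monthly windows should be
  read accordingly.
* Under non-zero persistence the prevalence series is a damped, lagged
  transform of the initiation process, so segmented-model coefficients
  fitted to prevalent counts estimate the prevalence-scale impact, not
  the initiation-scale truth; effects configured in the generator act
  on initiation. Calibration studies therefore use the count-level
  simulator, where the model's coefficient vector is the truth.
* The model family is fixed Poisson-with-HAC: no quasi-Poisson or
  negative-binomial dispersion parameter and no autoregressive error
  model; autocorrelation is handled only through the covariance.
* Registration is monthly: a patient registered at any point covering
  the month index counts for the whole month.

## A small worked run

```{r example, fig.width = 6, fig.height = 3.5, eval = FALSE}
cal <- study_calendar()
truth <- simulation_truth(population_start = 20000,
                          step_restriction = log(0.85), seed = 7)
patients <- simulate_patients(truth, cal)
events <- simulate_prescriptions(patients, truth, cal)
series <- monthly_prevalent_counts(events, patients, cal)
fit <- fit_poisson_itsa(build_design_matrix(cal, series))
coefficient_table(fit)
average_rr(fit)
autoplot(fit)
```
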