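# The synthetic generator: determinism, registration/population contracts,
# the initiation/persistence chain, and the closed-form expected-rate
# oracle.

small_cal <- study_calendar()

test_that("constant-growth population hits the configured size every month", {
  truth <- simulation_truth(population_start = 1000, population_growth = 0,
                            seed = 7)
  pats <- simulate_patients(truth, small_cal)
  end <- ifelse(is.na(pats$reg_end), Inf, pats$reg_end)
  for (t in c(0L, 13L, 59L)) {
    expect_equal(sum(pats$reg_start <= t & t < end), 1000)
  }

  truth_g <- simulation_truth(population_start = 1000, population_growth = 7,
                              seed = 7)
  pats_g <- simulate_patients(truth_g, small_cal)
  end_g <- ifelse(is.na(pats_g$reg_end), Inf, pats_g$reg_end)
  counts <- vapply(small_cal$months$t,
                   function(t) sum(pats_g$reg_start <= t & t < end_g),
                   integer(1))
  expect_equal(counts, 1000 + small_cal$months$t * 7)
})

test_that("population endpoints can match a configured final/initial ratio", {
  # 1/1000-scale population with growth chosen so the end/start ratio
  # matches 25504380 / 23864380
  target_ratio <- 25504380 / 23864380
  growth <- 23864 * (target_ratio - 1) / 59
  truth <- simulation_truth(population_start = 23864,
                            population_growth = growth, seed = 3)
  pats <- simulate_patients(truth, small_cal)
  end <- ifelse(is.na(pats$reg_end), Inf, pats$reg_end)
  n0 <- sum(pats$reg_start <= 0 & 0 < end)
  n59 <- sum(pats$reg_start <= 59 & 59 < end)
  expect_equal(n59 / n0, 1.0687, tolerance = 1e-3)
})

test_that("generator is deterministic given the truth and differs across seeds", {
  truth <- simulation_truth(population_start = 500, population_growth = 0,
                            seed = 11)
  p1 <- simulate_patients(truth, small_cal)
  p2 <- simulate_patients(truth, small_cal)
  expect_identical(p1, p2)
  e1 <- simulate_prescriptions(p1, truth, small_cal)
  e2 <- simulate_prescriptions(p2, truth, small_cal)
  expect_identical(e1, e2)

  truth_b <- simulation_truth(population_start = 500, population_growth = 0,
                              seed = 12)
  e3 <- simulate_prescriptions(simulate_patients(truth_b, small_cal),
                               truth_b, small_cal)
  expect_false(identical(e1, e3))
})

test_that("events fall only within registration and after burn-in start", {
  truth <- simulation_truth(population_start = 800, population_growth = 5,
                            seed = 5)
  pats <- simulate_patients(truth, small_cal)
  ev <- simulate_prescriptions(pats, truth, small_cal)
  expect_true(all(ev$month >= -truth$burn_in_months))
  joined <- merge(ev, pats[, c("patient_id", "reg_start", "reg_end")])
  expect_true(all(joined$month >= joined$reg_start))
  expect_true(all(is.na(joined$reg_end) | joined$month < joined$reg_end))
})

test_that("with all effects zero and persistence = initiation the monthly
           proportion is the flat baseline", {
  p <- 0.05
  truth <- simulation_truth(
    baseline_rate = p, monthly_trend = 1,
    seasonal_amplitude_sin = 0, seasonal_amplitude_cos = 0,
    repeat_persistence = p, population_start = 20000,
    population_growth = 0, subgroup_rate_modifiers = list(), seed = 21
  )
  pats <- simulate_patients(truth, small_cal)
  ev <- simulate_prescriptions(pats, truth, small_cal)
  prev <- monthly_prevalent_counts(ev, pats, small_cal)
  prop <- prev$numerator / prev$denominator
  se <- sqrt(p * (1 - p) / 20000)
  expect_true(all(abs(prop - p) < 4 * se))
  # symmetric-chain oracle: expected rate is exactly 1000 p
  expect_equal(truth_expected_rate(truth, small_cal, 0:59),
               rep(1000 * p, 60))
})

test_that("zero persistence forbids consecutive-month events and makes the
           oracle linear in initiation", {
  truth <- simulation_truth(repeat_persistence = 0, population_start = 2000,
                            population_growth = 0, seed = 9)
  pats <- simulate_patients(truth, small_cal)
  ev <- simulate_prescriptions(pats, truth, small_cal)
  gaps <- ev |>
    dplyr::distinct(patient_id, month) |>
    dplyr::group_by(patient_id) |>
    dplyr::summarise(min_gap = min(diff(sort(month)), Inf))
  expect_true(all(gaps$min_gap >= 2))

  # with zero persistence the marginal is (1 - pi_prev) * i, so doubling
  # the initiation probability doubles the expected rate to first order
  # (exact linearity would need the consecutive-month exclusion to vanish)
  r1 <- truth_expected_rate(truth, small_cal, 0:59)
  truth2 <- simulation_truth(baseline_rate = 2 * truth$baseline_rate,
                             repeat_persistence = 0, seed = 9)
  r2 <- truth_expected_rate(truth2, small_cal, 0:59)
  expect_equal(r2, 2 * r1, tolerance = 2.5 * truth2$baseline_rate)
})

test_that("a step effect moves the observed rate by the configured factor", {
  # step of log(0.8) at the first interruption, persistence 0 so the
  # monthly proportion is the initiation probability itself
  truth <- simulation_truth(
    baseline_rate = 0.05, monthly_trend = 1,
    seasonal_amplitude_sin = 0, seasonal_amplitude_cos = 0,
    step_restriction = log(0.8), repeat_persistence = 0,
    population_start = 60000, population_growth = 0,
    subgroup_rate_modifiers = list(), seed = 31
  )
  pats <- simulate_patients(truth, small_cal)
  ev <- simulate_prescriptions(pats, truth, small_cal)
  prev <- monthly_prevalent_counts(ev, pats, small_cal)
  t1 <- small_cal$interruption_1
  # truth-implied rate with the step removed, from the expected-rate oracle
  # (identical chain history up to the interruption month)
  truth_no_step <- simulation_truth(
    baseline_rate = 0.05, monthly_trend = 1,
    seasonal_amplitude_sin = 0, seasonal_amplitude_cos = 0,
    step_restriction = 0, repeat_persistence = 0,
    population_start = 60000, population_growth = 0,
    subgroup_rate_modifiers = list(), seed = 31
  )
  no_step_rate <- truth_expected_rate(truth_no_step, small_cal, t1) / 1000
  observed <- prev$numerator[prev$t == t1] / prev$denominator[prev$t == t1]
  se <- sqrt(0.8 * no_step_rate * (1 - 0.8 * no_step_rate) / 60000)
  expect_lt(abs(observed / no_step_rate - 0.8), 3 * se / no_step_rate)
})

test_that("aggregated rates match the expected-rate oracle within 3 binomial
           SEs at every month", {
  truth <- simulation_truth(
    population_start = 200000, population_growth = 0,
    step_restriction = log(0.9), slope_recovery = log(1.002),
    outlier_effects = c("2020-03" = -0.25),
    subgroup_prevalences = list(), subgroup_rate_modifiers = list(),
    seed = 17
  )
  pats <- simulate_patients(truth, small_cal)
  ev <- simulate_prescriptions(pats, truth, small_cal)
  prev <- monthly_prevalent_counts(ev, pats, small_cal)
  expected <- truth_expected_rate(truth, small_cal, prev$t)
  pi_t <- expected / 1000
  se_rate <- 1000 * sqrt(pi_t * (1 - pi_t) / prev$denominator)
  observed <- 1000 * prev$numerator / prev$denominator
  expect_true(all(abs(observed - expected) <= 3 * se_rate))
})

test_that("count-level simulator realises the segmented rate model exactly", {
  truth <- simulation_truth(
    baseline_rate = 0.03, repeat_persistence = 0,
    step_restriction = log(0.85), slope_recovery = log(0.99),
    population_start = 50000, population_growth = 20,
    subgroup_prevalences = list(), subgroup_rate_modifiers = list(),
    second_event_prob = 0, seed = 23
  )
  fast <- simulate_monthly_counts(truth, small_cal)
  # denominators follow the configured linear growth
  expect_equal(fast$denominator, 50000L + 20L * fast$t)
  # counts are centred on N_t p_t with binomial spread
  p_t <- rxits:::truth_initiation_prob(truth, small_cal, fast$t)
  se <- sqrt(p_t * (1 - p_t) * fast$denominator)
  expect_true(all(abs(fast$numerator - fast$denominator * p_t) <= 4 * se))
  # deterministic under the truth seed, reseedable for replicates
  expect_identical(simulate_monthly_counts(truth, small_cal),
                   simulate_monthly_counts(truth, small_cal))
  expect_false(identical(
    simulate_monthly_counts(truth, small_cal, seed = 1)$numerator,
    simulate_monthly_counts(truth, small_cal, seed = 2)$numerator
  ))
})

test_that("invalid configurations are rejected with configuration errors", {
  expect_error(simulation_truth(baseline_rate = 1.2),
               class = "rxits_config_error")
  expect_error(simulation_truth(repeat_persistence = -0.1),
               class = "rxits_config_error")
  expect_error(
    simulation_truth(subgroup_prevalences = list(learning_disability = 1.4)),
    class = "rxits_config_error"
  )
  # implied probability >= 1 reports the offending month
  bad <- simulation_truth(baseline_rate = 0.9, monthly_trend = 1.01,
                          repeat_persistence = 0)
  expect_error(simulate_monthly_counts(bad, small_cal), "month",
               class = "rxits_config_error")
})

test_that("subgroup flags are drawn at the configured prevalence and
           modifiers raise flagged patients' rates", {
  truth <- simulation_truth(
    population_start = 30000, population_growth = 0,
    subgroup_prevalences = list(learning_disability = 0.2, sex_F = 0.5),
    subgroup_rate_modifiers = list(learning_disability = 2),
    seed = 41
  )
  pats <- simulate_patients(truth, small_cal)
  expect_equal(mean(pats$learning_disability), 0.2, tolerance = 0.02)
  ev <- simulate_prescriptions(pats, truth, small_cal)
  prev_ld <- monthly_prevalent_counts(ev, pats, small_cal,
                                      "learning_disability")
  prev_all <- monthly_prevalent_counts(ev, pats, small_cal)
  rate_ld <- sum(prev_ld$numerator) / sum(prev_ld$denominator)
  rate_all <- sum(prev_all$numerator) / sum(prev_all$denominator)
  expect_gt(rate_ld / rate_all, 1.3)
})

test_that("CSV round trip preserves patients and events", {
  truth <- simulation_truth(population_start = 300, population_growth = 0,
                            seed = 2)
  pats <- simulate_patients(truth, small_cal)
  pats$reg_end[1:5] <- 10L  # exercise closed intervals
  ev <- simulate_prescriptions(pats, truth, small_cal)
  dir <- withr::local_tempdir()
  write_cohort_csv(pats, ev, small_cal, dir)
  back <- read_cohort_csv(dir, small_cal)
  expect_equal(as.data.frame(back$patients), as.data.frame(pats))
  expect_equal(as.data.frame(back$events), as.data.frame(ev))
})
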