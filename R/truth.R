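# Ground-truth configuration of the synthetic data-generating process, and
# the closed-form expected-rate oracle implied by it.

#' Define the ground truth of the synthetic prescribing process
#'
#' The generator realises monthly prescribing as a two-state
#' (prescribed / not prescribed) Bernoulli chain per patient. A patient not
#' prescribed in month `t - 1` initiates a prescription in month `t` with
#' probability
#' \deqn{p_t = p_0 \, \tau^t \exp(a \sin(2\pi t/12) + b \cos(2\pi t/12)
#'   + \text{step/slope/outlier terms active at } t)}
#' while a patient prescribed in month `t - 1` is prescribed again with
#' probability `repeat_persistence`. Persistence is what separates prevalent
#' from new (incident) prescribing: with high persistence most prescribed
#' patients are repeat patients and fail the 24-month washout.
#'
#' Step and slope effects are on the log scale and switch on at the two
#' interruption points of the accompanying [study_calendar()]; outlier
#' effects apply to single named months. The defaults emulate a growing
#' registered population with a gently rising baseline initiation rate and
#' mild annual seasonality, at desk scale (tens of thousands of patients
#' standing in for tens of millions), with all interruption effects zero —
#' effects are switched on explicitly per experiment.
#'
#' @param baseline_rate Per-patient-month initiation probability at `t = 0`
#'   (in `(0, 1)`).
#' @param monthly_trend Multiplicative per-month factor on the initiation
#'   probability (e.g. `1.003` for +0.3%/month).
#' @param seasonal_amplitude_sin,seasonal_amplitude_cos Log-scale Fourier
#'   coefficients at period 12 months.
#' @param step_restriction,slope_restriction Log-scale level shift and
#'   per-month slope change switching on at the first interruption.
#' @param step_recovery,slope_recovery Same for the second interruption.
#' @param outlier_effects Named numeric vector of log-scale effects for
#'   single months, names ISO `"YYYY-MM"` (the March/April-2020 analogue),
#'   e.g. `c("2020-03" = -0.3)`.
#' @param repeat_persistence Probability (in `[0, 1]`) that a patient
#'   prescribed in month `t - 1` is prescribed again in month `t`.
#' @param population_start Registered patients at `t = 0`.
#' @param population_growth Net per-month additions to the registered
#'   population (linear growth).
#' @param subgroup_prevalences Named list/vector of marginal probabilities
#'   for subgroup flags, assigned independently per patient.
#' @param subgroup_rate_modifiers Named list/vector of multiplicative
#'   modifiers on `baseline_rate` for flagged patients (multiplied together
#'   when a patient carries several flags).
#' @param drug_class_probs Named probabilities over
#'   `c("ssri", "tricyclic", "maoi", "other")` used to label events.
#' @param second_event_prob Probability that a prescribed patient-month
#'   carries a second prescription issue (an independently drawn class),
#'   so that within-month duplicates and multi-class months occur.
#' @param burn_in_months History length simulated before the study window;
#'   must be at least 24 when new-prescribing outcomes (24-month washout)
#'   will be computed.
#' @param seed Integer seed; all generator randomness derives from it.
#'
#' @return A validated list of class `simulation_truth`.
#' @seealso [simulate_patients()], [simulate_prescriptions()],
#'   [truth_expected_rate()]
#' @export
simulation_truth <- function(baseline_rate = 0.02,
                             monthly_trend = 1.003,
                             seasonal_amplitude_sin = 0.02,
                             seasonal_amplitude_cos = 0.03,
                             step_restriction = 0,
                             slope_restriction = 0,
                             step_recovery = 0,
                             slope_recovery = 0,
                             outlier_effects = NULL,
                             repeat_persistence = 0.75,
                             population_start = 25000,
                             population_growth = 29,
                             subgroup_prevalences = list(
                               learning_disability = 0.006,
                               autism = 0.010,
                               care_home = 0.007,
                               sex_F = 0.5
                             ),
                             subgroup_rate_modifiers = list(
                               learning_disability = 2.3,
                               autism = 1.5
                             ),
                             drug_class_probs = c(
                               ssri = 0.58, tricyclic = 0.19,
                               maoi = 0.02, other = 0.21
                             ),
                             second_event_prob = 0.05,
                             burn_in_months = 30,
                             seed = 20180101) {
  truth <- list(
    baseline_rate = baseline_rate,
    monthly_trend = monthly_trend,
    seasonal_amplitude_sin = seasonal_amplitude_sin,
    seasonal_amplitude_cos = seasonal_amplitude_cos,
    step_restriction = step_restriction,
    slope_restriction = slope_restriction,
    step_recovery = step_recovery,
    slope_recovery = slope_recovery,
    outlier_effects = outlier_effects,
    repeat_persistence = repeat_persistence,
    population_start = population_start,
    population_growth = population_growth,
    subgroup_prevalences = as.list(subgroup_prevalences),
    subgroup_rate_modifiers = as.list(subgroup_rate_modifiers),
    drug_class_probs = drug_class_probs,
    second_event_prob = second_event_prob,
    burn_in_months = burn_in_months,
    seed = seed
  )
  class(truth) <- "simulation_truth"
  validate_truth(truth)
  truth
}

validate_truth <- function(truth) {
  err <- function(msg) rlang::abort(msg, class = "rxits_config_error")
  with(truth, {
    if (!(baseline_rate > 0 && baseline_rate < 1)) {
      err("baseline_rate must lie in (0, 1)")
    }
    if (!(repeat_persistence >= 0 && repeat_persistence <= 1)) {
      err("repeat_persistence must lie in [0, 1]")
    }
    if (monthly_trend <= 0) err("monthly_trend must be positive")
    if (population_start < 1) err("population_start must be at least 1")
    if (burn_in_months < 0) err("burn_in_months must be non-negative")
    prev <- unlist(subgroup_prevalences)
    if (length(prev) && (is.null(names(subgroup_prevalences)) ||
                         any(!nzchar(names(subgroup_prevalences))))) {
      err("subgroup_prevalences must be named")
    }
    if (any(prev < 0 | prev > 1)) {
      err("subgroup prevalences must lie in [0, 1]")
    }
    if (any(unlist(subgroup_rate_modifiers) <= 0)) {
      err("subgroup_rate_modifiers must be positive")
    }
    if (!is.null(outlier_effects) &&
        (is.null(names(outlier_effects)) || any(!nzchar(names(outlier_effects))))) {
      err("outlier_effects must be a named vector (ISO month names)")
    }
    if (abs(sum(drug_class_probs) - 1) > 1e-8 || any(drug_class_probs < 0)) {
      err("drug_class_probs must be non-negative and sum to 1")
    }
    if (!(second_event_prob >= 0 && second_event_prob <= 1)) {
      err("second_event_prob must lie in [0, 1]")
    }
    if (length(seed) != 1 || is.na(seed) || seed != as.integer(seed)) {
      err("seed must be a single integer")
    }
  })
  invisible(truth)
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat("<simulation_truth>\n")
  cat("  baseline initiation:", x$baseline_rate,
      " trend:", x$monthly_trend, "/month\n")
  cat("  persistence:", x$repeat_persistence,
      " population:", x$population_start, "+",
      x$population_growth, "/month\n")
  eff <- c(step_restriction = x$step_restriction,
           slope_restriction = x$slope_restriction,
           step_recovery = x$step_recovery,
           slope_recovery = x$slope_recovery)
  cat("  log-scale effects:",
      paste(names(eff), signif(eff, 3), sep = "=", collapse = " "), "\n")
  cat("  seed:", x$seed, " burn-in:", x$burn_in_months, "months\n")
  invisible(x)
}

# Per-month initiation probability implied by the truth, before subgroup
# modifiers. `t` may be negative (burn-in); interruption terms use the
# calendar. Vectorised over t.
truth_initiation_prob <- function(truth, calendar, t) {
  i1 <- calendar$interruption_1
  i2 <- calendar$interruption_2
  log_p <- log(truth$baseline_rate) +
    t * log(truth$monthly_trend) +
    truth$seasonal_amplitude_sin * sin(2 * pi * t / 12) +
    truth$seasonal_amplitude_cos * cos(2 * pi * t / 12) +
    truth$step_restriction * (t >= i1) +
    truth$slope_restriction * pmax(0, t - i1 + 1) +
    truth$step_recovery * (t >= i2) +
    truth$slope_recovery * pmax(0, t - i2 + 1)
  if (!is.null(truth$outlier_effects)) {
    out_idx <- month_to_index(calendar, names(truth$outlier_effects))
    for (k in seq_along(out_idx)) {
      log_p <- log_p + truth$outlier_effects[[k]] * (t == out_idx[k])
    }
  }
  exp(log_p)
}

# Error if any in-window initiation probability (including the largest
# subgroup modifier) reaches 1.
check_probabilities <- function(truth, calendar) {
  t <- calendar$months$t
  mod <- c(1, unlist(truth$subgroup_rate_modifiers))
  p <- truth_initiation_prob(truth, calendar, t) * max(mod)
  if (any(p >= 1)) {
    bad <- calendar$months$month[which(p >= 1)[1]]
    rlang::abort(
      paste0("Implied initiation probability >= 1 at month ", bad),
      class = "rxits_config_error"
    )
  }
  invisible(TRUE)
}

#' Expected prevalent prescribing rate implied by the truth
#'
#' Closed-form oracle for the generator: the expected prescribed
#' proportion of the two-state (prescribed / not prescribed) chain with
#' the month's initiation probability \eqn{i_t} and persistence
#' \eqn{\rho}, scaled to a rate per 1000 patients.
#'
#' The default `"marginal"` method computes the chain's exact marginal
#' probability by the one-step recursion
#' \deqn{\pi_t = \pi_{t-1}\,\rho + (1 - \pi_{t-1})\, i_t}
#' from \eqn{\pi = 0} at the start of burn-in — exactly the expectation of
#' the simulated process for a continuously registered, unflagged patient.
#' The `"stationary"` method returns the fixed point
#' \deqn{\pi_t = \frac{i_t}{i_t + 1 - \rho}}
#' of that recursion at the month's rates (the balance equation
#' \eqn{\pi = \pi\rho + (1-\pi) i}); the two coincide when the initiation
#' probability is constant, and the marginal lags the moving fixed point
#' slightly when rates drift or oscillate. With persistence 0 both reduce
#' to \eqn{1000 \, i_t}.
#'
#' Subgroup modifiers are not applied; the oracle describes a baseline
#' (unflagged) patient.
#'
#' @param truth A [simulation_truth()].
#' @param calendar A [study_calendar()].
#' @param month ISO month string(s) or integer time index/indices within the
#'   window.
#' @param method `"marginal"` (exact chain marginal, default) or
#'   `"stationary"` (fixed-point approximation).
#' @return Numeric vector: expected prevalent prescriptions per 1000
#'   patients at each requested month.
#' @export
truth_expected_rate <- function(truth, calendar, month,
                                method = c("marginal", "stationary")) {
  method <- match.arg(method)
  t <- if (is.character(month)) month_to_index(calendar, month) else as.integer(month)
  if (any(t < 0 | t >= calendar$n_months)) {
    rlang::abort("month outside the study window", class = "rxits_config_error")
  }
  rho <- truth$repeat_persistence
  if (method == "stationary") {
    i <- truth_initiation_prob(truth, calendar, t)
    return(1000 * i / (i + 1 - rho))
  }
  ts_all <- (-truth$burn_in_months):(calendar$n_months - 1L)
  i_all <- truth_initiation_prob(truth, calendar, ts_all)
  pi <- 0
  pi_path <- numeric(length(ts_all))
  for (k in seq_along(ts_all)) {
    pi <- pi * rho + (1 - pi) * i_all[k]
    pi_path[k] <- pi
  }
  1000 * pi_path[match(t, ts_all)]
}
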