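# Patient-level synthetic data: registration records and prescription
# events realising the two-state initiation/persistence chain.

#' Simulate registration records
#'
#' Generates one record per patient with a registration interval (month
#' indices, half-open, end exclusive; `NA` end = still registered) and 0/1
#' subgroup flag columns drawn independently at the configured prevalences.
#'
#' The registered population grows linearly: at every in-window month `t`
#' the number of open records is `population_start + t * population_growth`
#' (rounded to whole patients). The founding cohort is registered from the
#' start of the burn-in period so prescription history is observable over
#' the full washout window; monthly entrants register at their entry month.
#'
#' @param truth A [simulation_truth()].
#' @param calendar A [study_calendar()].
#' @return A tibble with columns `patient_id`, `reg_start`, `reg_end`
#'   (month indices; `reg_end` is `NA` for open intervals) and one 0/1
#'   column per configured subgroup flag.
#' @export
simulate_patients <- function(truth, calendar) {
  validate_truth(truth)
  t_first <- -truth$burn_in_months
  t_last <- calendar$n_months - 1L

  pop_at <- function(t) round(truth$population_start + t * truth$population_growth)
  n0 <- pop_at(t_first)
  if (n0 < 1) {
    rlang::abort(
      "Population at burn-in start would be < 1; reduce burn_in_months or growth",
      class = "rxits_config_error"
    )
  }
  # entrants at month t (t > t_first) top the population up to pop_at(t)
  sizes <- diff(vapply(t_first:t_last, pop_at, numeric(1)))
  starts <- c(rep(t_first, n0), rep((t_first + 1L):t_last, times = pmax(sizes, 0)))

  withr::with_seed(truth$seed, {
    n <- length(starts)
    patients <- tibble::tibble(
      patient_id = sprintf("p%06d", seq_len(n)),
      reg_start = as.integer(starts),
      reg_end = NA_integer_
    )
    for (flag in names(truth$subgroup_prevalences)) {
      patients[[flag]] <- as.integer(
        stats::runif(n) < truth$subgroup_prevalences[[flag]]
      )
    }
    patients
  })
}

#' Simulate prescription events
#'
#' Realises the initiation/persistence chain month by month over the
#' burn-in and study window: a patient not prescribed in month `t - 1`
#' receives a prescription in month `t` with the truth-implied initiation
#' probability (times any subgroup modifiers); a patient prescribed in
#' `t - 1` is prescribed again with probability `repeat_persistence`.
#' Events are only generated while the patient is registered. Each
#' prescribed patient-month yields one event with a drug class drawn from
#' `drug_class_probs`, plus, with probability `second_event_prob`, a second
#' same-month event (independently drawn class) so duplicate and
#' multi-class months occur.
#'
#' Deterministic given the truth (including its seed): the same
#' configuration always yields the identical event set.
#'
#' @param patients Output of [simulate_patients()] under the same truth.
#' @param truth A [simulation_truth()].
#' @param calendar A [study_calendar()].
#' @return A tibble with columns `patient_id`, `month` (index; negative
#'   during burn-in), `drug_class`.
#' @export
simulate_prescriptions <- function(patients, truth, calendar) {
  validate_truth(truth)
  check_probabilities(truth, calendar)
  t_first <- -truth$burn_in_months
  t_last <- calendar$n_months - 1L

  n <- nrow(patients)
  modifier <- rep(1, n)
  for (flag in names(truth$subgroup_rate_modifiers)) {
    if (flag %in% names(patients)) {
      modifier <- modifier *
        ifelse(patients[[flag]] == 1, truth$subgroup_rate_modifiers[[flag]], 1)
    }
  }
  reg_start <- patients$reg_start
  reg_end <- ifelse(is.na(patients$reg_end), t_last + 1L, patients$reg_end)

  classes <- names(truth$drug_class_probs)
  months_list <- vector("list", t_last - t_first + 1L)
  ids_list <- vector("list", t_last - t_first + 1L)
  cls_list <- vector("list", t_last - t_first + 1L)

  withr::with_seed(truth$seed + 1L, {
    prescribed_prev <- rep(FALSE, n)
    k <- 0L
    for (t in t_first:t_last) {
      k <- k + 1L
      registered <- reg_start <= t & t < reg_end
      p_init <- truth_initiation_prob(truth, calendar, t) * modifier
      p <- ifelse(prescribed_prev, truth$repeat_persistence, p_init)
      if (any(p[registered] >= 1)) {
        rlang::abort(
          paste0("Implied prescription probability >= 1 at month ",
                 add_months(calendar$start, t)),
          class = "rxits_config_error"
        )
      }
      prescribed <- registered & (stats::runif(n) < p)
      idx <- which(prescribed)
      if (length(idx)) {
        second <- stats::runif(length(idx)) < truth$second_event_prob
        ids <- c(patients$patient_id[idx], patients$patient_id[idx][second])
        cls <- sample(classes, length(ids), replace = TRUE,
                      prob = truth$drug_class_probs)
        ids_list[[k]] <- ids
        cls_list[[k]] <- cls
        months_list[[k]] <- rep(t, length(ids))
      }
      prescribed_prev <- prescribed
    }
  })

  tibble::tibble(
    patient_id = unlist(ids_list) %||% character(0),
    month = as.integer(unlist(months_list) %||% integer(0)),
    drug_class = unlist(cls_list) %||% character(0)
  ) |>
    dplyr::arrange(.data$month, .data$patient_id)
}

#' Simulate monthly prevalent counts from the segmented rate model
#'
#' Draws monthly counts `y_t ~ Binomial(N_t, p_t)` directly, where `p_t`
#' is the truth-implied segmented log-linear probability (baseline, trend,
#' seasonality, steps/slopes/outliers) and
#' `N_t = population_start + t * population_growth` — i.e. exactly the
#' data-generating process the Poisson ITSA with log-population offset
#' assumes, with a known coefficient vector. This is the workhorse for
#' replicated calibration studies (parameter recovery, CI coverage),
#' where hundreds of series are needed.
#'
#' It is the pure initiation process: `repeat_persistence` is ignored.
#' The patient-level generator ([simulate_prescriptions()]) differs even
#' at persistence 0, because a patient prescribed in month `t - 1` is
#' then never prescribed at `t`, deflating the marginal rate by the
#' factor `1 - pi_(t-1)` (a few percent at typical prevalences); use
#' [truth_expected_rate()] as the oracle for that path.
#'
#' @inheritParams simulate_patients
#' @param seed Optional seed overriding `truth$seed` (handy for replicate
#'   loops); kept separate so the truth object itself stays immutable.
#' @return A monthly series tibble with columns `month`, `t`, `subgroup`,
#'   `outcome`, `numerator`, `denominator`, `redacted`, `rounded` —
#'   the same shape as [monthly_prevalent_counts()].
#' @export
simulate_monthly_counts <- function(truth, calendar, seed = NULL) {
  validate_truth(truth)
  check_probabilities(truth, calendar)
  t <- calendar$months$t
  p <- truth_initiation_prob(truth, calendar, t)
  n_t <- round(truth$population_start + t * truth$population_growth)
  y <- withr::with_seed(seed %||% truth$seed, stats::rbinom(length(t), n_t, p))
  tibble::tibble(
    month = calendar$months$month,
    t = t,
    subgroup = "all",
    outcome = "prevalent",
    numerator = as.integer(y),
    denominator = as.integer(n_t),
    redacted = FALSE,
    rounded = FALSE
  )
}

#' Write synthetic patients and events as CSV
#'
#' Months are encoded as ISO `"YYYY-MM"` in the files; burn-in months fall
#' before the window start. Registration ends that are open are written as
#' empty fields.
#'
#' @param patients,events Tibbles from [simulate_patients()] /
#'   [simulate_prescriptions()].
#' @param calendar The [study_calendar()] used to encode months.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_cohort_csv <- function(patients, events, calendar, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- patients
  p$reg_start <- add_months(calendar$start, p$reg_start)
  p$reg_end <- ifelse(is.na(p$reg_end), "",
                      add_months(calendar$start, p$reg_end))
  e <- events
  e$month <- add_months(calendar$start, e$month)
  paths <- c(patients = file.path(dir, "patients.csv"),
             events = file.path(dir, "events.csv"))
  readr::write_csv(p, paths[["patients"]])
  readr::write_csv(e, paths[["events"]])
  invisible(paths)
}

#' Read patients and events written by [write_cohort_csv()]
#'
#' @param dir Directory containing `patients.csv` and `events.csv`.
#' @param calendar The [study_calendar()] used to decode months.
#' @return A list with tibbles `patients` and `events` (months as indices).
#' @export
read_cohort_csv <- function(dir, calendar) {
  p <- readr::read_csv(file.path(dir, "patients.csv"),
                       col_types = readr::cols(
                         patient_id = readr::col_character(),
                         reg_start = readr::col_character(),
                         reg_end = readr::col_character(),
                         .default = readr::col_integer()
                       ))
  e <- readr::read_csv(file.path(dir, "events.csv"),
                       col_types = readr::cols(
                         patient_id = readr::col_character(),
                         month = readr::col_character(),
                         drug_class = readr::col_character()
                       ))
  p$reg_start <- month_to_index(calendar, p$reg_start)
  end_raw <- p$reg_end
  has_end <- !is.na(end_raw) & end_raw != ""
  reg_end <- rep(NA_integer_, nrow(p))
  reg_end[has_end] <- month_to_index(calendar, end_raw[has_end])
  p$reg_end <- reg_end
  e$month <- month_to_index(calendar, e$month)
  list(patients = p, events = e)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
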