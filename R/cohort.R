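# Cohort aggregation: event-level records -> monthly numerators and
# denominators for prevalent and new (incident) prescribing, per subgroup.

check_event_integrity <- function(events, patients) {
  unknown <- setdiff(unique(events$patient_id), patients$patient_id)
  if (length(unknown)) {
    rlang::abort(
      paste0("Events reference unknown patient id(s): ",
             paste(utils::head(unknown, 5), collapse = ", "),
             if (length(unknown) > 5) " ..." else ""),
      class = "rxits_data_error"
    )
  }
  invisible(TRUE)
}

# patients restricted to a subgroup flag ("all" keeps everyone)
subgroup_patients <- function(patients, subgroup) {
  if (identical(subgroup, "all")) return(patients)
  if (!subgroup %in% names(patients)) {
    rlang::abort(paste0("Unknown subgroup flag: ", subgroup),
                 class = "rxits_data_error")
  }
  patients[patients[[subgroup]] == 1, , drop = FALSE]
}

# registered-patient count for each t in `ts` (vectorised over patients)
registered_count <- function(patients, ts) {
  end <- ifelse(is.na(patients$reg_end), Inf, patients$reg_end)
  vapply(ts, function(t) sum(patients$reg_start <= t & t < end), integer(1))
}

month_series_skeleton <- function(calendar, subgroup, outcome) {
  tibble::tibble(
    month = calendar$months$month,
    t = calendar$months$t,
    subgroup = subgroup,
    outcome = outcome,
    numerator = 0L,
    denominator = 0L,
    redacted = FALSE,
    rounded = FALSE
  )
}

#' Monthly prevalent prescribing counts
#'
#' For each month of the study window, counts distinct registered patients
#' with at least one prescription event in that month (a patient with
#' several prescriptions in one month is counted once) over the denominator
#' of all registered patients, optionally restricted to a subgroup flag.
#'
#' @param events Event tibble (`patient_id`, `month` index, `drug_class`).
#' @param patients Patient tibble (`patient_id`, `reg_start`, `reg_end`,
#'   flag columns).
#' @param calendar A [study_calendar()].
#' @param subgroup `"all"` or the name of a 0/1 flag column in `patients`.
#' @return A monthly series tibble: `month`, `t`, `subgroup`, `outcome`,
#'   `numerator`, `denominator`, `redacted`, `rounded`.
#' @export
monthly_prevalent_counts <- function(events, patients, calendar,
                                     subgroup = "all") {
  check_event_integrity(events, patients)
  pats <- subgroup_patients(patients, subgroup)
  ser <- month_series_skeleton(calendar, subgroup, "prevalent")

  ev <- events |>
    dplyr::filter(.data$month >= 0, .data$month < calendar$n_months) |>
    dplyr::semi_join(pats, by = "patient_id") |>
    dplyr::distinct(.data$patient_id, .data$month) |>
    dplyr::inner_join(
      pats[, c("patient_id", "reg_start", "reg_end")], by = "patient_id"
    ) |>
    dplyr::filter(
      .data$reg_start <= .data$month,
      is.na(.data$reg_end) | .data$month < .data$reg_end
    ) |>
    dplyr::count(.data$month, name = "numerator")

  ser$numerator[match(ev$month, ser$t)] <- ev$numerator
  ser$denominator <- registered_count(pats, ser$t)
  ser
}

#' Monthly new (incident) prescribing counts
#'
#' A prescription at month `t` is "new" when the patient had no
#' prescription event in the 24 calendar months strictly before `t`
#' (the washout window `[t - 24, t - 1]`). The numerator counts distinct
#' registered patients with a new prescription at `t`; the denominator is
#' the antidepressant-naive registered population — registered patients
#' with no event in the washout window. Burn-in history (negative month
#' indices) participates in the washout, so new prescribing is decidable
#' from the first study month; if the supplied records cannot cover the
#' washout at month 0 an error is raised rather than silently truncating.
#'
#' @inheritParams monthly_prevalent_counts
#' @param washout_months Length of the washout window (months strictly
#'   before the index month), default 24 (the "previous 2 years").
#' @param naive_denominator If `TRUE` (default) the denominator is the
#'   antidepressant-naive registered population; if `FALSE`, all registered
#'   patients.
#' @return A monthly series tibble, `outcome = "new"`.
#' @export
monthly_new_counts <- function(events, patients, calendar, subgroup = "all",
                               washout_months = 24,
                               naive_denominator = TRUE) {
  check_event_integrity(events, patients)
  if (min(patients$reg_start) > -washout_months) {
    rlang::abort(
      paste0("Insufficient history: need records from ", washout_months,
             " months before the window start to decide the washout"),
      class = "rxits_data_error"
    )
  }
  pats <- subgroup_patients(patients, subgroup)
  ser <- month_series_skeleton(calendar, subgroup, "new")
  n_months <- calendar$n_months

  ev <- events |>
    dplyr::semi_join(pats, by = "patient_id") |>
    dplyr::distinct(.data$patient_id, .data$month) |>
    dplyr::arrange(.data$patient_id, .data$month)

  # numerator: event months whose predecessor (same patient) is more than
  # `washout_months` months back
  new_ev <- ev |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(gap = .data$month - dplyr::lag(.data$month)) |>
    dplyr::ungroup() |>
    dplyr::filter(is.na(.data$gap) | .data$gap > washout_months) |>
    dplyr::filter(.data$month >= 0, .data$month < n_months) |>
    dplyr::inner_join(
      pats[, c("patient_id", "reg_start", "reg_end")], by = "patient_id"
    ) |>
    dplyr::filter(
      .data$reg_start <= .data$month,
      is.na(.data$reg_end) | .data$month < .data$reg_end
    ) |>
    dplyr::count(.data$month, name = "numerator")
  ser$numerator[match(new_ev$month, ser$t)] <- new_ev$numerator

  if (naive_denominator) {
    # per patient, union the month intervals blocked by each event
    # (months m+1 .. m+washout are non-naive), then count blocked
    # registered patient-months with a +1/-1 difference array
    blocked <- ev |>
      dplyr::mutate(
        from = .data$month + 1L,
        to = .data$month + as.integer(washout_months)  # inclusive
      ) |>
      dplyr::filter(.data$to >= 0, .data$from <= n_months - 1L) |>
      dplyr::mutate(from = pmax(.data$from, 0L),
                    to = pmin(.data$to, n_months - 1L)) |>
      dplyr::inner_join(
        pats[, c("patient_id", "reg_start", "reg_end")], by = "patient_id"
      ) |>
      dplyr::mutate(
        from = pmax(.data$from, .data$reg_start),
        to = pmin(.data$to,
                  ifelse(is.na(.data$reg_end), n_months - 1L,
                         .data$reg_end - 1L))
      ) |>
      dplyr::filter(.data$from <= .data$to) |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::arrange(.data$from, .by_group = TRUE) |>
      # merge overlapping intervals so each patient counts once per month
      dplyr::mutate(
        new_run = cumsum(
          dplyr::lag(cummax(.data$to), default = -2L) < .data$from - 1L
        )
      ) |>
      dplyr::group_by(.data$patient_id, .data$new_run) |>
      dplyr::summarise(from = min(.data$from), to = max(.data$to),
                       .groups = "drop")

    diff_arr <- rep(0L, n_months + 1L)
    if (nrow(blocked)) {
      add <- tabulate(blocked$from + 1L, nbins = n_months)
      rem <- tabulate(blocked$to + 2L, nbins = n_months + 1L)
      diff_arr <- c(add, 0L) - rem
    }
    blocked_per_month <- cumsum(diff_arr)[seq_len(n_months)]
    ser$denominator <- registered_count(pats, ser$t) - blocked_per_month
  } else {
    ser$denominator <- registered_count(pats, ser$t)
  }
  ser
}

#' Apply statistical disclosure control to a monthly series
#'
#' Counts less than or equal to the redaction threshold are suppressed
#' (set to `NA`, `redacted = TRUE`); remaining counts are rounded to the
#' nearest multiple of `round_to`, with ties going away from zero
#' (15 -> 20). The function is pure (the input series is not modified) and
#' idempotent: already-rounded counts pass through unchanged.
#'
#' Never apply disclosure control to the series passed to the model;
#' modelling uses raw counts, disclosure control is for published outputs
#' only.
#'
#' @param series A monthly series tibble with `numerator` and `denominator`.
#' @param redact_le Redact counts `<=` this value (default 5; the threshold
#'   is read literally, so 0 is redacted too).
#' @param round_to Rounding base for surviving counts (default 10).
#' @return The series with redaction/rounding applied and the `redacted`
#'   and `rounded` flags set.
#' @export
apply_disclosure_control <- function(series, redact_le = 5, round_to = 10) {
  round_away <- function(x) {
    ifelse(is.na(x), NA_integer_,
           as.integer(sign(x) * floor(abs(x) / round_to + 0.5) * round_to))
  }
  series |>
    dplyr::mutate(
      redacted = is.na(.data$numerator) | .data$numerator <= redact_le |
        is.na(.data$denominator) | .data$denominator <= redact_le,
      numerator = ifelse(.data$redacted, NA_integer_,
                         round_away(.data$numerator)),
      denominator = ifelse(.data$redacted, NA_integer_,
                           round_away(.data$denominator)),
      rounded = TRUE
    )
}

#' Prescribing rate per 1000 patients
#'
#' `1000 * numerator / denominator`, reported to one decimal place, the
#' convention for published prescribing rates. For descriptive tables the
#' inputs are the disclosure-controlled (rounded) counts, so the published
#' rate is computed from the published numbers.
#'
#' @param numerator,denominator Non-negative counts (vectorised).
#' @return Rates per 1000, rounded to one decimal.
#' @examples
#' rate_per_1000(2048040, 25455570) # 80.5
#' @export
rate_per_1000 <- function(numerator, denominator) {
  if (any(!is.na(denominator) & denominator <= 0)) {
    rlang::abort("Rate undefined: zero or negative denominator",
                 class = "rxits_data_error")
  }
  round(1000 * numerator / denominator, 1)
}

#' Assign a drug class to a patient-month
#'
#' Maps the set of prescription classes a patient received in one month to
#' a single label: monoamine-oxidase inhibitors are merged into `"other"`;
#' a single remaining class labels the month with that class; two or more
#' distinct classes label it `"multiple"`.
#'
#' @param classes Character vector of event classes for one patient-month
#'   (subset of `ssri`, `tricyclic`, `maoi`, `other`; at least one).
#' @return A single label: `"ssri"`, `"tricyclic"`, `"other"` or
#'   `"multiple"`.
#' @examples
#' assign_drug_class(c("ssri", "ssri")) # "ssri"
#' assign_drug_class("maoi") # "other"
#' assign_drug_class(c("ssri", "other")) # "multiple"
#' @export
assign_drug_class <- function(classes) {
  known <- c("ssri", "tricyclic", "maoi", "other")
  if (length(classes) == 0) {
    rlang::abort("At least one event class required",
                 class = "rxits_data_error")
  }
  bad <- setdiff(unique(classes), known)
  if (length(bad)) {
    rlang::abort(paste0("Unknown drug class(es): ",
                        paste(bad, collapse = ", ")),
                 class = "rxits_data_error")
  }
  mapped <- unique(ifelse(classes == "maoi", "other", classes))
  if (length(mapped) > 1) "multiple" else mapped
}
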