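# Orchestration: one configuration drives simulate -> aggregate -> fit ->
# effects, writing CSV outputs and a reproducibility manifest.

#' Descriptive summary table for a single month
#'
#' The census-style table: for each subgroup, the count of patients
#' prescribed in the month, the registered count, the prescribing rate
#' per 1000, and the drug-class breakdown of prescribed patients
#' (SSRI / tricyclic / other / multiple, with MAOIs merged into "other").
#' Counts are disclosure-controlled (small cells suppressed, the rest
#' rounded to the nearest 10) and the published rate is computed from the
#' rounded counts, so a reader can reproduce it from the table itself.
#'
#' @param events,patients Event and patient tibbles (month as index).
#' @param calendar A [study_calendar()].
#' @param month ISO month or index to describe.
#' @param subgroups Character vector of subgroup flags (plus `"all"`).
#' @param disclosure Apply disclosure control (default `TRUE`).
#' @return A tibble: `subgroup`, `prescribed`, `registered`,
#'   `rate_per_1000`, `redacted`, and class share columns `pct_ssri`,
#'   `pct_tricyclic`, `pct_other`, `pct_multiple`.
#' @export
descriptive_table <- function(events, patients, calendar, month,
                              subgroups = "all", disclosure = TRUE) {
  t_idx <- if (is.character(month)) month_to_index(calendar, month) else
    as.integer(month)
  if (t_idx < 0 || t_idx >= calendar$n_months) {
    rlang::abort("month outside the study window",
                 class = "rxits_data_error")
  }
  check_event_integrity(events, patients)
  month_events <- events[events$month == t_idx, , drop = FALSE]

  purrr::map(unique(c(subgroups)), function(sg) {
    pats <- subgroup_patients(patients, sg)
    end <- ifelse(is.na(pats$reg_end), Inf, pats$reg_end)
    registered_ids <- pats$patient_id[pats$reg_start <= t_idx & t_idx < end]
    ev <- month_events[month_events$patient_id %in% registered_ids, ,
                       drop = FALSE]
    n_prescribed_raw <- length(unique(ev$patient_id))
    prescribed <- n_prescribed_raw
    registered <- length(registered_ids)

    class_by_patient <- if (n_prescribed_raw > 0) {
      vapply(split(ev$drug_class, ev$patient_id), assign_drug_class,
             character(1))
    } else {
      character(0)
    }
    share <- function(cls) {
      if (n_prescribed_raw == 0) NA_real_ else
        round(100 * mean(class_by_patient == cls), 1)
    }

    if (disclosure) {
      ser <- tibble::tibble(numerator = prescribed,
                            denominator = registered,
                            redacted = FALSE, rounded = FALSE)
      ser <- apply_disclosure_control(ser)
      prescribed <- ser$numerator
      registered <- ser$denominator
      redacted <- ser$redacted
    } else {
      redacted <- FALSE
    }
    tibble::tibble(
      subgroup = sg,
      prescribed = prescribed,
      registered = registered,
      rate_per_1000 = if (redacted) NA_real_ else
        rate_per_1000(prescribed, registered),
      redacted = redacted,
      pct_ssri = share("ssri"),
      pct_tricyclic = share("tricyclic"),
      pct_other = share("other"),
      pct_multiple = share("multiple")
    )
  }) |>
    purrr::list_rbind()
}

#' Run the full pipeline from one configuration
#'
#' Stages: simulate patient-level data (or read supplied CSVs in the
#' documented schema), aggregate monthly prevalent and new prescribing
#' series per subgroup, fit the segmented Poisson model per
#' subgroup/outcome, and summarise effects against the counterfactual.
#' Outputs are written as CSV plus a JSON manifest (configuration, seed,
#' package version, configuration hash) so a run is reproducible from its
#' manifest. Any stage error aborts with the stage name attached.
#'
#' @param config A named list (or path to a YAML file) with elements:
#'   `calendar` (arguments for [study_calendar()]), exactly one of `truth`
#'   (arguments for [simulation_truth()]) or `input_dir` (directory with
#'   `patients.csv`/`events.csv`), and optionally `subgroups` (character,
#'   default `"all"`), `outcomes` (subset of `c("prevalent", "new")`),
#'   `lag`, `fourier_pairs`, `window` (length-2 ISO months for the
#'   averaging window), `disclosure` (logical, default `TRUE`),
#'   `descriptive_month` (ISO month, default 2 months before the window
#'   end), `out_dir` (default `tempfile()`).
#' @return Invisibly, a list with the output directory, the manifest, and
#'   the in-memory results (`series`, `fits`, `effects`, `coefficients`,
#'   `descriptive`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(paste0("Pipeline stage '", name, "' failed: ",
                          conditionMessage(e)),
                   class = "rxits_pipeline_error", parent = e)
    })
  }

  has_truth <- !is.null(config$truth)
  has_input <- !is.null(config$input_dir)
  if (has_truth == has_input) {
    rlang::abort("Exactly one of config$truth or config$input_dir required",
                 class = "rxits_config_error")
  }

  calendar <- stage("calendar",
                    do.call(study_calendar, config$calendar %||% list()))
  out_dir <- config$out_dir %||% tempfile("rxits_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  subgroups <- config$subgroups %||% "all"
  outcomes <- config$outcomes %||% c("prevalent", "new")
  disclosure <- config$disclosure %||% TRUE

  if (has_truth) {
    truth <- stage("simulate", do.call(simulation_truth, config$truth))
    patients <- stage("simulate", simulate_patients(truth, calendar))
    events <- stage("simulate",
                    simulate_prescriptions(patients, truth, calendar))
    write_cohort_csv(patients, events, calendar, out_dir)
  } else {
    dat <- stage("read", read_cohort_csv(config$input_dir, calendar))
    patients <- dat$patients
    events <- dat$events
  }

  series <- stage("aggregate", {
    purrr::map(subgroups, function(sg) {
      out <- list()
      if ("prevalent" %in% outcomes) {
        out$prevalent <- monthly_prevalent_counts(events, patients,
                                                  calendar, sg)
      }
      if ("new" %in% outcomes) {
        out$new <- monthly_new_counts(events, patients, calendar, sg)
      }
      purrr::list_rbind(out)
    }) |> purrr::list_rbind()
  })
  published <- if (disclosure) apply_disclosure_control(series) else series
  readr::write_csv(published, file.path(out_dir, "series.csv"))

  fits <- stage("fit", {
    series |>
      dplyr::group_by(.data$subgroup, .data$outcome) |>
      dplyr::group_map(function(ser, key) {
        design <- build_design_matrix(
          calendar, ser,
          fourier_pairs = config$fourier_pairs %||% 1
        )
        fit <- fit_poisson_itsa(design, lag = config$lag %||% 2)
        list(subgroup = key$subgroup, outcome = key$outcome, fit = fit)
      })
  })

  coef_tbl <- purrr::map(fits, function(f) {
    dplyr::mutate(coefficient_table(f$fit),
                  subgroup = f$subgroup, outcome = f$outcome,
                  .before = 1)
  }) |> purrr::list_rbind()
  readr::write_csv(coef_tbl, file.path(out_dir, "coefficients.csv"))

  effects_tbl <- stage("effects", {
    purrr::map(fits, function(f) {
      avg <- average_rr(f$fit, window = config$window)
      rd <- rate_difference(f$fit)
      tibble::tibble(
        subgroup = f$subgroup, outcome = f$outcome,
        average_rr = avg$rr, rr_ci_low = avg$ci_low,
        rr_ci_high = avg$ci_high,
        rate_diff_last_month = rd$rate_difference,
        rate_diff_ci_low = rd$ci_low, rate_diff_ci_high = rd$ci_high
      )
    }) |> purrr::list_rbind()
  })
  readr::write_csv(effects_tbl, file.path(out_dir, "effects.csv"))

  desc_month <- config$descriptive_month %||%
    index_to_month(calendar, calendar$n_months - 3L)
  descriptive <- stage("descriptive",
                       descriptive_table(events, patients, calendar,
                                         desc_month, subgroups,
                                         disclosure = disclosure))
  readr::write_csv(descriptive, file.path(out_dir, "descriptive.csv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("rxits")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = if (has_truth) config$truth$seed else NULL,
    config = config,
    config_hash = rlang::hash(config),
    outputs = c("series.csv", "coefficients.csv", "effects.csv",
                "descriptive.csv")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")

  invisible(list(
    out_dir = out_dir, manifest = manifest, calendar = calendar,
    series = series, published = published, fits = fits,
    coefficients = coef_tbl, effects = effects_tbl,
    descriptive = descriptive
  ))
}
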