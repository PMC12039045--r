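# Study calendar: maps ISO "YYYY-MM" months to a zero-based model time index
# and records the interruption points and outlier months.

parse_iso_month <- function(x) {
  ok <- grepl("^\\d{4}-(0[1-9]|1[0-2])$", x)
  if (!all(ok)) {
    rlang::abort(
      paste0("Invalid ISO month(s): ", paste(x[!ok], collapse = ", "),
             " (expected \"YYYY-MM\")"),
      class = "rxits_calendar_error"
    )
  }
  list(year = as.integer(substr(x, 1, 4)), mon = as.integer(substr(x, 6, 7)))
}

#' Create a study calendar
#'
#' A study calendar maps calendar months to the zero-based time index `t`
#' used throughout the package, and records the two interruption points
#' (start of the restrictions period and start of the recovery period) and
#' any outlier months to be absorbed by dummy variables.
#'
#' The default window is the 60 months January 2018 to December 2022, with
#' interruptions in March 2020 (restrictions, `t = 26`) and March 2021
#' (recovery, `t = 38`) and outlier dummies for March and April 2020 — the
#' three-period design of a pre-interruption phase, a 12-month restrictions
#' phase and a 22-month recovery phase.
#'
#' @param start,end ISO `"YYYY-MM"` months delimiting the study window
#'   (inclusive).
#' @param interruption_1 ISO month at which the first interruption (level
#'   shift and slope change) takes effect.
#' @param interruption_2 ISO month of the second interruption. Must be after
#'   `interruption_1` and within the window.
#' @param outlier_months Character vector of ISO months coded as outlier
#'   dummies; must lie in `[interruption_1, interruption_2)`.
#'
#' @return An object of class `study_calendar`: a list with the window
#'   endpoints, `n_months`, integer indices `interruption_1`,
#'   `interruption_2` and `outlier_months`, and a `months` tibble with
#'   columns `month` (ISO) and `t` (index, starting at 0).
#'
#' @examples
#' cal <- study_calendar()
#' cal$interruption_1 # 26
#' head(cal$months)
#' @export
study_calendar <- function(start = "2018-01",
                           end = "2022-12",
                           interruption_1 = "2020-03",
                           interruption_2 = "2021-03",
                           outlier_months = c("2020-03", "2020-04")) {
  n <- month_diff(start, end) + 1L
  if (n < 2L) {
    rlang::abort("Study window must span at least two months",
                 class = "rxits_calendar_error")
  }
  months <- tibble::tibble(t = seq_len(n) - 1L)
  months$month <- add_months(start, months$t)

  i1 <- month_diff(start, interruption_1)
  i2 <- month_diff(start, interruption_2)
  out_idx <- vapply(outlier_months, function(m) month_diff(start, m), integer(1))
  out_idx <- unname(sort(unique(out_idx)))

  if (!(i1 > 0L && i2 > i1 && i2 <= n - 1L)) {
    rlang::abort(
      "Require 0 < interruption_1 < interruption_2 <= last month index",
      class = "rxits_calendar_error"
    )
  }
  if (length(out_idx) && !all(out_idx >= i1 & out_idx < i2)) {
    rlang::abort(
      "Outlier months must lie in [interruption_1, interruption_2)",
      class = "rxits_calendar_error"
    )
  }

  structure(
    list(
      start = start, end = end, n_months = n,
      interruption_1 = i1, interruption_2 = i2,
      outlier_months = out_idx,
      months = months[, c("month", "t")]
    ),
    class = "study_calendar"
  )
}

#' @export
print.study_calendar <- function(x, ...) {
  cat("<study_calendar> ", x$start, " .. ", x$end,
      " (", x$n_months, " months)\n", sep = "")
  cat("  interruption 1 (restrictions): t = ", x$interruption_1,
      " (", index_to_month(x, x$interruption_1), ")\n", sep = "")
  cat("  interruption 2 (recovery):     t = ", x$interruption_2,
      " (", index_to_month(x, x$interruption_2), ")\n", sep = "")
  if (length(x$outlier_months)) {
    cat("  outlier months: ",
        paste(index_to_month(x, x$outlier_months), collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

# number of months from ISO month `from` to ISO month `to` (signed)
month_diff <- function(from, to) {
  a <- parse_iso_month(from)
  b <- parse_iso_month(to)
  (b$year - a$year) * 12L + (b$mon - a$mon)
}

# ISO month `k` months after ISO month `x` (k may be negative, vectorised in k)
add_months <- function(x, k) {
  a <- parse_iso_month(x)
  m0 <- a$year * 12L + (a$mon - 1L) + as.integer(k)
  sprintf("%04d-%02d", m0 %/% 12L, m0 %% 12L + 1L)
}

#' Convert between ISO months and calendar time indices
#'
#' @param calendar A [study_calendar()].
#' @param month Character vector of ISO `"YYYY-MM"` months.
#' @param t Integer vector of time indices (0 = window start; negative values
#'   address burn-in months before the window).
#' @return `month_to_index()` returns integer indices; `index_to_month()`
#'   returns ISO month strings.
#' @export
month_to_index <- function(calendar, month) {
  vapply(month, function(m) month_diff(calendar$start, m), integer(1),
         USE.NAMES = FALSE)
}

#' @rdname month_to_index
#' @export
index_to_month <- function(calendar, t) {
  add_months(calendar$start, t)
}
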