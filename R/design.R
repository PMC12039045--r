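# Segmented ITSA design matrix: pre-trend, step and slope change at each
# interruption, one Fourier pair for seasonality, outlier dummies, and a
# log-population offset.

#' Build the segmented design matrix for the Poisson ITSA
#'
#' Columns, for month index `t`:
#' * `intercept`;
#' * `time` — the pre-interruption monthly trend, `t`;
#' * `step_restriction` — `1[t >= interruption_1]` (level shift);
#' * `slope_restriction` — `max(0, t - interruption_1 + 1)` (slope change);
#' * `step_recovery`, `slope_recovery` — likewise for `interruption_2`;
#' * `season_sin`, `season_cos` — `sin(2*pi*t/12)`, `cos(2*pi*t/12)`
#'   (further pairs at harmonics `2, 3, ...` when `fourier_pairs > 1`);
#' * one `outlier_YYYY_MM` dummy per calendar outlier month;
#' * optionally `time_sq` (`t^2`) when `quadratic_trend = TRUE`.
#'
#' The default `"inclusive"` slope coding gives the slope-change column the
#' value 1 in the interruption month itself, so the step coefficient is the
#' level shift at that month; `"exclusive"` delays the slope by one month
#' (`max(0, t - interruption)`).
#'
#' The offset is the log of the series denominator (registered or naive
#' population), so exponentiated coefficients act on rates, not counts.
#' The series must be raw: redacted or rounded counts are refused, since
#' disclosure control is for published outputs, never for model input.
#'
#' @param calendar A [study_calendar()].
#' @param series A monthly series tibble (one row per window month, e.g.
#'   from [monthly_prevalent_counts()]), unredacted and unrounded.
#' @param fourier_pairs Number of seasonal harmonic pairs (default 1).
#' @param slope_coding `"inclusive"` (default) or `"exclusive"`, see above.
#' @param quadratic_trend Add a squared-time column (off by default; kept
#'   available because a curvature check is a standard model-fit probe).
#' @return An object of class `itsa_design`: list with the model matrix
#'   `X`, `offset` (log denominator), response `y`, the month table, the
#'   names of the pandemic-type columns (`pandemic_cols`: steps, slopes and
#'   outlier dummies — the columns zeroed in the counterfactual), and the
#'   calendar.
#' @export
build_design_matrix <- function(calendar, series, fourier_pairs = 1,
                                slope_coding = c("inclusive", "exclusive"),
                                quadratic_trend = FALSE) {
  slope_coding <- match.arg(slope_coding)
  series <- dplyr::arrange(series, .data$t)
  if (!identical(as.integer(series$t), calendar$months$t)) {
    rlang::abort(
      "Series must have exactly one row per window month, in order, no gaps",
      class = "rxits_design_error"
    )
  }
  if (any(series$redacted) || any(series$rounded)) {
    rlang::abort(
      "Model input must be raw counts: redacted/rounded series refused",
      class = "rxits_design_error"
    )
  }
  if (any(is.na(series$denominator) | series$denominator <= 0)) {
    rlang::abort("Offset undefined: non-positive denominator",
                 class = "rxits_design_error")
  }

  t <- as.numeric(series$t)
  i1 <- calendar$interruption_1
  i2 <- calendar$interruption_2
  shift <- if (slope_coding == "inclusive") 1 else 0

  X <- cbind(
    intercept = 1,
    time = t,
    step_restriction = as.numeric(t >= i1),
    slope_restriction = pmax(0, t - i1 + shift),
    step_recovery = as.numeric(t >= i2),
    slope_recovery = pmax(0, t - i2 + shift)
  )
  if (quadratic_trend) X <- cbind(X, time_sq = t^2)
  for (h in seq_len(fourier_pairs)) {
    sc <- cbind(sin(2 * pi * h * t / 12), cos(2 * pi * h * t / 12))
    colnames(sc) <- if (h == 1) c("season_sin", "season_cos") else
      paste0(c("season_sin", "season_cos"), h)
    X <- cbind(X, sc)
  }
  for (m in calendar$outlier_months) {
    d <- as.numeric(t == m)
    nm <- paste0("outlier_", gsub("-", "_", index_to_month(calendar, m)))
    X <- cbind(X, d)
    colnames(X)[ncol(X)] <- nm
  }

  pandemic_cols <- c(
    "step_restriction", "slope_restriction", "step_recovery",
    "slope_recovery",
    grep("^outlier_", colnames(X), value = TRUE)
  )

  structure(
    list(
      X = X,
      offset = log(series$denominator),
      y = as.numeric(series$numerator),
      months = series[, c("month", "t")],
      denominator = as.numeric(series$denominator),
      pandemic_cols = pandemic_cols,
      calendar = calendar
    ),
    class = "itsa_design"
  )
}

#' @export
print.itsa_design <- function(x, ...) {
  cat("<itsa_design> ", nrow(x$X), " months x ", ncol(x$X), " columns\n",
      sep = "")
  cat("  columns:", paste(colnames(x$X), collapse = ", "), "\n")
  invisible(x)
}
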