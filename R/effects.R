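# Counterfactual construction and effect summaries: monthly relative
# risks, the geometric-mean average RR with its CI, and per-1000 rate
# differences via the delta method.

# design matrix with pandemic-type columns (steps, slopes, outliers)
# zeroed — the "no interruption" world
counterfactual_matrix <- function(design) {
  Xcf <- design$X
  Xcf[, design$pandemic_cols] <- 0
  Xcf
}

# per-month contrast c_t: x_t restricted to the pandemic columns
# (log RR_t = c_t' beta)
pandemic_contrasts <- function(design) {
  C <- matrix(0, nrow(design$X), ncol(design$X),
              dimnames = dimnames(design$X))
  C[, design$pandemic_cols] <- design$X[, design$pandemic_cols]
  C
}

z_quantile <- function(conf_level) stats::qnorm(1 - (1 - conf_level) / 2)

#' Counterfactual expected rates
#'
#' Projects the fitted model into the no-interruption world: expected
#' counts with the step, slope-change and outlier coefficients' columns
#' set to zero, keeping the intercept, pre-trend and seasonal terms (and
#' the population offset). Months before the first interruption are
#' unchanged by construction.
#'
#' @param fit An `itsa_fit`.
#' @return A tibble per month: `month`, `t`, `observed`, `fitted`,
#'   `counterfactual` (expected counts), `denominator`, and the
#'   corresponding per-1000 `fitted_rate` and `counterfactual_rate`.
#' @export
counterfactual_rates <- function(fit) {
  design <- fit$design
  # both paths evaluated from the coefficient vector, so the identity
  # "equal when pandemic coefficients are zero" holds by construction
  mu_fit <- exp(drop(design$X %*% fit$beta) + design$offset)
  mu_cf <- exp(drop(counterfactual_matrix(design) %*% fit$beta) +
                 design$offset)
  tibble::tibble(
    month = design$months$month,
    t = design$months$t,
    observed = fit$y,
    fitted = mu_fit,
    counterfactual = mu_cf,
    denominator = design$denominator,
    fitted_rate = 1000 * mu_fit / design$denominator,
    counterfactual_rate = 1000 * mu_cf / design$denominator
  )
}

#' Monthly relative risk of fitted versus counterfactual
#'
#' For each month, `RR_t = fitted_t / counterfactual_t = exp(c_t' beta)`
#' where `c_t` keeps only the pandemic-type columns of the design row.
#' The CI uses `Var(log RR_t) = c_t' V c_t` with the HAC covariance `V`.
#' Pre-interruption months have `RR_t = 1` exactly with a zero-width
#' interval, since their contrast is identically zero.
#'
#' @param fit An `itsa_fit`.
#' @param months Optional ISO months or indices to restrict to.
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble: `month`, `t`, `rr`, `ci_low`, `ci_high`.
#' @export
monthly_rr <- function(fit, months = NULL, conf_level = 0.95) {
  design <- fit$design
  C <- pandemic_contrasts(design)
  log_rr <- drop(C %*% fit$beta)
  se <- sqrt(pmax(0, rowSums((C %*% fit$vcov) * C)))
  z <- z_quantile(conf_level)
  out <- tibble::tibble(
    month = design$months$month,
    t = design$months$t,
    rr = exp(log_rr),
    ci_low = exp(log_rr - z * se),
    ci_high = exp(log_rr + z * se)
  )
  if (!is.null(months)) {
    idx <- if (is.character(months)) {
      month_to_index(design$calendar, months)
    } else {
      as.integer(months)
    }
    out <- out[match(idx, out$t), ]
  }
  out
}

#' Average relative risk over a window (geometric mean, with CI)
#'
#' The overall post-interruption effect: the geometric mean of the monthly
#' fitted/counterfactual ratios over the window. Because the geometric
#' mean of `exp(c_t' beta)` is `exp(mean(c_t)' beta)`, the log of the
#' average RR is a linear functional of the coefficients; its variance is
#' `dbar' V dbar` with `dbar = mean(c_t)` and the CI is the exact
#' normal-theory interval for that functional under the HAC covariance.
#' A single-month window reduces to [monthly_rr()] for that month.
#'
#' The window must be stated explicitly when it matters: the default runs
#' from the first interruption to the end of the study, and outlier months
#' (whose dummies contribute to their contrasts) are included unless
#' `exclude_outliers = TRUE`.
#'
#' @param fit An `itsa_fit`.
#' @param window Length-2 vector (ISO months or indices), inclusive;
#'   default `c(interruption_1, last month)`.
#' @param exclude_outliers Drop calendar outlier months from the average.
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `window_start`, `window_end`, `n_months`,
#'   `rr`, `ci_low`, `ci_high`.
#' @export
average_rr <- function(fit, window = NULL, exclude_outliers = FALSE,
                       conf_level = 0.95) {
  design <- fit$design
  cal <- design$calendar
  if (is.null(window)) {
    window <- c(cal$interruption_1, cal$n_months - 1L)
  } else if (is.character(window)) {
    window <- month_to_index(cal, window)
  }
  if (length(window) != 2 || window[2] < window[1] ||
      window[1] < 0 || window[2] > cal$n_months - 1L) {
    rlang::abort("Averaging window must be an ordered pair inside the study window",
                 class = "rxits_effects_error")
  }
  ts <- seq(window[1], window[2])
  if (exclude_outliers) ts <- setdiff(ts, cal$outlier_months)
  if (length(ts) == 0) {
    rlang::abort("Empty averaging window", class = "rxits_effects_error")
  }
  C <- pandemic_contrasts(design)
  dbar <- colMeans(C[match(ts, design$months$t), , drop = FALSE])
  log_a <- sum(dbar * fit$beta)
  se <- sqrt(max(0, drop(dbar %*% fit$vcov %*% dbar)))
  z <- z_quantile(conf_level)
  tibble::tibble(
    window_start = index_to_month(cal, min(ts)),
    window_end = index_to_month(cal, max(ts)),
    n_months = length(ts),
    rr = exp(log_a),
    ci_low = exp(log_a - z * se),
    ci_high = exp(log_a + z * se)
  )
}

#' Rate difference between fitted and counterfactual at a month
#'
#' `Delta_t = (fitted_t - counterfactual_t) / N_t * 1000`, the per-1000
#' excess (or deficit) attributable to the interruptions at a named month
#' — conventionally the last month of the study. The CI comes from the
#' delta method on `g(beta) = (exp(x_t' beta) - exp(x_cf,t' beta)) *
#' exp(offset_t) / N_t * 1000`, whose gradient is
#' `(mu_t x_t - mu_cf,t x_cf,t) / N_t * 1000`, with the HAC covariance.
#'
#' @param fit An `itsa_fit`.
#' @param month ISO month or index; default the last study month.
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `month`, `rate_difference`, `ci_low`,
#'   `ci_high` (per 1000 patients).
#' @export
rate_difference <- function(fit, month = NULL, conf_level = 0.95) {
  design <- fit$design
  cal <- design$calendar
  t_idx <- if (is.null(month)) {
    cal$n_months - 1L
  } else if (is.character(month)) {
    month_to_index(cal, month)
  } else {
    as.integer(month)
  }
  i <- match(t_idx, design$months$t)
  if (is.na(i)) {
    rlang::abort("month outside the fitted window",
                 class = "rxits_effects_error")
  }
  x <- design$X[i, ]
  x_cf <- counterfactual_matrix(design)[i, ]
  n_t <- design$denominator[i]
  mu <- exp(sum(x * fit$beta) + design$offset[i])
  mu_cf <- exp(sum(x_cf * fit$beta) + design$offset[i])
  delta <- (mu - mu_cf) / n_t * 1000
  grad <- (mu * x - mu_cf * x_cf) / n_t * 1000
  se <- sqrt(max(0, drop(grad %*% fit$vcov %*% grad)))
  z <- z_quantile(conf_level)
  tibble::tibble(
    month = index_to_month(cal, t_idx),
    rate_difference = delta,
    ci_low = delta - z * se,
    ci_high = delta + z * se
  )
}

#' Fit independent models per subgroup
#'
#' Fits a fully separate segmented Poisson model to each subgroup's
#' monthly series (no interaction terms: one model per subgroup, as when
#' each demographic stratum acts as its own population). A failure in one
#' subgroup — e.g. an all-zero series — is captured and reported without
#' aborting the others.
#'
#' @param series_by_subgroup A monthly series tibble containing several
#'   subgroups (column `subgroup`), e.g. rows from
#'   [monthly_prevalent_counts()] stacked over flags.
#' @param calendar A [study_calendar()].
#' @param window Averaging window passed to [average_rr()].
#' @param lag,fourier_pairs Passed to the design/fit.
#' @return A tibble with one row per subgroup: `subgroup`, `fit` (list
#'   column of `itsa_fit` or `NULL`), `error` (message or `NA`), and the
#'   unnested effect summaries `rr`, `ci_low`, `ci_high`,
#'   `rate_diff_last_month`, `rate_diff_ci_low`, `rate_diff_ci_high`.
#' @export
fit_subgroup_models <- function(series_by_subgroup, calendar, window = NULL,
                                lag = 2, fourier_pairs = 1) {
  groups <- split(series_by_subgroup,
                  series_by_subgroup$subgroup)
  purrr::imap(groups, function(ser, name) {
    res <- tryCatch({
      design <- build_design_matrix(calendar, ser,
                                    fourier_pairs = fourier_pairs)
      fit <- fit_poisson_itsa(design, lag = lag)
      avg <- average_rr(fit, window = window)
      rd <- rate_difference(fit)
      tibble::tibble(
        subgroup = name, fit = list(fit), error = NA_character_,
        rr = avg$rr, ci_low = avg$ci_low, ci_high = avg$ci_high,
        rate_diff_last_month = rd$rate_difference,
        rate_diff_ci_low = rd$ci_low, rate_diff_ci_high = rd$ci_high
      )
    }, error = function(e) {
      tibble::tibble(
        subgroup = name, fit = list(NULL), error = conditionMessage(e),
        rr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        rate_diff_last_month = NA_real_,
        rate_diff_ci_low = NA_real_, rate_diff_ci_high = NA_real_
      )
    })
    res
  }) |>
    purrr::list_rbind()
}
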