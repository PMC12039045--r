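# broom-style methods and plotting for fitted ITSA objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted ITSA
#'
#' One row per coefficient, on the log scale by default, with HAC standard
#' errors and normal-quantile confidence intervals. With
#' `exponentiate = TRUE` estimates and intervals are rate ratios.
#'
#' @param x An `itsa_fit`.
#' @param conf_level Confidence level (default 0.95).
#' @param exponentiate Report `exp(beta)` instead of `beta`.
#' @param ... Unused.
#' @return A tibble: `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, `conf.low`, `conf.high`.
#' @export
tidy.itsa_fit <- function(x, conf_level = 0.95, exponentiate = FALSE, ...) {
  se <- sqrt(diag(x$vcov))
  z <- x$beta / se
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- tibble::tibble(
    term = names(x$beta),
    estimate = unname(x$beta),
    std.error = unname(se),
    statistic = unname(z),
    p.value = 2 * stats::pnorm(-abs(unname(z))),
    conf.low = unname(x$beta - q * se),
    conf.high = unname(x$beta + q * se)
  )
  if (exponentiate) {
    out$estimate <- exp(out$estimate)
    out$conf.low <- exp(out$conf.low)
    out$conf.high <- exp(out$conf.high)
  }
  out
}

#' Glance at a fitted ITSA
#'
#' @param x An `itsa_fit`.
#' @param ... Unused.
#' @return One-row tibble: `nobs`, `df`, `log_likelihood`, `deviance`,
#'   `converged`, `n_iterations`, `nw_lag`.
#' @export
glance.itsa_fit <- function(x, ...) {
  y <- x$y
  mu <- x$fitted
  sat <- sum(stats::dpois(y, pmax(y, 1e-12), log = TRUE) * (y > 0))
  tibble::tibble(
    nobs = length(y),
    df = length(x$beta),
    log_likelihood = x$log_likelihood,
    deviance = 2 * (sat - x$log_likelihood),
    converged = x$converged,
    n_iterations = x$n_iterations,
    nw_lag = x$lag
  )
}

#' Plot observed, fitted and counterfactual rates
#'
#' The standard ITSA figure: observed monthly rates per 1000 as points,
#' the model-fitted rate as a solid line, the no-interruption
#' counterfactual as a dashed line, with vertical dotted lines at the two
#' interruption points.
#'
#' @param object An `itsa_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.itsa_fit <- function(object, ...) {
  cf <- counterfactual_rates(object)
  cf$observed_rate <- 1000 * cf$observed / cf$denominator
  cal <- object$design$calendar
  ggplot2::ggplot(cf, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed_rate),
                        colour = "grey30", size = 1) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted_rate),
                       colour = "#2166ac") +
    ggplot2::geom_line(ggplot2::aes(y = .data$counterfactual_rate),
                       colour = "#b2182b", linetype = "dashed") +
    ggplot2::geom_vline(xintercept = c(cal$interruption_1,
                                       cal$interruption_2),
                        linetype = "dotted") +
    ggplot2::labs(x = "Month of study", y = "Rate per 1000 patients",
                  title = "Observed, fitted and counterfactual rates") +
    ggplot2::theme_minimal()
}

#' Forest-style plot of subgroup average relative risks
#'
#' @param subgroup_effects Output of [fit_subgroup_models()].
#' @return A ggplot object: point estimates with CI bars by subgroup,
#'   reference line at RR 1.
#' @export
plot_subgroup_rr <- function(subgroup_effects) {
  d <- subgroup_effects[!is.na(subgroup_effects$rr), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rr, y = .data$subgroup)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dotted") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      height = 0.2
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Average relative risk vs counterfactual",
                  y = NULL) +
    ggplot2::theme_minimal()
}
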