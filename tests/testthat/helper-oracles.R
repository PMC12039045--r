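# Independent oracles and fixture builders shared across tests. These are
# deliberately naive reimplementations (loops over patients and months,
# generic optimisers) kept separate from the package's own code paths.

# Brute-force prevalent counts: loop over every (month, patient) pair.
brute_prevalent <- function(events, patients, calendar, subgroup = "all") {
  if (subgroup != "all") {
    patients <- patients[patients[[subgroup]] == 1, , drop = FALSE]
  }
  ts <- calendar$months$t
  num <- den <- integer(length(ts))
  for (k in seq_along(ts)) {
    t <- ts[k]
    reg <- patients$patient_id[
      patients$reg_start <= t &
        (is.na(patients$reg_end) | t < patients$reg_end)
    ]
    den[k] <- length(reg)
    prescribed <- unique(events$patient_id[events$month == t])
    num[k] <- length(intersect(prescribed, reg))
  }
  tibble::tibble(t = ts, numerator = num, denominator = den)
}

# Brute-force new counts: exhaustive washout scan per (patient, month).
brute_new <- function(events, patients, calendar, subgroup = "all",
                      washout = 24) {
  if (subgroup != "all") {
    patients <- patients[patients[[subgroup]] == 1, , drop = FALSE]
  }
  ts <- calendar$months$t
  num <- den <- integer(length(ts))
  ev_by_pat <- split(events$month, events$patient_id)
  for (k in seq_along(ts)) {
    t <- ts[k]
    for (i in seq_len(nrow(patients))) {
      pid <- patients$patient_id[i]
      if (!(patients$reg_start[i] <= t &&
            (is.na(patients$reg_end[i]) || t < patients$reg_end[i]))) next
      months_i <- ev_by_pat[[pid]]
      naive <- !any(months_i >= t - washout & months_i <= t - 1)
      if (naive) {
        den[k] <- den[k] + 1L
        if (any(months_i == t)) num[k] <- num[k] + 1L
      }
    }
  }
  tibble::tibble(t = ts, numerator = num, denominator = den)
}

# Random patient/event fixture at toy scale, with history deep enough for
# the washout and some closed registration intervals.
make_random_cohort <- function(n_patients = 200, calendar = study_calendar(),
                               seed = 1, event_rate = 0.08) {
  withr::with_seed(seed, {
    reg_start <- sample(c(rep(-30L, n_patients * 0.7),
                          sample(-30:40, n_patients * 0.3, replace = TRUE)))
    reg_start <- reg_start[seq_len(n_patients)]
    reg_end <- ifelse(stats::runif(n_patients) < 0.15,
                      reg_start + sample(5:60, n_patients, replace = TRUE),
                      NA_integer_)
    patients <- tibble::tibble(
      patient_id = sprintf("r%04d", seq_len(n_patients)),
      reg_start = as.integer(reg_start),
      reg_end = as.integer(reg_end),
      flag_a = as.integer(stats::runif(n_patients) < 0.3)
    )
    ev <- lapply(seq_len(n_patients), function(i) {
      lo <- patients$reg_start[i]
      hi <- min(calendar$n_months - 1L,
                ifelse(is.na(patients$reg_end[i]), calendar$n_months - 1L,
                       patients$reg_end[i] - 1L))
      if (hi < lo) return(NULL)
      m <- lo:hi
      m <- m[stats::runif(length(m)) < event_rate]
      if (!length(m)) return(NULL)
      tibble::tibble(
        patient_id = patients$patient_id[i],
        month = as.integer(m),
        drug_class = sample(c("ssri", "tricyclic", "maoi", "other"),
                            length(m), replace = TRUE)
      )
    })
    list(patients = patients, events = dplyr::bind_rows(ev))
  })
}

# Independent Poisson maximiser: BFGS on the (negative) log-likelihood
# with analytic gradient, polished by Newton steps with a *numerical*
# Hessian (finite differences of the gradient) — no IRLS machinery.
bfgs_poisson <- function(X, y, offset) {
  nll <- function(b) {
    eta <- drop(X %*% b) + offset
    sum(exp(eta)) - sum(y * eta)
  }
  gr <- function(b) {
    mu <- exp(drop(X %*% b) + offset)
    -drop(crossprod(X, y - mu))
  }
  start <- numeric(ncol(X))
  start[1] <- log(max(sum(y), 0.5) / sum(exp(offset)))
  b <- stats::optim(start, nll, gr, method = "BFGS",
                    control = list(maxit = 2000, reltol = 1e-14))$par
  for (k in 1:20) {
    g <- gr(b)
    if (max(abs(g)) < 1e-11 * max(1, sum(y))) break
    H <- stats::optimHess(b, nll, gr)
    b <- b - solve(H, g)
  }
  b
}

# HC0 sandwich computed directly (no Bartlett terms).
hc0_sandwich <- function(X, y, mu) {
  u <- X * (y - mu)
  B <- solve(crossprod(X, X * mu))
  B %*% crossprod(u) %*% B
}

# Minimal hand-built design object (for closed-form and tiny fixtures).
manual_design <- function(X, y, offset, calendar = NULL,
                          pandemic_cols = character(0)) {
  n <- nrow(X)
  structure(
    list(
      X = X, offset = offset, y = y,
      months = tibble::tibble(month = sprintf("m%02d", seq_len(n)),
                              t = seq_len(n) - 1L),
      denominator = exp(offset),
      pandemic_cols = pandemic_cols,
      calendar = calendar
    ),
    class = "itsa_design"
  )
}

# Draws from N(beta, V) for parametric-bootstrap oracles.
draw_mvnorm <- function(n, mean, sigma, seed = 1) {
  withr::with_seed(seed, {
    L <- chol(sigma + diag(1e-12, nrow(sigma)))
    z <- matrix(stats::rnorm(n * length(mean)), n)
    sweep(z %*% L, 2, mean, `+`)
  })
}

# A raw prevalent-style series tibble from bare vectors.
series_from_counts <- function(calendar, numerator, denominator,
                               outcome = "prevalent", subgroup = "all") {
  tibble::tibble(
    month = calendar$months$month,
    t = calendar$months$t,
    subgroup = subgroup,
    outcome = outcome,
    numerator = as.integer(numerator),
    denominator = as.integer(denominator),
    redacted = FALSE,
    rounded = FALSE
  )
}
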