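#' Simulate right-censored survival records
#'
#' Event times are drawn by inverse-CDF sampling from the named parametric
#' family. Censoring is administrative (a fixed cut-off) and/or random:
#' independent exponential censoring whose rate is solved numerically so
#' the expected fraction of subjects censored by the random mechanism
#' (before the administrative cut-off is applied) equals
#' `random_censor_rate`.
#'
#' @param n Number of subjects.
#' @param family One of [survival_families()].
#' @param params Named parameters, as in [parametric_fit()].
#' @param administrative_censor_time Cut-off in months (`Inf` for none).
#' @param random_censor_rate Target random-censoring fraction in `[0, 1)`.
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble of survival records (`time_months`, `event`).
#' @export
#' @examples
#' simulate_ipd(100, "loglogistic", c(scale = 17.43, shape = 1.489),
#'              administrative_censor_time = 30, seed = 1)
simulate_ipd <- function(n, family, params,
                         administrative_censor_time = Inf,
                         random_censor_rate = 0, seed = NULL) {
  stopifnot(n >= 1, n == round(n))
  family <- check_family(family)
  params <- check_family_params(family, params)
  if (random_censor_rate < 0 || random_censor_rate >= 1) {
    abort("`random_censor_rate` must lie in [0, 1)")
  }
  if (administrative_censor_time <= 0) {
    abort("`administrative_censor_time` must be positive")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  t_event <- family_quantile(family, params, runif(n))
  t_event <- pmax(t_event, .Machine$double.eps)
  time <- t_event
  event <- rep(1, n)

  if (random_censor_rate > 0) {
    rate <- censor_rate_for(family, params, random_censor_rate)
    t_cens <- stats::rexp(n, rate = rate)
    censored <- t_cens < time
    time[censored] <- t_cens[censored]
    event[censored] <- 0
  }
  over <- time > administrative_censor_time
  time[over] <- administrative_censor_time
  event[over] <- 0

  tibble::tibble(time_months = time, event = event)
}

# exponential censoring rate lambda with P(C < T) = target, solved via
# P(C < T) = integral of S_T(t) * lambda * exp(-lambda t) dt
censor_rate_for <- function(family, params, target) {
  frac <- function(lambda) {
    integrate(
      function(t) family_survival(family, params, t) * lambda * exp(-lambda * t),
      lower = 0, upper = Inf, rel.tol = 1e-8
    )$value
  }
  uniroot(function(l) frac(l) - target,
          interval = c(1e-8, 1e4), tol = 1e-10)$root
}

#' Render survival records as a digitized Kaplan-Meier fixture
#'
#' Computes the product-limit curve of the records, samples its step
#' function on a regular time grid (emulating point selection from a
#' published figure) and tabulates the number at risk at regular interval
#' boundaries. The result satisfies every [digitized_km()] invariant and
#' parses through [read_digitized_curve()] after a round trip to CSV.
#'
#' @inheritParams km_estimate
#' @param coord_grid_step Grid spacing of the sampled coordinates, months.
#' @param risk_interval Spacing of the number-at-risk table, months.
#' @param arm_label,endpoint Labels for the resulting curve.
#' @param with_total_events Record the total event count (default `TRUE`).
#' @return A `digitized_km` object.
#' @export
make_digitized <- function(records, coord_grid_step = 0.1, risk_interval = 3,
                           arm_label = "arm", endpoint = c("OS", "PFS"),
                           with_total_events = TRUE) {
  endpoint <- match.arg(endpoint)
  records <- as_survival_records(records)
  if (coord_grid_step <= 0) abort("`coord_grid_step` must be positive")
  if (risk_interval <= 0) abort("`risk_interval` must be positive")
  km <- km_estimate(records)
  t_max <- max(records$time_months)
  grid <- seq(0, t_max, by = coord_grid_step)
  if (grid[length(grid)] < t_max) grid <- c(grid, t_max)
  coords <- tibble::tibble(
    time_months = grid,
    survival = km_survival(km, grid)
  )
  risk_times <- seq(0, t_max, by = risk_interval)
  risk <- tibble::tibble(
    time_months = risk_times,
    n_at_risk = vapply(risk_times, function(b) {
      sum(records$time_months >= b)
    }, numeric(1))
  )
  digitized_km(
    coords, risk, arm_label = arm_label, endpoint = endpoint,
    total_events = if (with_total_events) sum(records$event) else NULL
  )
}

#' Write a synthetic two-arm trial as digitized-curve fixtures
#'
#' Simulates a miniature two-arm trial (2:1 allocation, log-logistic OS and
#' PFS event times from the reference configuration's parameters,
#' administrative censoring) and writes each arm/endpoint as the CSV pair
#' consumed by [read_digitized_curve()]. This emulates the raw-material
#' pathway - digitized published curves - with no external download.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n Total subjects across both arms (default 805, allocated 2:1).
#' @param administrative_censor_time Follow-up cut-off, months.
#' @return Invisibly, a tibble listing the written files (`arm`,
#'   `endpoint`, `coords_path`, `risk_path`, `total_events`).
#' @export
make_fixtures <- function(out_dir, seed = 20240718, n = 805,
                          administrative_censor_time = 34) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- reference_config()
  arms <- list(cfg$intervention, cfg$comparator)
  n_arm <- c(round(n * 2 / 3), n - round(n * 2 / 3))
  set.seed(as.integer(seed))
  rows <- list()
  for (i in seq_along(arms)) {
    arm <- arms[[i]]
    for (ep in c("OS", "PFS")) {
      fit <- if (ep == "OS") arm$os_fit else arm$pfs_fit
      rec <- simulate_ipd(
        n_arm[i], fit$family, fit$params,
        administrative_censor_time = administrative_censor_time
      )
      curve <- make_digitized(rec, coord_grid_step = 0.1, risk_interval = 3,
                              arm_label = arm$name, endpoint = ep)
      stem <- file.path(out_dir, paste0(arm$name, "_", tolower(ep)))
      write_digitized_curve(curve, paste0(stem, "_coords.csv"),
                            paste0(stem, "_risk.csv"))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        arm = arm$name, endpoint = ep,
        coords_path = paste0(stem, "_coords.csv"),
        risk_path = paste0(stem, "_risk.csv"),
        total_events = curve$total_events
      )
    }
  }
  invisible(dplyr::bind_rows(rows))
}
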