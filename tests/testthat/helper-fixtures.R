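# shared fixtures, built in code

# tiny exact step curve: 2 subjects, events at 1 and 2 months
toy_curve <- function() {
  digitized_km(
    coords = data.frame(time_months = c(0, 1, 2), survival = c(1, 0.5, 0)),
    risk_table = data.frame(time_months = 0, n_at_risk = 2)
  )
}

# brute-force product-limit estimator over explicit risk sets,
# independent of survival::survfit
brute_force_km <- function(records) {
  times <- sort(unique(records$time_months[records$event == 1]))
  surv <- numeric(length(times))
  s <- 1
  for (i in seq_along(times)) {
    tt <- times[i]
    # events precede censorings at ties: at risk = everyone with time >= tt
    at_risk <- sum(records$time_months >= tt)
    d <- sum(records$time_months == tt & records$event == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  list(time = times, survival = surv)
}

ref_loglogistic_os <- function() {
  parametric_fit("loglogistic", c(scale = 17.43252, shape = 1.48925))
}

# small parameter sets used for per-family simulation checks
family_test_params <- function() {
  list(
    exponential = c(rate = 0.08),
    weibull = c(shape = 1.3, scale = 12),
    gamma = c(shape = 2, rate = 0.15),
    generalized_gamma = c(mu = 2.2, sigma = 0.8, Q = 0.5),
    gompertz = c(shape = 0.05, rate = 0.04),
    loglogistic = c(scale = 10, shape = 1.8),
    lognormal = c(meanlog = 2.3, sdlog = 0.7)
  )
}
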