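#' Product-limit (Kaplan-Meier) estimate of survival records
#'
#' Thin wrapper around [survival::survfit()] returning a tidy step table
#' and the median survival time. Ties between events and censorings at the
#' same time are handled events-first (the standard KM convention).
#'
#' @param records Survival records, see [as_survival_records()].
#' @return An object of class `km_fit`: a list with `steps` (tibble
#'   `time_months`, `n_risk`, `n_event`, `n_censor`, `survival`), `median`
#'   (earliest time with survival <= 0.5, `NA` if never reached) and `n`.
#' @export
km_estimate <- function(records) {
  records <- as_survival_records(records)
  sf <- survival::survfit(
    survival::Surv(time_months, event) ~ 1,
    data = records, conf.type = "none"
  )
  steps <- tibble::tibble(
    time_months = sf$time,
    n_risk = sf$n.risk,
    n_event = sf$n.event,
    n_censor = sf$n.censor,
    survival = sf$surv
  )
  med <- steps$time_months[steps$survival <= 0.5]
  structure(
    list(
      steps = steps,
      median = if (length(med)) min(med) else NA_real_,
      n = nrow(records)
    ),
    class = "km_fit"
  )
}

#' @export
print.km_fit <- function(x, ...) {
  cat("<km_fit> n = ", x$n, ", events = ", sum(x$steps$n_event),
      ", median = ",
      if (is.na(x$median)) "not reached" else format(x$median, digits = 4),
      " months\n", sep = "")
  invisible(x)
}

#' Evaluate a KM step function at arbitrary times
#'
#' @param km A `km_fit` object.
#' @param t Times in months (vectorised); survival is 1 before the first
#'   event and right-continuous at steps.
#' @return Survival probabilities.
#' @export
km_survival <- function(km, t) {
  stopifnot(inherits(km, "km_fit"))
  if (any(t < 0)) abort("`t` must be non-negative")
  f <- stats::stepfun(km$steps$time_months, c(1, km$steps$survival),
                      right = FALSE)
  f(t)
}

#' @export
tidy.km_fit <- function(x, ...) x$steps

#' @export
glance.km_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    events = sum(x$steps$n_event),
    median = x$median
  )
}

#' @export
autoplot.km_fit <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(time_months = 0, survival = 1),
    object$steps[c("time_months", "survival")]
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time_months, .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability") +
    ggplot2::theme_minimal()
}
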