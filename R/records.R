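#' Validate a table of right-censored survival records
#'
#' A survival record is one pseudo-subject: a follow-up time in months and an
#' event indicator (1 = event, 0 = right-censored). All reconstruction,
#' fitting and simulation functions exchange records in this shape.
#'
#' @param records A data frame with columns `time_months` (finite, positive)
#'   and `event` (0 or 1).
#' @return A validated tibble with columns `time_months` and `event`.
#' @export
as_survival_records <- function(records) {
  if (!is.data.frame(records)) abort("`records` must be a data frame")
  need <- c("time_months", "event")
  if (!all(need %in% names(records))) {
    abort("`records` must have columns `time_months` and `event`")
  }
  out <- tibble::as_tibble(records[need])
  if (nrow(out) == 0L) abort("`records` is empty")
  if (any(!is.finite(out$time_months)) || any(out$time_months <= 0)) {
    abort("`time_months` must be finite and strictly positive")
  }
  if (!all(out$event %in% c(0, 1))) {
    abort("`event` must be 0 (censored) or 1 (event)")
  }
  out
}
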