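#' Construct a digitized Kaplan-Meier curve object
#'
#' Bundles the point-selected step-curve coordinates of a published KM plot
#' with its number-at-risk table, the two ingredients the Guyot
#' reconstruction needs. Coordinates are treated as exact samples of the
#' step function; no smoothing is applied.
#'
#' @param coords Data frame with columns `time_months`, `survival`: the
#'   digitized curve coordinates. Times must be strictly increasing and
#'   survival non-increasing (small digitization rises up to `monotone_tol`
#'   are flattened). A `(0, 1)` anchor is prepended when absent.
#' @param risk_table Data frame with columns `time_months`, `n_at_risk`: the
#'   published number-at-risk row. Times strictly increasing, counts
#'   non-increasing.
#' @param arm_label,endpoint Labels carried through to outputs; `endpoint`
#'   is `"OS"` or `"PFS"`.
#' @param total_events Optional total event count for the arm, used by
#'   [reconstruct_ipd()] to anchor the final interval.
#' @param monotone_tol Largest survival rise between consecutive coordinates
#'   attributed to digitization noise and flattened; larger rises error.
#' @return An object of class `digitized_km`.
#' @seealso [read_digitized_curve()], [reconstruct_ipd()], [make_digitized()]
#' @export
digitized_km <- function(coords, risk_table, arm_label = "arm",
                         endpoint = c("OS", "PFS"), total_events = NULL,
                         monotone_tol = 0.005) {
  endpoint <- match.arg(endpoint)
  if (!is.data.frame(coords) ||
      !all(c("time_months", "survival") %in% names(coords))) {
    abort("`coords` must have columns `time_months` and `survival`")
  }
  if (!is.data.frame(risk_table) ||
      !all(c("time_months", "n_at_risk") %in% names(risk_table))) {
    abort("`risk_table` must have columns `time_months` and `n_at_risk`")
  }
  coords <- tibble::as_tibble(coords[c("time_months", "survival")])
  risk_table <- tibble::as_tibble(risk_table[c("time_months", "n_at_risk")])
  if (nrow(risk_table) == 0L) abort("risk table is empty")
  if (nrow(coords) == 0L) abort("coordinate table is empty")
  if (any(!is.finite(coords$time_months)) || any(!is.finite(coords$survival))) {
    abort("coordinates must be finite")
  }

  coords <- dplyr::arrange(coords, .data$time_months)
  if (anyDuplicated(coords$time_months)) {
    abort(paste0("duplicate coordinate time at row ",
                 which(duplicated(coords$time_months))[1]))
  }
  if (coords$time_months[1] < 0) abort("coordinate times must be >= 0")
  if (coords$time_months[1] > 0) {
    coords <- dplyr::bind_rows(
      tibble::tibble(time_months = 0, survival = 1), coords
    )
  }
  if (coords$survival[1] > 1 || coords$survival[1] < 1 - 0.02) {
    abort(paste0("survival at time 0 must be within 0.02 of 1, got ",
                 signif(coords$survival[1], 4)))
  }
  if (any(coords$survival < 0)) {
    abort(paste0("negative survival at row ", which(coords$survival < 0)[1]))
  }
  rises <- diff(coords$survival)
  if (any(rises > monotone_tol)) {
    bad <- which(rises > monotone_tol)[1] + 1L
    abort(paste0(
      "survival rises from ", signif(coords$survival[bad - 1L], 4), " to ",
      signif(coords$survival[bad], 4), " at coordinate row ", bad,
      "; beyond digitization tolerance ", monotone_tol
    ))
  }
  coords$survival <- pmin(1, cummin(coords$survival))

  rt <- risk_table
  if (any(diff(rt$time_months) <= 0)) {
    abort(paste0("risk-table times must be strictly increasing (row ",
                 which(diff(rt$time_months) <= 0)[1] + 1L, ")"))
  }
  if (any(rt$n_at_risk < 0) || any(rt$n_at_risk != round(rt$n_at_risk))) {
    abort("`n_at_risk` must be non-negative integers")
  }
  if (any(diff(rt$n_at_risk) > 0)) {
    abort(paste0("number at risk increases over time at risk-table row ",
                 which(diff(rt$n_at_risk) > 0)[1] + 1L))
  }
  if (rt$n_at_risk[1] < 1) abort("initial number at risk must be >= 1")
  if (rt$time_months[1] > coords$time_months[1]) {
    abort("risk table must start at or before the first coordinate time")
  }
  if (!is.null(total_events)) {
    if (length(total_events) != 1L || !is.finite(total_events) ||
        total_events < 0 || total_events != round(total_events)) {
      abort("`total_events` must be a single non-negative integer")
    }
    total_events <- as.integer(total_events)
  }

  structure(
    list(
      arm_label = as.character(arm_label),
      endpoint = endpoint,
      coords = coords,
      risk_table = rt,
      total_events = total_events
    ),
    class = "digitized_km"
  )
}

#' @export
print.digitized_km <- function(x, ...) {
  cat("<digitized_km> ", x$arm_label, " / ", x$endpoint, "\n", sep = "")
  cat("  ", nrow(x$coords), " coordinates over [",
      min(x$coords$time_months), ", ", max(x$coords$time_months),
      "] months\n", sep = "")
  cat("  ", nrow(x$risk_table), " risk intervals, initial n at risk ",
      x$risk_table$n_at_risk[1], "\n", sep = "")
  if (!is.null(x$total_events)) {
    cat("  total events: ", x$total_events, "\n", sep = "")
  }
  invisible(x)
}

#' Read a digitized Kaplan-Meier curve from CSV files
#'
#' Reads the curve-coordinate CSV (header `time_months,survival`) and the
#' companion risk-table CSV (header `time_months,n_at_risk`), validates both
#' and returns a [digitized_km()] object.
#'
#' @param coords_path Path to the coordinate CSV.
#' @param risk_path Path to the number-at-risk CSV.
#' @inheritParams digitized_km
#' @return A `digitized_km` object.
#' @export
read_digitized_curve <- function(coords_path, risk_path, arm_label = "arm",
                                 endpoint = c("OS", "PFS"),
                                 total_events = NULL, monotone_tol = 0.005) {
  for (p in c(coords_path, risk_path)) {
    if (!file.exists(p)) abort(paste0("file not found: ", p))
  }
  coords <- read.csv(coords_path)
  if (!all(c("time_months", "survival") %in% names(coords))) {
    abort(paste0(coords_path,
                 ": expected header `time_months,survival`, got `",
                 paste(names(coords), collapse = ","), "`"))
  }
  risk <- read.csv(risk_path)
  if (!all(c("time_months", "n_at_risk") %in% names(risk))) {
    abort(paste0(risk_path,
                 ": expected header `time_months,n_at_risk`, got `",
                 paste(names(risk), collapse = ","), "`"))
  }
  for (col in c("time_months", "survival")) {
    bad <- which(!is.finite(as.numeric(coords[[col]])))
    if (length(bad)) {
      abort(paste0(coords_path, ": non-numeric `", col, "` at row ", bad[1]))
    }
  }
  digitized_km(coords, risk, arm_label = arm_label, endpoint = endpoint,
               total_events = total_events, monotone_tol = monotone_tol)
}

#' Write a digitized curve to the CSV pair consumed by [read_digitized_curve()]
#'
#' @param curve A `digitized_km` object.
#' @param coords_path,risk_path Destination CSV paths.
#' @return The `curve`, invisibly.
#' @export
write_digitized_curve <- function(curve, coords_path, risk_path) {
  stopifnot(inherits(curve, "digitized_km"))
  write.csv(curve$coords, coords_path, row.names = FALSE)
  write.csv(curve$risk_table, risk_path, row.names = FALSE)
  invisible(curve)
}
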