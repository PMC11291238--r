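#' Construct a parametric survival fit from known parameters
#'
#' Used for the pre-fitted pathway, where published scale/shape parameters
#' are taken as given rather than re-estimated. The log-logistic
#' parameterization is \eqn{S(t) = 1 / (1 + (t/\alpha)^\beta)} with scale
#' \eqn{\alpha} (equal to the median, in months) and dimensionless shape
#' \eqn{\beta}.
#'
#' @param family One of [survival_families()].
#' @param params Named numeric vector of the family's parameters (for
#'   `"loglogistic"`: `scale`, `shape`).
#' @return A `parametric_fit` object.
#' @export
#' @examples
#' fit <- parametric_fit("loglogistic", c(scale = 17.43252, shape = 1.48925))
#' survival_at(fit, c(0, 12, 17.43252))
parametric_fit <- function(family, params) {
  family <- check_family(family)
  params <- check_family_params(family, params)
  structure(
    list(
      family = family,
      params = params,
      loglik = NA_real_,
      aic = NA_real_,
      bic = NA_real_,
      n = NA_integer_,
      n_events = NA_integer_,
      converged = NA,
      source = "specified"
    ),
    class = "parametric_fit"
  )
}

#' Fit one parametric family to right-censored survival records
#'
#' Maximum-likelihood estimation of the right-censored log-likelihood
#' \eqn{\sum_{events} \log f(t_i) + \sum_{censored} \log S(t_i)} via
#' [flexsurv::flexsurvreg()]. AIC and BIC are recomputed from the returned
#' log-likelihood as \eqn{2k - 2\ell} and \eqn{k \log n - 2\ell}, with
#' \eqn{k} the number of free parameters and \eqn{n} the record count.
#'
#' @inheritParams km_estimate
#' @param family One of [survival_families()].
#' @return A `parametric_fit` object with estimates, `loglik`, `aic`, `bic`.
#' @export
fit_family <- function(records, family) {
  records <- as_survival_records(records)
  family <- check_family(family)
  if (sum(records$event) < 1) {
    abort("all records are censored; the likelihood has no maximum")
  }
  fit <- tryCatch(
    flexsurv::flexsurvreg(
      survival::Surv(time_months, event) ~ 1,
      data = records, dist = .flexsurv_dist[[family]]
    ),
    error = function(e) {
      abort(paste0("fit of family '", family, "' failed to converge: ",
                   conditionMessage(e)))
    }
  )
  est <- fit$res[, "est"]
  params <- switch(family,
    loglogistic = c(scale = unname(est["scale"]), shape = unname(est["shape"])),
    setNames(as.numeric(est), rownames(fit$res))
  )
  params <- check_family_params(family, params)
  k <- length(params)
  ll <- as.numeric(stats::logLik(fit))
  n <- nrow(records)
  structure(
    list(
      family = family,
      params = params,
      loglik = ll,
      aic = 2 * k - 2 * ll,
      bic = k * log(n) - 2 * ll,
      n = n,
      n_events = as.integer(sum(records$event)),
      converged = TRUE,
      source = "mle"
    ),
    class = "parametric_fit"
  )
}

#' Fit several parametric families to the same records
#'
#' @inheritParams fit_family
#' @param families Families to fit; defaults to all seven.
#' @return A named list of `parametric_fit` objects. Families whose
#'   optimization fails are dropped with a warning.
#' @export
fit_all_families <- function(records, families = survival_families()) {
  records <- as_survival_records(records)
  fits <- list()
  for (fam in families) {
    res <- tryCatch(fit_family(records, fam), error = function(e) e)
    if (inherits(res, "error")) {
      warn(paste0("dropping family '", fam, "': ", conditionMessage(res)))
    } else {
      fits[[fam]] <- res
    }
  }
  if (!length(fits)) abort("no family could be fitted")
  fits
}

#' Select the best-fitting family by AIC
#'
#' Ties are broken by lower BIC, then lexicographic family name.
#'
#' @param fits A list of `parametric_fit` objects fitted to the same records.
#' @return The name of the winning family.
#' @export
select_best <- function(fits) {
  if (!length(fits)) abort("`fits` is empty")
  if (inherits(fits, "parametric_fit")) fits <- list(fits)
  tab <- fit_table(fits)
  tab <- dplyr::arrange(tab, .data$aic, .data$bic, .data$family)
  tab$family[1]
}

#' Tabulate a set of parametric fits
#'
#' One row per family with log-likelihood, AIC and BIC, mirroring the usual
#' model-comparison table of survival extrapolation reports.
#'
#' @inheritParams select_best
#' @return A tibble with columns `family`, `n`, `n_events`, `loglik`,
#'   `aic`, `bic`, `params` (list-column).
#' @export
fit_table <- function(fits) {
  purrr::map_dfr(fits, function(f) {
    stopifnot(inherits(f, "parametric_fit"))
    tibble::tibble(
      family = f$family, n = f$n, n_events = f$n_events,
      loglik = f$loglik, aic = f$aic, bic = f$bic,
      params = list(f$params)
    )
  })
}

#' Evaluate the fitted survival function
#'
#' @param fit A `parametric_fit` object.
#' @param t Times in months, `t >= 0` (vectorised).
#' @return Survival probabilities \eqn{S(t)}; \eqn{S(0) = 1}.
#' @export
survival_at <- function(fit, t) {
  stopifnot(inherits(fit, "parametric_fit"))
  if (any(!is.finite(t) & !is.infinite(t)) || any(t < 0)) {
    abort("`t` must be non-negative")
  }
  family_survival(fit$family, fit$params, t)
}

#' @export
print.parametric_fit <- function(x, ...) {
  cat("<parametric_fit> ", x$family, " (", x$source, ")\n", sep = "")
  cat("  ", paste(names(x$params), "=", signif(x$params, 6),
                  collapse = ", "), "\n", sep = "")
  if (!is.na(x$loglik)) {
    cat("  n = ", x$n, ", events = ", x$n_events,
        ", loglik = ", signif(x$loglik, 6),
        ", AIC = ", signif(x$aic, 6),
        ", BIC = ", signif(x$bic, 6), "\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.parametric_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params), estimate = unname(x$params))
}

#' @export
glance.parametric_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family, loglik = x$loglik, aic = x$aic, bic = x$bic,
    n = x$n, n_events = x$n_events, converged = x$converged
  )
}
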