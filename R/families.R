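#' Supported parametric survival families
#'
#' The seven families conventionally screened when extrapolating oncology
#' survival curves: exponential, Weibull, gamma, generalized gamma,
#' Gompertz, log-logistic and log-normal.
#'
#' @return Character vector of family names.
#' @export
#' @examples
#' survival_families()
survival_families <- function() {
  c("exponential", "weibull", "gamma", "generalized_gamma",
    "gompertz", "loglogistic", "lognormal")
}

# family name -> flexsurv distribution tag
.flexsurv_dist <- c(
  exponential       = "exp",
  weibull           = "weibull",
  gamma             = "gamma",
  generalized_gamma = "gengamma",
  gompertz          = "gompertz",
  loglogistic       = "llogis",
  lognormal         = "lnorm"
)

# canonical parameter names per family, in flexsurv's ordering
.family_params <- list(
  exponential       = "rate",
  weibull           = c("shape", "scale"),
  gamma             = c("shape", "rate"),
  generalized_gamma = c("mu", "sigma", "Q"),
  gompertz          = c("shape", "rate"),
  loglogistic       = c("scale", "shape"),
  lognormal         = c("meanlog", "sdlog")
)

check_family <- function(family) {
  if (!is.character(family) || length(family) != 1L ||
      !family %in% survival_families()) {
    abort(paste0(
      "`family` must be one of: ",
      paste(survival_families(), collapse = ", ")
    ))
  }
  family
}

check_family_params <- function(family, params) {
  wanted <- .family_params[[family]]
  if (is.null(names(params)) || !setequal(names(params), wanted)) {
    abort(paste0(
      "params for family '", family, "' must be named: ",
      paste(wanted, collapse = ", ")
    ))
  }
  params <- params[wanted]
  # support checks: scale-type parameters strictly positive; gompertz shape,
  # lognormal meanlog and generalized-gamma mu/Q may be any real
  pos <- switch(family,
    exponential       = "rate",
    weibull           = c("shape", "scale"),
    gamma             = c("shape", "rate"),
    generalized_gamma = "sigma",
    gompertz          = "rate",
    loglogistic       = c("scale", "shape"),
    lognormal         = "sdlog"
  )
  if (any(!is.finite(params))) abort("family parameters must be finite")
  if (any(params[pos] <= 0)) {
    abort(paste0(
      "family '", family, "' requires strictly positive: ",
      paste(pos, collapse = ", ")
    ))
  }
  params
}

# S(t) for a named family; t vectorised, t >= 0 assumed checked by caller
family_survival <- function(family, params, t) {
  switch(family,
    exponential = exp(-params[["rate"]] * t),
    weibull = exp(-(t / params[["scale"]])^params[["shape"]]),
    gamma = stats::pgamma(t, shape = params[["shape"]], rate = params[["rate"]],
                          lower.tail = FALSE),
    generalized_gamma = flexsurv::pgengamma(
      t, mu = params[["mu"]], sigma = params[["sigma"]], Q = params[["Q"]],
      lower.tail = FALSE),
    gompertz = flexsurv::pgompertz(
      t, shape = params[["shape"]], rate = params[["rate"]],
      lower.tail = FALSE),
    loglogistic = 1 / (1 + (t / params[["scale"]])^params[["shape"]]),
    lognormal = stats::plnorm(t, meanlog = params[["meanlog"]],
                              sdlog = params[["sdlog"]], lower.tail = FALSE)
  )
}

# quantile function (inverse CDF) for event-time simulation
family_quantile <- function(family, params, p) {
  switch(family,
    exponential = stats::qexp(p, rate = params[["rate"]]),
    weibull = stats::qweibull(p, shape = params[["shape"]],
                              scale = params[["scale"]]),
    gamma = stats::qgamma(p, shape = params[["shape"]], rate = params[["rate"]]),
    generalized_gamma = flexsurv::qgengamma(
      p, mu = params[["mu"]], sigma = params[["sigma"]], Q = params[["Q"]]),
    gompertz = flexsurv::qgompertz(p, shape = params[["shape"]],
                                   rate = params[["rate"]]),
    loglogistic = params[["scale"]] * (p / (1 - p))^(1 / params[["shape"]]),
    lognormal = stats::qlnorm(p, meanlog = params[["meanlog"]],
                              sdlog = params[["sdlog"]])
  )
}

# CDF, used by goodness-of-fit checks
family_cdf <- function(family, params, t) {
  1 - family_survival(family, params, t)
}
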