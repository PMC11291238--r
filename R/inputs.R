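#' Cycle and economic structure of the cohort model
#'
#' Collects everything the cohort engine needs besides the survival fits:
#' cycle structure, discounting, per-cycle costs, state utilities, the
#' willingness-to-pay threshold and the accrual conventions.
#'
#' @param cycle_days Cycle length in days (default 21, a 3-week cycle).
#' @param n_cycles Number of model cycles (default 208, about 12 years).
#' @param annual_discount_rate Annual discount rate applied to both costs
#'   and QALYs, in `[0, 0.08]` (default 0.05). Discounting is continuous in
#'   cycles: the factor at cycle \eqn{k} is \eqn{(1+r)^{-k \cdot
#'   \mathrm{cycle\_days}/365.25}}.
#' @param bsc_cost_per_cycle Best-supportive-care cost per cycle, CNY.
#' @param severe_ae_cost One-time cost of a severe adverse event, CNY.
#' @param u_pfs,u_pd Health-state utilities for progression-free and
#'   progressed disease; both in `[0, 1]` with `u_pfs > u_pd`.
#' @param wtp_threshold Willingness-to-pay per QALY, CNY (default 257,016,
#'   three times China's 2022 per-capita GDP).
#' @param bsc_scope Whether BSC accrues for everyone alive
#'   (`"all_alive"`, default) or in the progressed state only (`"pd_only"`).
#' @param half_cycle_correction Average adjacent-cycle occupancies before
#'   accrual (default `FALSE`).
#' @return An object of class `economic_inputs` (a named list).
#' @export
economic_inputs <- function(cycle_days = 21, n_cycles = 208,
                            annual_discount_rate = 0.05,
                            bsc_cost_per_cycle = 2467,
                            severe_ae_cost = 2534,
                            u_pfs = 0.804, u_pd = 0.321,
                            wtp_threshold = 257016,
                            bsc_scope = c("all_alive", "pd_only"),
                            half_cycle_correction = FALSE) {
  bsc_scope <- match.arg(bsc_scope)
  stopifnot(
    cycle_days > 0, n_cycles >= 1, n_cycles == round(n_cycles),
    bsc_cost_per_cycle >= 0, severe_ae_cost >= 0,
    is.logical(half_cycle_correction), wtp_threshold > 0
  )
  if (annual_discount_rate < 0 || annual_discount_rate > 0.08) {
    abort("`annual_discount_rate` must lie in [0, 0.08]")
  }
  if (u_pfs < 0 || u_pfs > 1 || u_pd < 0 || u_pd > 1) {
    abort("utilities must lie in [0, 1]")
  }
  if (u_pfs <= u_pd) abort("`u_pfs` must exceed `u_pd`")
  structure(
    list(
      cycle_days = cycle_days, n_cycles = as.integer(n_cycles),
      annual_discount_rate = annual_discount_rate,
      bsc_cost_per_cycle = bsc_cost_per_cycle,
      severe_ae_cost = severe_ae_cost,
      u_pfs = u_pfs, u_pd = u_pd,
      wtp_threshold = wtp_threshold,
      bsc_scope = bsc_scope,
      half_cycle_correction = half_cycle_correction
    ),
    class = "economic_inputs"
  )
}

cycle_months <- function(inputs) inputs$cycle_days / DAYS_PER_MONTH
cycle_years <- function(inputs) inputs$cycle_days / DAYS_PER_YEAR

#' Specify a treatment arm
#'
#' @param name Arm label.
#' @param os_fit,pfs_fit `parametric_fit` objects for overall and
#'   progression-free survival.
#' @param drug_cost_per_cycle Drug acquisition cost per cycle, CNY; accrues
#'   while in the progression-free state (treatment until progression).
#' @param ae_profile Optional tibble of grade >= 3 adverse events with
#'   columns `ae_name`, `incidence` (probability), `disutility` (positive
#'   utility decrement) and `duration_cycles`; applied once at model entry,
#'   weighted by incidence.
#' @return An object of class `arm_spec`.
#' @export
arm_spec <- function(name, os_fit, pfs_fit, drug_cost_per_cycle,
                     ae_profile = NULL) {
  stopifnot(inherits(os_fit, "parametric_fit"),
            inherits(pfs_fit, "parametric_fit"),
            drug_cost_per_cycle >= 0)
  if (is.null(ae_profile)) {
    ae_profile <- tibble::tibble(
      ae_name = character(), incidence = numeric(),
      disutility = numeric(), duration_cycles = integer()
    )
  }
  ae_profile <- tibble::as_tibble(ae_profile)
  need <- c("ae_name", "incidence", "disutility", "duration_cycles")
  if (!all(need %in% names(ae_profile))) {
    abort("`ae_profile` needs columns ae_name, incidence, disutility, duration_cycles")
  }
  if (any(ae_profile$incidence < 0 | ae_profile$incidence > 1)) {
    abort("AE incidences must lie in [0, 1]")
  }
  if (any(ae_profile$disutility < 0)) {
    abort("disutilities are stored as positive decrements")
  }
  if (any(ae_profile$duration_cycles < 1)) {
    abort("`duration_cycles` must be >= 1")
  }
  structure(
    list(
      name = as.character(name),
      os_fit = os_fit, pfs_fit = pfs_fit,
      drug_cost_per_cycle = drug_cost_per_cycle,
      ae_profile = ae_profile
    ),
    class = "arm_spec"
  )
}

#' Assemble a full model configuration
#'
#' @param inputs An [economic_inputs()] object.
#' @param intervention,comparator [arm_spec()] objects; incremental results
#'   are intervention minus comparator.
#' @param params Optional tibble of sensitivity-analysis parameter
#'   specifications (columns `id`, `base`, `low`, `high`, `psa_family`),
#'   see [parameter_specs()].
#' @param curves Optional named list giving digitized-curve CSV paths per
#'   arm and endpoint for the reconstruction pathway of [run_analysis()];
#'   see that function's details.
#' @return An object of class `ce_config`.
#' @export
ce_config <- function(inputs, intervention, comparator, params = NULL,
                      curves = NULL) {
  stopifnot(inherits(inputs, "economic_inputs"),
            inherits(intervention, "arm_spec"),
            inherits(comparator, "arm_spec"))
  if (!is.null(params)) {
    params <- tibble::as_tibble(params)
    need <- c("id", "base", "low", "high", "psa_family")
    if (!all(need %in% names(params))) {
      abort("`params` needs columns id, base, low, high, psa_family")
    }
    if (any(params$low > params$base | params$base > params$high)) {
      abort("parameter ranges must satisfy low <= base <= high")
    }
    if (!all(params$psa_family %in% c("beta", "gamma", "fixed"))) {
      abort("`psa_family` must be beta, gamma or fixed")
    }
  }
  structure(
    list(inputs = inputs, intervention = intervention,
         comparator = comparator, params = params, curves = curves),
    class = "ce_config"
  )
}

#' Sensitivity-analysis ranges of the reference configuration
#'
#' One row per varied parameter: the base value, the one-way range and the
#' probabilistic-sensitivity-analysis distribution family (beta for
#' quantities on `[0, 1]`, gamma for costs, fixed for the discount rate).
#' Disutility parameters are handled on their positive magnitude.
#'
#' @return A tibble with columns `id`, `base`, `low`, `high`, `psa_family`.
#' @export
parameter_specs <- function() {
  tibble::tribble(
    ~id,                          ~base,   ~low,     ~high,    ~psa_family,
    "drug_cost.tislelizumab",     2675,    2140,     2675,     "gamma",
    "drug_cost.docetaxel",        419.25,  419.25,   898.36,   "gamma",
    "bsc_cost",                   2467,    1973.65,  2960.47,  "gamma",
    "severe_ae_cost",             2534,    2027.2,   3040.8,   "gamma",
    "u_pfs",                      0.804,   0.724,    0.884,    "beta",
    "u_pd",                       0.321,   0.289,    0.353,    "beta",
    "du.neutropenia",             0.200,   0.180,    0.220,    "beta",
    "du.febrile_neutropenia",     0.420,   0.378,    0.462,    "beta",
    "du.anemia",                  0.078,   0.070,    0.086,    "beta",
    "du.asthenia",                0.078,   0.070,    0.086,    "beta",
    "discount_rate",              0.05,    0,        0.08,     "fixed"
  )
}

default_ae_profile <- function() {
  # the four grade >= 3 adverse events carried by the model; incidences
  # default to 0 and are meant to be overridden from trial data when known
  tibble::tibble(
    ae_name = c("neutropenia", "febrile_neutropenia", "anemia", "asthenia"),
    incidence = 0,
    disutility = c(0.200, 0.420, 0.078, 0.078),
    duration_cycles = 1L
  )
}

#' Reference configuration: tislelizumab vs docetaxel in advanced NSCLC
#'
#' The bundled base case: per-arm log-logistic OS/PFS parameters, per-cycle
#' drug and best-supportive-care costs, adverse-event cost, state utilities
#' and disutilities, a 5% annual discount rate over 208 three-week cycles,
#' and a willingness-to-pay threshold of 257,016 CNY/QALY. Adverse-event
#' incidences default to zero (their disutilities and one-time cost are
#' carried but inactive until incidences are supplied).
#'
#' @return A [ce_config()] object.
#' @export
#' @examples
#' cfg <- reference_config()
#' res <- run_base_case(cfg)
#' tidy(res)
reference_config <- function() {
  tis <- arm_spec(
    "tislelizumab",
    os_fit = parametric_fit("loglogistic", c(scale = 17.43252, shape = 1.48925)),
    pfs_fit = parametric_fit("loglogistic", c(scale = 4.84787, shape = 1.42274)),
    drug_cost_per_cycle = 2675,
    ae_profile = default_ae_profile()
  )
  doc <- arm_spec(
    "docetaxel",
    os_fit = parametric_fit("loglogistic", c(scale = 11.7162, shape = 1.5699)),
    pfs_fit = parametric_fit("loglogistic", c(scale = 3.11381, shape = 2.12956)),
    drug_cost_per_cycle = 419.25,
    ae_profile = default_ae_profile()
  )
  ce_config(
    inputs = economic_inputs(),
    intervention = tis,
    comparator = doc,
    params = parameter_specs()
  )
}

# set one sensitivity parameter in a config; ids as in parameter_specs()
apply_parameter <- function(config, id, value) {
  stopifnot(inherits(config, "ce_config"))
  set_du <- function(arm, ae, value) {
    i <- which(arm$ae_profile$ae_name == ae)
    if (!length(i)) abort(paste0("arm '", arm$name, "' has no AE '", ae, "'"))
    arm$ae_profile$disutility[i] <- value
    arm
  }
  if (grepl("^drug_cost\\.", id)) {
    arm_name <- sub("^drug_cost\\.", "", id)
    hit <- FALSE
    for (slot in c("intervention", "comparator")) {
      if (config[[slot]]$name == arm_name) {
        config[[slot]]$drug_cost_per_cycle <- value
        hit <- TRUE
      }
    }
    if (!hit) abort(paste0("unknown arm in parameter id: ", id))
  } else if (grepl("^du\\.", id)) {
    ae <- sub("^du\\.", "", id)
    config$intervention <- set_du(config$intervention, ae, value)
    config$comparator <- set_du(config$comparator, ae, value)
  } else if (id == "bsc_cost") {
    config$inputs$bsc_cost_per_cycle <- value
  } else if (id == "severe_ae_cost") {
    config$inputs$severe_ae_cost <- value
  } else if (id == "u_pfs") {
    config$inputs$u_pfs <- value
  } else if (id == "u_pd") {
    config$inputs$u_pd <- value
  } else if (id == "discount_rate") {
    config$inputs$annual_discount_rate <- value
  } else {
    abort(paste0("unknown parameter id: ", id))
  }
  config
}
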