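#' Build the three-state cohort trace from OS and PFS fits
#'
#' Partitioned-survival occupancy: at cycle time \eqn{t_k} the
#' progression-free share is \eqn{\min(S_{pfs}(t_k), S_{os}(t_k))}, the dead
#' share \eqn{1 - S_{os}(t_k)}, and progressed disease the remainder. The
#' whole cohort starts progression-free at cycle 0.
#'
#' @param os_fit,pfs_fit `parametric_fit` objects for overall and
#'   progression-free survival.
#' @param inputs An [economic_inputs()] object (cycle structure).
#' @return A tibble of class `cohort_trace` with columns `cycle`,
#'   `t_months`, `pfs`, `pd`, `dead`; one row per cycle `0..n_cycles`.
#' @export
cohort_trace <- function(os_fit, pfs_fit, inputs) {
  stopifnot(inherits(inputs, "economic_inputs"))
  k <- 0:inputs$n_cycles
  t_m <- k * cycle_months(inputs)
  s_os <- survival_at(os_fit, t_m)
  s_pfs <- pmin(survival_at(pfs_fit, t_m), s_os)
  out <- tibble::tibble(
    cycle = k,
    t_months = t_m,
    pfs = s_pfs,
    pd = s_os - s_pfs,
    dead = 1 - s_os
  )
  class(out) <- c("cohort_trace", class(out))
  out
}

#' Per-cycle transition probabilities implied by the survival curves
#'
#' Expresses the partitioned-survival trace as a time-inhomogeneous Markov
#' chain: progression-free continuation is the PFS survival ratio
#' \eqn{S_{pfs}(t_k)/S_{pfs}(t_{k-1})}; the cohort deaths of the cycle,
#' \eqn{S_{os}(t_{k-1}) - S_{os}(t_k)}, are allocated to the progressed
#' state first with any overflow drawn from the progression-free state; the
#' progression probability is the remainder (clamped at zero). States whose
#' occupancy has reached numerical zero are treated as absorbing-empty.
#' Propagating a cohort through these matrices reproduces [cohort_trace()]
#' to numerical precision.
#'
#' @inheritParams cohort_trace
#' @return A tibble with one row per cycle `1..n_cycles` and columns
#'   `cycle`, `t_months`, `pfs_pfs`, `pfs_pd`, `pfs_dead`, `pd_pd`,
#'   `pd_dead` (death is absorbing).
#' @export
transition_matrices <- function(os_fit, pfs_fit, inputs) {
  stopifnot(inherits(inputs, "economic_inputs"))
  k <- 0:inputs$n_cycles
  t_m <- k * cycle_months(inputs)
  s_os <- survival_at(os_fit, t_m)
  s_pfs <- pmin(survival_at(pfs_fit, t_m), s_os)
  eps <- .Machine$double.xmin

  i0 <- seq_len(inputs$n_cycles)       # previous cycle index
  i1 <- i0 + 1L
  pfs0 <- s_pfs[i0]; pfs1 <- s_pfs[i1]
  pd0 <- s_os[i0] - s_pfs[i0]
  deaths <- s_os[i0] - s_os[i1]

  pd_dead <- ifelse(pd0 > eps, pmin(deaths, pd0) / pd0, 0)
  overflow <- pmax(deaths - pd0, 0)
  pfs_pfs <- ifelse(pfs0 > eps, pfs1 / pfs0, 1)
  pfs_dead <- ifelse(pfs0 > eps, overflow / pfs0, 0)
  pfs_pd <- pmax(1 - pfs_pfs - pfs_dead, 0)

  tibble::tibble(
    cycle = i0,
    t_months = t_m[i1],
    pfs_pfs = pfs_pfs,
    pfs_pd = pfs_pd,
    pfs_dead = pfs_dead,
    pd_pd = 1 - pd_dead,
    pd_dead = pd_dead
  )
}

#' Propagate a cohort through per-cycle transition matrices
#'
#' Starts the whole cohort progression-free and applies the matrices of
#' [transition_matrices()] cycle by cycle. Used to demonstrate the
#' equivalence of the transition-matrix view with the partitioned-survival
#' trace.
#'
#' @param tm Output of [transition_matrices()].
#' @return A `cohort_trace` tibble.
#' @export
propagate_transitions <- function(tm) {
  n <- nrow(tm)
  pfs <- pd <- dead <- numeric(n + 1L)
  pfs[1] <- 1
  for (k in seq_len(n)) {
    pfs[k + 1L] <- pfs[k] * tm$pfs_pfs[k]
    pd[k + 1L] <- pd[k] * tm$pd_pd[k] + pfs[k] * tm$pfs_pd[k]
    dead[k + 1L] <- dead[k] + pd[k] * tm$pd_dead[k] + pfs[k] * tm$pfs_dead[k]
  }
  out <- tibble::tibble(
    cycle = 0:n,
    t_months = c(0, tm$t_months),
    pfs = pfs, pd = pd, dead = dead
  )
  class(out) <- c("cohort_trace", class(out))
  out
}

#' Accumulate discounted costs and QALYs over a cohort trace
#'
#' For each cycle \eqn{k \ge 1}, costs accrue as drug cost on the
#' progression-free occupancy plus best-supportive-care cost on the BSC
#' scope (everyone alive, or progressed only), and QALYs as
#' utility-weighted occupancy times the cycle length in years; both are
#' discounted by \eqn{(1+r)^{-t_k}} with \eqn{t_k} in years. The one-time
#' adverse-event burden (incidence-weighted cost and disutility) enters at
#' cycle 1. With `half_cycle_correction`, adjacent-cycle occupancies are
#' averaged before accrual.
#'
#' @param trace A [cohort_trace()].
#' @param arm An [arm_spec()] (drug cost and AE profile).
#' @param inputs An [economic_inputs()].
#' @return A one-row tibble of class `ce_outcome`: `arm`, `cost`, `qalys`.
#' @export
accumulate_outcomes <- function(trace, arm, inputs) {
  stopifnot(inherits(trace, "cohort_trace"), inherits(arm, "arm_spec"),
            inherits(inputs, "economic_inputs"))
  if (nrow(trace) != inputs$n_cycles + 1L) {
    abort("`trace` and `inputs` disagree on the number of cycles")
  }
  kk <- seq_len(inputs$n_cycles) + 1L   # rows for cycles 1..n
  pfs <- trace$pfs[kk]
  pd <- trace$pd[kk]
  if (inputs$half_cycle_correction) {
    pfs <- (trace$pfs[kk - 1L] + trace$pfs[kk]) / 2
    pd <- (trace$pd[kk - 1L] + trace$pd[kk]) / 2
  }
  t_years <- trace$cycle[kk] * cycle_years(inputs)
  disc <- (1 + inputs$annual_discount_rate)^(-t_years)

  bsc_occ <- if (inputs$bsc_scope == "all_alive") pfs + pd else pd
  cost_k <- pfs * arm$drug_cost_per_cycle + bsc_occ * inputs$bsc_cost_per_cycle
  qaly_k <- (pfs * inputs$u_pfs + pd * inputs$u_pd) * cycle_years(inputs)

  ae <- arm$ae_profile
  ae_cost <- sum(ae$incidence * inputs$severe_ae_cost)
  ae_qaly <- sum(ae$incidence * ae$disutility * ae$duration_cycles *
                   cycle_years(inputs))

  out <- tibble::tibble(
    arm = arm$name,
    cost = sum(disc * cost_k) + disc[1] * ae_cost,
    qalys = sum(disc * qaly_k) - disc[1] * ae_qaly
  )
  class(out) <- c("ce_outcome", class(out))
  out
}

#' Incremental cost-effectiveness ratio of two arm outcomes
#'
#' Deltas are intervention minus comparator, on unrounded totals. When the
#' delta signs disagree the ratio is uninterpretable and a dominance label
#' is returned instead: `"dominant"` (cheaper and more effective) or
#' `"dominated"` (costlier and less effective, including the degenerate
#' case of extra cost with no QALY change).
#'
#' @param intervention,comparator One-row `ce_outcome` tibbles from
#'   [accumulate_outcomes()].
#' @return A one-row tibble of class `icer_result`: `delta_cost`,
#'   `delta_qalys`, `icer` (`NA` under dominance), `label`.
#' @export
icer <- function(intervention, comparator) {
  stopifnot(inherits(intervention, "ce_outcome"),
            inherits(comparator, "ce_outcome"))
  dc <- intervention$cost - comparator$cost
  dq <- intervention$qalys - comparator$qalys
  if (abs(dq) < 1e-12) {
    label <- if (dc > 0) "dominated" else if (dc < 0) "dominant" else "icer"
    ratio <- if (label == "icer") 0 else NA_real_
  } else if (dc >= 0 && dq > 0 || dc <= 0 && dq < 0) {
    label <- "icer"
    ratio <- dc / dq
  } else if (dc < 0 && dq > 0) {
    label <- "dominant"
    ratio <- NA_real_
  } else {
    label <- "dominated"
    ratio <- NA_real_
  }
  out <- tibble::tibble(delta_cost = dc, delta_qalys = dq,
                        icer = ratio, label = label)
  class(out) <- c("icer_result", class(out))
  out
}

#' Per-cycle drug cost from unit price and dose
#'
#' Bills the exact administered milligrams at the per-milligram price
#' implied by the pack (no vial rounding).
#'
#' @param unit_price Price of one pack, CNY.
#' @param pack_content_mg Milligrams per pack.
#' @param dose_mg Milligrams per administration; build with [flat_dose()]
#'   or [bsa_dose()].
#' @return Cost per administration (= per cycle), CNY.
#' @export
#' @examples
#' dosing_cost(65, 20, bsa_dose(75, bsa = 1.72))   # 419.25
#' dosing_cost(1377.5, 100, flat_dose(200))        # 2755
dosing_cost <- function(unit_price, pack_content_mg, dose_mg) {
  if (unit_price <= 0) abort("`unit_price` must be positive")
  if (pack_content_mg <= 0) abort("`pack_content_mg` must be positive")
  if (dose_mg < 0) abort("`dose_mg` must be non-negative")
  unit_price / pack_content_mg * dose_mg
}

#' @rdname dosing_cost
#' @param mg Flat dose in milligrams.
#' @export
flat_dose <- function(mg) {
  if (mg < 0) abort("dose must be non-negative")
  mg
}

#' @rdname dosing_cost
#' @param mg_per_m2 Dose per square metre of body surface area.
#' @param bsa Body surface area in square metres (default 1.72).
#' @export
bsa_dose <- function(mg_per_m2, bsa = 1.72) {
  if (mg_per_m2 < 0 || bsa <= 0) abort("dose and BSA must be positive")
  mg_per_m2 * bsa
}

#' Run the base-case cost-effectiveness analysis
#'
#' Builds each arm's cohort trace, accumulates discounted costs and QALYs
#' and computes the incremental result.
#'
#' @param config A [ce_config()] object.
#' @return An object of class `ce_result`: list with `outcomes` (two-row
#'   tibble), `icer` (an `icer_result`), `traces` (named list of
#'   `cohort_trace`) and `config`.
#' @export
run_base_case <- function(config) {
  stopifnot(inherits(config, "ce_config"))
  arms <- list(config$intervention, config$comparator)
  traces <- lapply(arms, function(a) {
    cohort_trace(a$os_fit, a$pfs_fit, config$inputs)
  })
  names(traces) <- vapply(arms, `[[`, "", "name")
  outcomes <- purrr::map2_dfr(traces, arms, accumulate_outcomes,
                              inputs = config$inputs)
  class(outcomes) <- c("ce_outcome", class(tibble::tibble()))
  res <- icer(outcomes[1, ], outcomes[2, ])
  structure(
    list(outcomes = outcomes, icer = res, traces = traces, config = config),
    class = "ce_result"
  )
}

#' @export
print.ce_result <- function(x, ...) {
  cat("<ce_result>\n")
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.ce_result <- function(x, ...) {
  out <- x$outcomes
  out$delta_cost <- c(x$icer$delta_cost, NA)
  out$delta_qalys <- c(x$icer$delta_qalys, NA)
  out$icer <- c(x$icer$icer, NA)
  tibble::as_tibble(out)
}

#' @export
glance.ce_result <- function(x, ...) {
  tibble::tibble(
    delta_cost = x$icer$delta_cost,
    delta_qalys = x$icer$delta_qalys,
    icer = x$icer$icer,
    label = x$icer$label,
    wtp_threshold = x$config$inputs$wtp_threshold,
    cost_effective = !is.na(x$icer$icer) &
      x$icer$icer < x$config$inputs$wtp_threshold |
      x$icer$label == "dominant"
  )
}

#' @export
autoplot.cohort_trace <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("pfs", "pd", "dead"),
    names_to = "state", values_to = "occupancy"
  )
  df$state <- factor(df$state, levels = c("pfs", "pd", "dead"),
                     labels = c("Progression-free", "Progressed", "Dead"))
  ggplot2::ggplot(df, ggplot2::aes(.data$t_months, .data$occupancy,
                                   fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "Time (months)", y = "State occupancy", fill = NULL) +
    ggplot2::theme_minimal()
}
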