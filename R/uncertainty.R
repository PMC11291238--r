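#' Moment-matched PSA distribution for a parameter range
#'
#' Reads the one-way range as a 95% interval, so the standard deviation is
#' \eqn{\sigma = (high - low)/3.92}, and matches a beta (quantities on
#' `[0, 1]`) or gamma (costs) distribution to mean = base and that
#' \eqn{\sigma} by the method of moments:
#' beta `shape1` \eqn{= m(m(1-m)/\sigma^2 - 1)}, `shape2`
#' \eqn{= (1-m)(m(1-m)/\sigma^2 - 1)}; gamma `shape` \eqn{= (m/\sigma)^2},
#' `scale` \eqn{= \sigma^2/m}. A zero-width range degenerates to a fixed
#' point mass.
#'
#' @param base,low,high Base value and one-way range (`low <= base <= high`).
#' @param psa_family `"beta"`, `"gamma"` or `"fixed"`.
#' @return An object of class `psa_dist`: list with `family`, `params`,
#'   `mean`, `sd`.
#' @export
#' @examples
#' moment_match(0.804, 0.724, 0.884, "beta")
moment_match <- function(base, low, high, psa_family = c("beta", "gamma", "fixed")) {
  psa_family <- match.arg(psa_family)
  if (low > base || base > high) abort("need low <= base <= high")
  sd <- (high - low) / 3.92
  if (psa_family == "fixed" || sd == 0) {
    return(structure(
      list(family = "fixed", params = c(value = base), mean = base, sd = 0),
      class = "psa_dist"
    ))
  }
  m <- base
  if (psa_family == "beta") {
    if (m <= 0 || m >= 1) abort("beta moment matching needs base in (0, 1)")
    v <- sd^2
    if (v >= m * (1 - m)) {
      abort(paste0("infeasible beta moments: variance ", signif(v, 4),
                   " >= m(1-m) = ", signif(m * (1 - m), 4)))
    }
    nu <- m * (1 - m) / v - 1
    params <- c(shape1 = m * nu, shape2 = (1 - m) * nu)
  } else {
    if (m <= 0) abort("gamma moment matching needs a positive base")
    params <- c(shape = (m / sd)^2, scale = sd^2 / m)
  }
  structure(
    list(family = psa_family, params = params, mean = m, sd = sd),
    class = "psa_dist"
  )
}

#' @export
print.psa_dist <- function(x, ...) {
  cat("<psa_dist> ", x$family, ": ",
      paste(names(x$params), "=", signif(x$params, 6), collapse = ", "),
      " (mean ", signif(x$mean, 6), ", sd ", signif(x$sd, 6), ")\n", sep = "")
  invisible(x)
}

# n draws from a psa_dist
psa_sample <- function(dist, n) {
  switch(dist$family,
    fixed = rep(dist$params[["value"]], n),
    beta = rbeta(n, dist$params[["shape1"]], dist$params[["shape2"]]),
    gamma = rgamma(n, shape = dist$params[["shape"]],
                   scale = dist$params[["scale"]])
  )
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-runs the full base case with each parameter at its low and at its
#' high bound, all others held at base, and reports the ICER swing. Entries
#' are sorted by descending swing; the ordering does not depend on the
#' order of the input specifications.
#'
#' @param config A [ce_config()] with a `params` table (see
#'   [parameter_specs()]).
#' @param params Optional replacement parameter table.
#' @return A tibble of class `tornado`: `parameter`, `icer_low`,
#'   `icer_high`, `swing`, plus attribute `base_icer`.
#' @export
one_way_sa <- function(config, params = NULL) {
  stopifnot(inherits(config, "ce_config"))
  params <- params %||% config$params
  if (is.null(params)) abort("no parameter specifications supplied")
  base <- run_base_case(config)
  icer_at <- function(id, value) {
    run_base_case(apply_parameter(config, id, value))$icer$icer
  }
  out <- purrr::pmap_dfr(
    params[c("id", "low", "high")],
    function(id, low, high) {
      tibble::tibble(
        parameter = id,
        icer_low = icer_at(id, low),
        icer_high = icer_at(id, high)
      )
    }
  )
  out$swing <- abs(out$icer_high - out$icer_low)
  out <- dplyr::arrange(out, dplyr::desc(.data$swing), .data$parameter)
  attr(out, "base_icer") <- base$icer$icer
  class(out) <- c("tornado", class(out))
  out
}

#' Probabilistic sensitivity analysis (second-order Monte Carlo)
#'
#' Each draw samples every non-fixed parameter independently from its
#' moment-matched distribution ([moment_match()]), re-evaluates both arms
#' of the cohort model and records the per-arm and incremental discounted
#' costs and QALYs. Survival-model parameters are not varied (no published
#' ranges), so the state occupancies are common to all draws and are built
#' once. Results are reproducible under a fixed seed.
#'
#' @inheritParams one_way_sa
#' @param n_draws Number of Monte Carlo iterations (default 5000).
#' @param seed Integer seed (default 20240718).
#' @return An object of class `psa_result`: list with `draws` (tibble
#'   `draw`, per-arm `cost_*`/`qalys_*`, `delta_cost`, `delta_qalys`),
#'   `n_draws`, `seed`, `base` (the deterministic `ce_result`).
#' @export
run_psa <- function(config, n_draws = 5000, seed = 20240718, params = NULL) {
  stopifnot(inherits(config, "ce_config"), n_draws >= 1)
  params <- params %||% config$params
  if (is.null(params)) abort("no parameter specifications supplied")

  dists <- purrr::pmap(
    params[c("base", "low", "high", "psa_family")],
    function(base, low, high, psa_family) {
      moment_match(base, low, high, psa_family)
    }
  )
  names(dists) <- params$id

  set.seed(as.integer(seed))
  draw_mat <- vapply(dists, psa_sample, numeric(n_draws), n = n_draws)
  if (n_draws == 1L) draw_mat <- matrix(draw_mat, nrow = 1,
                                        dimnames = list(NULL, names(dists)))

  arms <- list(config$intervention, config$comparator)
  arm_names <- vapply(arms, `[[`, "", "name")
  traces <- lapply(arms, function(a) {
    cohort_trace(a$os_fit, a$pfs_fit, config$inputs)
  })

  one_draw <- function(values) {
    cfg <- config
    for (id in names(dists)) cfg <- apply_parameter(cfg, id, values[[id]])
    out <- purrr::map2_dfr(traces, list(cfg$intervention, cfg$comparator),
                           accumulate_outcomes, inputs = cfg$inputs)
    c(cost1 = out$cost[1], qalys1 = out$qalys[1],
      cost2 = out$cost[2], qalys2 = out$qalys[2])
  }
  res <- t(apply(draw_mat, 1, one_draw))

  draws <- tibble::tibble(
    draw = seq_len(n_draws),
    cost_intervention = res[, "cost1"],
    qalys_intervention = res[, "qalys1"],
    cost_comparator = res[, "cost2"],
    qalys_comparator = res[, "qalys2"],
    delta_cost = res[, "cost1"] - res[, "cost2"],
    delta_qalys = res[, "qalys1"] - res[, "qalys2"]
  )
  structure(
    list(
      draws = draws,
      samples = tibble::as_tibble(draw_mat),
      arm_names = arm_names,
      n_draws = as.integer(n_draws),
      seed = as.integer(seed),
      base = run_base_case(config),
      wtp_threshold = config$inputs$wtp_threshold
    ),
    class = "psa_result"
  )
}

#' @export
print.psa_result <- function(x, ...) {
  cat("<psa_result> ", x$n_draws, " draws (seed ", x$seed, ")\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' @export
tidy.psa_result <- function(x, ...) x$draws

#' @export
glance.psa_result <- function(x, ...) {
  tibble::tibble(
    n_draws = x$n_draws,
    seed = x$seed,
    mean_delta_cost = mean(x$draws$delta_cost),
    mean_delta_qalys = mean(x$draws$delta_qalys),
    prob_ce_at_wtp = prob_cost_effective(x, x$wtp_threshold),
    wtp_threshold = x$wtp_threshold
  )
}

#' Probability of cost-effectiveness at given willingness-to-pay values
#'
#' The fraction of PSA draws with positive net monetary benefit
#' \eqn{\lambda \Delta E - \Delta C > 0}.
#'
#' @param psa A `psa_result`.
#' @param wtp Willingness-to-pay values, CNY/QALY (vectorised).
#' @return Probabilities in `[0, 1]`.
#' @export
prob_cost_effective <- function(psa, wtp) {
  stopifnot(inherits(psa, "psa_result"))
  vapply(wtp, function(l) {
    mean(l * psa$draws$delta_qalys - psa$draws$delta_cost > 0)
  }, numeric(1))
}

#' Cost-effectiveness acceptability curve
#'
#' @inheritParams prob_cost_effective
#' @param wtp_grid Strictly increasing willingness-to-pay grid (default 0
#'   to 600,000 CNY/QALY in steps of 10,000).
#' @return A tibble of class `ceac_curve`: `wtp`, `probability`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 600000, by = 10000)) {
  stopifnot(inherits(psa, "psa_result"), length(wtp_grid) >= 1)
  if (any(diff(wtp_grid) <= 0)) abort("`wtp_grid` must be strictly increasing")
  out <- tibble::tibble(
    wtp = wtp_grid,
    probability = prob_cost_effective(psa, wtp_grid)
  )
  class(out) <- c("ceac_curve", class(out))
  out
}

#' @export
autoplot.ceac_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$wtp, .data$probability)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (CNY/QALY)",
                  y = "Probability cost-effective") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.psa_result <- function(object, ...) {
  ggplot2::ggplot(object$draws,
                  ggplot2::aes(.data$delta_qalys, .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_abline(slope = object$wtp_threshold, intercept = 0,
                         linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (CNY)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.tornado <- function(object, ...) {
  base <- attr(object, "base_icer")
  df <- tibble::as_tibble(object)
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$icer_low, xend = .data$icer_high,
                   y = .data$parameter, yend = .data$parameter),
      linewidth = 4, colour = "steelblue"
    ) +
    ggplot2::geom_vline(xintercept = base, linetype = "dashed") +
    ggplot2::labs(x = "ICER (CNY/QALY)", y = NULL) +
    ggplot2::theme_minimal()
}
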