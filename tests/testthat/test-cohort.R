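ref_inputs <- economic_inputs()

test_that("the cohort starts progression-free and trace rows sum to one", {
  cfg <- reference_config()
  for (arm in list(cfg$intervention, cfg$comparator)) {
    tr <- cohort_trace(arm$os_fit, arm$pfs_fit, ref_inputs)
    expect_equal(nrow(tr), 209)
    expect_equal(unlist(tr[1, c("pfs", "pd", "dead")]),
                 c(pfs = 1, pd = 0, dead = 0))
    expect_true(all(abs(tr$pfs + tr$pd + tr$dead - 1) < 1e-9))
    expect_true(all(diff(tr$dead) >= -1e-15))
    expect_true(all(tr$pfs >= 0 & tr$pfs <= 1))
    expect_true(all(tr$pd >= 0 & tr$pd <= 1))
  }
})

test_that("degenerate flat curves keep everyone progression-free", {
  # gompertz with rate -> 0 is numerically flat over the horizon
  flat <- parametric_fit("gompertz", c(shape = 0, rate = 1e-300))
  tr <- cohort_trace(flat, flat, ref_inputs)
  expect_true(all(tr$pfs == 1))
  expect_true(all(tr$pd == 0))
  expect_true(all(tr$dead == 0))
})

test_that("occupancy matches direct log-logistic evaluation at cycle 30", {
  cfg <- reference_config()
  tis <- cfg$intervention
  tr <- cohort_trace(tis$os_fit, tis$pfs_fit, ref_inputs)
  t30 <- 30 * 21 / 30.4375
  s_os <- 1 / (1 + (t30 / 17.43252)^1.48925)
  s_pfs <- 1 / (1 + (t30 / 4.84787)^1.42274)
  row <- tr[tr$cycle == 30, ]
  expect_equal(row$t_months, t30)
  expect_equal(row$pfs, min(s_pfs, s_os), tolerance = 1e-12)
  expect_equal(row$pd, s_os - min(s_pfs, s_os), tolerance = 1e-12)
  expect_equal(row$dead, 1 - s_os, tolerance = 1e-12)
})

test_that("transition matrices are row-stochastic and reproduce the trace", {
  cfg <- reference_config()
  for (arm in list(cfg$intervention, cfg$comparator)) {
    tm <- transition_matrices(arm$os_fit, arm$pfs_fit, ref_inputs)
    expect_true(all(abs(tm$pfs_pfs + tm$pfs_pd + tm$pfs_dead - 1) < 1e-12))
    expect_true(all(abs(tm$pd_pd + tm$pd_dead - 1) < 1e-12))
    expect_true(all(tm$pfs_pfs >= 0 & tm$pfs_pd >= 0 & tm$pfs_dead >= 0 &
                      tm$pd_dead >= 0))
    prop <- propagate_transitions(tm)
    tr <- cohort_trace(arm$os_fit, arm$pfs_fit, ref_inputs)
    expect_lt(max(abs(prop$pfs - tr$pfs)), 1e-9)
    expect_lt(max(abs(prop$pd - tr$pd)), 1e-9)
    expect_lt(max(abs(prop$dead - tr$dead)), 1e-9)
  }
})

test_that("constant survival curves yield identity transitions", {
  flat <- parametric_fit("gompertz", c(shape = 0, rate = 1e-300))
  tm <- transition_matrices(flat, flat, ref_inputs)
  expect_true(all(tm$pfs_pfs == 1))
  expect_true(all(tm$pd_pd == 1))
})

test_that("zero costs and utilities accumulate to zero", {
  cfg <- reference_config()
  inp <- economic_inputs(bsc_cost_per_cycle = 0, severe_ae_cost = 0,
                         u_pfs = 1e-9, u_pd = 0)
  arm <- arm_spec("free", cfg$intervention$os_fit, cfg$intervention$pfs_fit,
                  drug_cost_per_cycle = 0)
  tr <- cohort_trace(arm$os_fit, arm$pfs_fit, inp)
  out <- accumulate_outcomes(tr, arm, inp)
  expect_equal(out$cost, 0)
  expect_equal(out$qalys, 0, tolerance = 1e-8)
})

test_that("an immortal progression-free cohort accrues the full horizon", {
  flat <- parametric_fit("gompertz", c(shape = 0, rate = 1e-300))
  inp <- economic_inputs(annual_discount_rate = 0, bsc_cost_per_cycle = 0,
                         severe_ae_cost = 0, u_pfs = 1, u_pd = 0.5)
  arm <- arm_spec("immortal", flat, flat, drug_cost_per_cycle = 0)
  out <- accumulate_outcomes(cohort_trace(flat, flat, inp), arm, inp)
  expect_equal(out$qalys, 208 * 21 / 365.25, tolerance = 1e-12)
})

test_that("raising the discount rate never raises either total", {
  cfg <- reference_config()
  prev <- NULL
  for (r in c(0, 0.03, 0.05, 0.08)) {
    cfg_r <- apply_parameter(cfg, "discount_rate", r)
    res <- run_base_case(cfg_r)
    if (!is.null(prev)) {
      expect_true(all(res$outcomes$cost <= prev$cost + 1e-9))
      expect_true(all(res$outcomes$qalys <= prev$qalys + 1e-9))
    }
    prev <- res$outcomes
  }
})

test_that("exponential life-years stay below the 1/rate asymptote", {
  rate <- 0.08
  fit <- parametric_fit("exponential", c(rate = rate))
  inp <- economic_inputs(annual_discount_rate = 0, bsc_cost_per_cycle = 0,
                         severe_ae_cost = 0, u_pfs = 1, u_pd = 0.5)
  arm <- arm_spec("exp", fit, fit, drug_cost_per_cycle = 0)
  out <- accumulate_outcomes(cohort_trace(fit, fit, inp), arm, inp)
  # undiscounted life-years (u = 1 everywhere alive) in months, vs 1/rate
  ly_months <- out$qalys * 365.25 / 30.4375
  expect_lt(ly_months, 1 / rate)
  # the truncated sum approaches the bound from below
  expect_gt(ly_months, 0.9 / rate)
})

test_that("AE burden enters once, weighted by incidence", {
  cfg <- reference_config()
  arm <- cfg$intervention
  arm$ae_profile$incidence <- c(0.1, 0.05, 0.2, 0.1)
  tr <- cohort_trace(arm$os_fit, arm$pfs_fit, ref_inputs)
  base <- accumulate_outcomes(tr, cfg$intervention, ref_inputs)
  with_ae <- accumulate_outcomes(tr, arm, ref_inputs)
  disc1 <- 1.05^(-21 / 365.25)
  exp_cost <- sum(arm$ae_profile$incidence) * ref_inputs$severe_ae_cost * disc1
  exp_qaly <- sum(arm$ae_profile$incidence * arm$ae_profile$disutility) *
    (21 / 365.25) * disc1
  expect_equal(with_ae$cost - base$cost, exp_cost)
  expect_equal(base$qalys - with_ae$qalys, exp_qaly)
})

test_that("ICER arithmetic and dominance labels", {
  mk <- function(cost, qalys) {
    out <- tibble::tibble(arm = "x", cost = cost, qalys = qalys)
    class(out) <- c("ce_outcome", class(out))
    out
  }
  r <- icer(mk(200, 1.0), mk(100, 0.5))
  expect_equal(r$icer, 200)
  expect_equal(r$label, "icer")
  expect_equal(icer(mk(90, 1.1), mk(100, 1.0))$label, "dominant")
  expect_equal(icer(mk(110, 0.9), mk(100, 1.0))$label, "dominated")
  deg <- icer(mk(110, 1), mk(100, 1))
  expect_equal(deg$label, "dominated")
  expect_true(is.na(deg$icer))
})

test_that("dosing arithmetic bills exact milligrams", {
  expect_equal(dosing_cost(65, 20, bsa_dose(75, bsa = 1.72)), 419.25)
  # 139.28/20 * 129 mg = 898.356, printed as 898.36 at two decimals
  expect_equal(dosing_cost(139.28, 20, bsa_dose(75, bsa = 1.72)), 898.356)
  expect_equal(dosing_cost(1377.5, 100, flat_dose(200)), 2755)
  expect_equal(dosing_cost(100, 50, flat_dose(0)), 0)
  expect_error(dosing_cost(-5, 20, 100), "positive")
  expect_error(dosing_cost(65, 0, 100), "positive")
})
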