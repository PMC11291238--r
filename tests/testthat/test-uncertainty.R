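test_that("beta moment matching recovers the requested mean and sd", {
  mm <- moment_match(0.804, 0.724, 0.884, "beta")
  sd_target <- (0.884 - 0.724) / 3.92
  expect_equal(sd_target, 0.0408163, tolerance = 1e-6)
  a <- mm$params[["shape1"]]; b <- mm$params[["shape2"]]
  expect_equal(a / (a + b), 0.804, tolerance = 1e-9)
  expect_equal(sqrt(a * b / ((a + b)^2 * (a + b + 1))), sd_target,
               tolerance = 1e-9)
})

test_that("gamma moment matching recovers the requested mean and sd", {
  mm <- moment_match(2467, 1973.65, 2960.47, "gamma")
  sh <- mm$params[["shape"]]; sc <- mm$params[["scale"]]
  expect_equal(sh * sc, 2467, tolerance = 1e-9)
  expect_equal(sqrt(sh) * sc, (2960.47 - 1973.65) / 3.92, tolerance = 1e-9)
  expect_equal(mm$sd, 251.7398, tolerance = 1e-4)
})

test_that("degenerate and infeasible ranges are handled", {
  mm <- moment_match(0.5, 0.5, 0.5, "beta")
  expect_equal(mm$family, "fixed")
  # variance >= m(1-m) cannot come from a beta
  expect_error(moment_match(0.5, -1.5, 2.5, "beta"), "infeasible")
  expect_no_error(moment_match(0.9, 0.5, 0.95, "fixed"))
})

test_that("tornado: degenerate range gives zero swing, order is invariant", {
  cfg <- reference_config()
  params <- cfg$params[cfg$params$id %in%
                         c("bsc_cost", "u_pfs", "drug_cost.tislelizumab"), ]
  params <- dplyr::bind_rows(
    params,
    tibble::tibble(id = "u_pd", base = 0.321, low = 0.321, high = 0.321,
                   psa_family = "beta")
  )
  tor <- one_way_sa(cfg, params = params)
  expect_equal(tor$swing[tor$parameter == "u_pd"], 0)
  tor_rev <- one_way_sa(cfg, params = params[rev(seq_len(nrow(params))), ])
  expect_equal(tibble::as_tibble(tor), tibble::as_tibble(tor_rev))
  expect_error(one_way_sa(cfg, params = tibble::tibble(
    id = "not_a_parameter", base = 1, low = 0, high = 2,
    psa_family = "fixed"
  )), "unknown parameter")
})

test_that("all-fixed PSA reproduces the base-case deltas in every draw", {
  cfg <- reference_config()
  params <- cfg$params
  params$psa_family <- "fixed"
  psa <- run_psa(cfg, n_draws = 5, seed = 1, params = params)
  base <- run_base_case(cfg)
  expect_true(all(abs(psa$draws$delta_cost - base$icer$delta_cost) < 1e-9))
  expect_true(all(abs(psa$draws$delta_qalys - base$icer$delta_qalys) < 1e-9))
})

test_that("the PSA is seed-reproducible and seeds differ", {
  cfg <- reference_config()
  a <- run_psa(cfg, n_draws = 50, seed = 42)
  b <- run_psa(cfg, n_draws = 50, seed = 42)
  c <- run_psa(cfg, n_draws = 50, seed = 43)
  expect_identical(a$draws, b$draws)
  expect_false(identical(a$draws$delta_cost, c$draws$delta_cost))
})

test_that("PSA parameter samples converge to their base values", {
  cfg <- reference_config()
  n <- 2000
  psa <- run_psa(cfg, n_draws = n, seed = 7)
  specs <- cfg$params[cfg$params$psa_family != "fixed", ]
  for (i in seq_len(nrow(specs))) {
    s <- specs[i, ]
    draws <- psa$samples[[s$id]]
    mc_se <- (s$high - s$low) / 3.92 / sqrt(n)
    expect_lt(abs(mean(draws) - s$base), 3 * mc_se,
              label = paste0("mean of ", s$id))
  }
})

test_that("PSA delta means stay near the deterministic base deltas", {
  cfg <- reference_config()
  psa <- run_psa(cfg, n_draws = 1000, seed = 99)
  base <- run_base_case(cfg)
  expect_lt(abs(mean(psa$draws$delta_cost) - base$icer$delta_cost) /
              abs(base$icer$delta_cost), 0.05)
  expect_lt(abs(mean(psa$draws$delta_qalys) - base$icer$delta_qalys) /
              abs(base$icer$delta_qalys), 0.05)
})

test_that("CEAC equals brute-force net-monetary-benefit counting", {
  cfg <- reference_config()
  psa <- run_psa(cfg, n_draws = 400, seed = 3)
  grid <- seq(0, 600000, by = 50000)
  curve <- ceac(psa, grid)
  for (j in seq_along(grid)) {
    nmb <- grid[j] * psa$draws$delta_qalys - psa$draws$delta_cost
    expect_equal(curve$probability[j], sum(nmb > 0) / nrow(psa$draws))
  }
  expect_true(all(curve$probability >= 0 & curve$probability <= 1))
  # with almost surely positive delta-QALYs the curve is non-decreasing
  expect_true(all(psa$draws$delta_qalys > 0))
  expect_true(all(diff(curve$probability) >= 0))
})

test_that("single-draw NMB sign cases", {
  cfg <- reference_config()
  params <- cfg$params
  params$psa_family <- "fixed"
  psa <- run_psa(cfg, n_draws = 1, seed = 1, params = params)
  psa$draws$delta_cost <- 1
  psa$draws$delta_qalys <- 1
  expect_equal(prob_cost_effective(psa, 2), 1)
  expect_equal(prob_cost_effective(psa, 0.5), 0)
})
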