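test_that("no censoring mechanisms means every record is an event", {
  rec <- simulate_ipd(500, "loglogistic", c(scale = 17.43, shape = 1.489),
                      seed = 1)
  expect_true(all(rec$event == 1))
  expect_true(all(rec$time_months > 0))
})

test_that("identical spec and seed reproduce byte-identical records", {
  a <- simulate_ipd(200, "gamma", c(shape = 2, rate = 0.2),
                    administrative_censor_time = 15,
                    random_censor_rate = 0.1, seed = 99)
  b <- simulate_ipd(200, "gamma", c(shape = 2, rate = 0.2),
                    administrative_censor_time = 15,
                    random_censor_rate = 0.1, seed = 99)
  expect_identical(a, b)
})

test_that("log-logistic sampling honours its median identities", {
  rec <- simulate_ipd(10000, "loglogistic", c(scale = 17.43, shape = 1.489),
                      seed = 12)
  expect_lt(abs(stats::median(rec$time_months) - 17.43) / 17.43, 0.02)
  s_at_scale <- mean(rec$time_months > 17.43)
  expect_lt(abs(s_at_scale - 0.5), 0.02)
})

test_that("random censoring hits the requested expected fraction", {
  rec <- simulate_ipd(8000, "weibull", c(shape = 1.4, scale = 12),
                      random_censor_rate = 0.3, seed = 4)
  expect_lt(abs(mean(rec$event == 0) - 0.3), 0.02)
})

test_that("uncensored draws pass a goodness-of-fit test per family", {
  pars <- family_test_params()
  for (fam in names(pars)) {
    rec <- simulate_ipd(5000, fam, pars[[fam]], seed = 2)
    p <- pars[[fam]]
    cdf <- switch(fam,
      exponential = function(q) stats::pexp(q, rate = p[["rate"]]),
      weibull = function(q) stats::pweibull(q, p[["shape"]], p[["scale"]]),
      gamma = function(q) stats::pgamma(q, p[["shape"]], p[["rate"]]),
      generalized_gamma = function(q) {
        flexsurv::pgengamma(q, p[["mu"]], p[["sigma"]], p[["Q"]])
      },
      gompertz = function(q) flexsurv::pgompertz(q, p[["shape"]], p[["rate"]]),
      loglogistic = function(q) 1 / (1 + (q / p[["scale"]])^(-p[["shape"]])),
      lognormal = function(q) stats::plnorm(q, p[["meanlog"]], p[["sdlog"]])
    )
    ks <- suppressWarnings(stats::ks.test(rec$time_months, cdf))
    expect_gt(ks$p.value, 0.01, label = paste0("KS p-value for ", fam))
  }
})

test_that("a two-subject KM renders as the expected step coordinates", {
  rec <- data.frame(time_months = c(1, 2), event = 1)
  dig <- make_digitized(rec, coord_grid_step = 0.5, risk_interval = 1)
  expect_equal(unique(dig$coords$survival), c(1, 0.5, 0))
  expect_equal(dig$coords$survival[dig$coords$time_months == 1], 0.5)
  expect_equal(dig$risk_table$n_at_risk, c(2, 2, 1))
  expect_error(make_digitized(rec, coord_grid_step = 0), "positive")
})

test_that("simulate -> digitize -> reconstruct -> fit recovers parameters", {
  rec <- simulate_ipd(1200, "loglogistic", c(scale = 17.43252, shape = 1.48925),
                      administrative_censor_time = 34, seed = 314)
  dig <- make_digitized(rec, coord_grid_step = 0.1, risk_interval = 3)
  ipd <- reconstruct_ipd(dig)
  fit <- fit_family(ipd, "loglogistic")
  expect_lt(abs(fit$params[["scale"]] - 17.43252) / 17.43252, 0.10)
  expect_lt(abs(fit$params[["shape"]] - 1.48925) / 1.48925, 0.10)
})

test_that("the reference configuration carries the published inputs", {
  cfg <- reference_config()
  expect_equal(unname(cfg$intervention$os_fit$params),
               c(17.43252, 1.48925))
  expect_equal(unname(cfg$comparator$os_fit$params), c(11.7162, 1.5699))
  expect_equal(cfg$inputs$u_pfs, 0.804)
  expect_equal(cfg$inputs$u_pd, 0.321)
  p <- cfg$params
  expect_equal(p$low[p$id == "u_pfs"], 0.724)
  expect_equal(p$high[p$id == "u_pfs"], 0.884)
  expect_equal(p$low[p$id == "u_pd"], 0.289)
  expect_equal(p$high[p$id == "u_pd"], 0.353)
  expect_equal(cfg$inputs$annual_discount_rate, 0.05)
  expect_equal(cfg$inputs$wtp_threshold, 257016)
  expect_equal(cfg$inputs$n_cycles, 208L)
  # the config survives a YAML round trip
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back$inputs, cfg$inputs)
  expect_equal(back$intervention$os_fit$params, cfg$intervention$os_fit$params)
  expect_equal(back$params, cfg$params)
})
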