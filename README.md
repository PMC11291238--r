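# psmcea

Partitioned-survival cost-effectiveness modelling from published
Kaplan-Meier curves, for health economists and HTA analysts who must work
without individual patient data.

When only the published survival figures of a trial are available, the
standard workflow is: digitize the Kaplan-Meier curves, reconstruct
pseudo-individual patient data with the Guyot algorithm, fit and
extrapolate parametric survival models, and feed the extrapolated curves
into a cohort model that accumulates discounted costs and quality-adjusted
life years (QALYs). `psmcea` implements the whole chain as a
tidyverse-style R package:

* **Curve reconstruction** — `read_digitized_curve()`, `reconstruct_ipd()`
  (Guyot interval balancing), `km_estimate()`.
* **Parametric survival** — `fit_family()` / `fit_all_families()` over
  exponential, Weibull, gamma, generalized gamma, Gompertz, log-logistic
  and log-normal; `select_best()` by AIC with BIC tie-break;
  `survival_at()` for extrapolation. The log-logistic convention is
  S(t) = 1 / (1 + (t/α)^β) with scale α = median (months).
* **Cohort engine** — a three-state model (progression-free, progressed,
  dead) over 208 three-week cycles, occupancy by the partitioned-survival
  identity PFS = min(S_pfs, S_os), PD = S_os − PFS, dead = 1 − S_os, with
  an equivalent transition-matrix view; discounted cost/QALY accumulation
  (`accumulate_outcomes()`), incremental results (`icer()`), exact-mg
  dosing arithmetic (`dosing_cost()`).
* **Uncertainty** — one-way sensitivity analysis with tornado ranking
  (`one_way_sa()`), moment-matched beta/gamma parameter distributions
  (`moment_match()`), second-order Monte Carlo PSA (`run_psa()`), and
  cost-effectiveness acceptability curves (`ceac()`).
* **Synthetic data** — `simulate_ipd()`, `make_digitized()`,
  `make_fixtures()` generate right-censored records and digitized-curve
  fixtures so every stage is testable offline.
* **Pipeline** — `run_analysis()` orchestrates reconstruct → fit → select
  → base case → OWSA → PSA → CEAC and writes CSV/JSON artifacts plus a
  run manifest.

The bundled reference configuration (`reference_config()`) is a
second-line comparison of tislelizumab versus docetaxel in advanced
non-small-cell lung cancer, with per-arm log-logistic OS/PFS parameters,
CNY costs, Chinese-population utilities, a 5% annual discount rate and a
willingness-to-pay threshold of 257,016 CNY/QALY (3× 2022 per-capita GDP).

## Worked example

```r
library(psmcea)

cfg <- reference_config()
res <- run_base_case(cfg)
tidy(res)
#> # A tibble: 2 × 6
#>   arm             cost qalys delta_cost delta_qalys    icer
#>   <chr>          <dbl> <dbl>      <dbl>       <dbl>   <dbl>
#> 1 tislelizumab 130019. 1.08      61520.       0.419 146893.
#> 2 docetaxel     68500. 0.660        NA       NA         NA
```

Read: under these inputs the tislelizumab arm accrues a discounted
130,019 CNY and 1.08 QALYs, docetaxel 68,500 CNY and 0.66 QALYs; the
incremental 61,520 CNY buys 0.419 QALYs, an ICER of 146,893 CNY per QALY
— below the 257,016 threshold, so cost-effective at the conventional
willingness to pay. (The published analysis this configuration mirrors
prints different per-arm totals that are not mutually consistent with its
own stated inputs; see the methods vignette's "Known limitations" for the
arithmetic.)

Uncertainty analysis:

```r
tor <- one_way_sa(cfg)          # tornado: BSC cost and PFS utility dominate
psa <- run_psa(cfg, n_draws = 5000, seed = 20240718)
prob_cost_effective(psa, c(100000, 257016, 500000))
#> [1] 0 1 1
autoplot(ceac(psa))             # acceptability curve, ggplot2
```

Full pipeline with all artifacts (traces, tornado, PSA draws, CEAC,
manifest) written to a directory:

```r
run_analysis(cfg, "results/", seed = 20240718, n_draws = 5000)
```

Starting from digitized curves instead of published parameters: point
`cfg$curves` at the coordinate/risk-table CSV pairs (the format of
`make_fixtures()`), and `run_analysis()` will reconstruct pseudo-IPD, fit
all seven families per arm and endpoint, select by AIC/BIC and carry the
winners into the economic model.

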