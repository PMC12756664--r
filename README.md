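# rdscreen

Sharp regression discontinuity (RD) analysis for threshold-triggered
health screening, with a seeded synthetic-cohort generator so the entire
pipeline is testable without any external data.

## The science

Many screening programs act deterministically on a measured variable: a
referral is issued exactly when baseline BMI reaches 25 kg/m². That rule
creates a natural experiment. People just below and just above the
cutoff are comparable in everything that varies smoothly with BMI, so a
jump in later outcomes at the cutoff estimates the causal effect of
being flagged.

`rdscreen` fits the standard sharp RD model

```
Y = a0 + a1*Above + a2*(X - c) + a3*Above*(X - c) + covariates + error
```

by triangular-kernel-weighted local linear (or quadratic) regression,
where `Above = 1` when `X >= c` (the boundary is treated). The jump
`a1` is the estimate of interest; inference uses HC1 sandwich standard
errors and conventional Wald intervals. Around that core the package
provides:

- **Synthetic cohorts** (`simulate_cohort()`, `sim_config()`): seeded,
  BMI-like right-skewed running variable, polynomial outcome surfaces
  with an injectable discontinuity, covariates, binary outcomes on a
  log-risk scale, differential attrition, and optional bunching at the
  cutoff for manipulation studies.
- **Bandwidth selection** (`select_bandwidth()`): a documented plug-in
  selector in the Imbens–Kalyanaraman style.
- **Validity diagnostics**: McCrary-style density discontinuity test,
  covariate balance with Wilson intervals, covariate placebo RDs, and
  an attrition continuity test.
- **Robustness batteries**: placebo cutoffs, donut RD, bandwidth
  sensitivity, age-coding sensitivity, and a 2 (polynomial order) × 5
  (covariate set) estimate grid.
- **Binary outcomes** (`fit_binary_rd()`): risk ratios at the cutoff by
  modified Poisson regression with robust variance.
- **Heterogeneity and power** (`interaction_rd()`, `estimate_power()`):
  subgroup jumps with a joint Wald test, and simulation-based power.
- **Reporting** (`run_report()`, `plot_rd()`, plus a command-line entry
  point in `inst/cli/rdscreen.R`).

See `vignettes/rdscreen-methods.Rmd` for the full methodology.

## Worked example

Simulate a cohort with a true jump of 0.8 BMI units at the cutoff, then
estimate it:

```r
library(rdscreen)

cohort <- simulate_cohort(sim_config(n_subjects = 6561, tau = 0.8, seed = 7))

fit <- fit_sharp_rd(cohort, "bmi_change",
                    rd_spec(bandwidth = 2.9,
                            covariates = c("age_group", "sex")))
fit
#> Sharp RD fit: bmi_change  (order 1, triangular kernel, h = 2.9, cutoff = 25)
#>   tau = 0.8002  (SE 0.1508, 95% CI 0.5048 to 1.096, p = 1.11e-07)
#>   n: 848 below / 876 above cutoff; covariates: age_group, sex
```

The injected 0.8 jump is recovered. Check that the running variable
shows no manipulation, and that the estimate is stable across
bandwidths:

```r
density_discontinuity_test(cohort$x)
#> Running-variable density test [McCrary-style binned local linear]
#>   f(left) = 0.09504, f(right) = 0.1024 at cutoff 25
#>   log difference = 0.0747 (SE 0.1078), p = 0.488

bandwidth_sensitivity(cohort, "bmi_change", rd_spec(bandwidth = 2.9))
#> # A tibble: 5 × 14
#>   multiplier outcome  tau_hat    se ci_low ci_high  p_value n_left n_right     h
#>        <dbl> <chr>      <dbl> <dbl>  <dbl>   <dbl>    <dbl>  <int>   <int> <dbl>
#> 1        0.5 bmi_cha…   0.922 0.208  0.515    1.33 8.96e- 6    424     522  1.45
#> 2        0.8 bmi_cha…   0.848 0.165  0.525    1.17 2.69e- 7    692     754  2.32
#> 3        1   bmi_cha…   0.795 0.149  0.503    1.09 9.82e- 8    848     876  2.9
#> 4        1.2 bmi_cha…   0.790 0.137  0.521    1.06 8.21e- 9    972    1015  3.48
#> 5        1.5 bmi_cha…   0.820 0.124  0.577    1.06 3.61e-11   1166    1167  4.35
```

A data-driven bandwidth is available with
`select_bandwidth(cohort, "bmi_change")`, `fit_rd_grid()` produces the
full order-by-covariate-set grid, and `run_report()` writes every table
and diagnostic for one cohort into a directory. The same pipeline is
scriptable from the shell:

```sh
Rscript inst/cli/rdscreen.R simulate --seed 42 --n 6561 --out out/cohort.csv
Rscript inst/cli/rdscreen.R report --data out/cohort.csv \
    --outcome bmi_change --bandwidth 2.9 --out out/report
```

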