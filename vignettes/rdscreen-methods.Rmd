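---
title: "Methods: sharp regression discontinuity for threshold-triggered screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sharp regression discontinuity for threshold-triggered screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdscreen)
```

## Setting and model

`rdscreen` implements a sharp regression discontinuity (RD) analysis for
health-screening programs in which an intervention is triggered
deterministically by a measured variable crossing a fixed threshold — the
motivating case is a referral issued whenever baseline BMI is at or above
25 kg/m². Because assignment is a deterministic function of the running
variable $X$, subjects just below and just above the cutoff $c$ are
comparable, and the jump in the conditional outcome mean at $c$ identifies
the local effect of crossing the threshold.

The estimating equation is the standard local linear (optionally local
quadratic) specification in centered coordinates:

$$
Y_i = \alpha_0 + \alpha_1 \, \text{Above}_i
    + \alpha_2 (X_i - c) + \alpha_3 \, \text{Above}_i (X_i - c)
    + X_i^{\top}\kappa + v_i,
$$

with $\text{Above}_i = \mathbf{1}\{X_i \ge c\}$ — the boundary itself is
treated, matching how a referral rule is applied in practice. The target
parameter is $\alpha_1$, the discontinuity at $c$. Key structural
choices:

- **Separate slopes per side.** The interaction
  $\text{Above}_i (X_i - c)$ lets the running-variable slope differ
  across the cutoff, so the jump is not contaminated by slope
  differences.
- **Additive covariates with a shared intercept.** Optional covariates
  enter linearly and are never interacted with side. They are a
  precision device, not an identification device; categorical covariates
  expand to indicator columns against the first (sorted) level, and rows
  with missing covariate values are dropped listwise with the dropped
  count recorded on the fit.
- **Kernel-weighted fit.** Observations are weighted by a triangular
  kernel $w_i = \max(0, 1 - |X_i - c|/h)$ (a uniform kernel is available
  as an option), so the fit is local to the cutoff. The same bandwidth
  $h$ is used on both sides: the design is symmetric, and a common $h$
  keeps the estimate a simple contrast of two boundary regressions.

## Inference

Standard errors default to the heteroskedasticity-consistent HC1 sandwich
computed on the weighted regression, with classical model-based errors
available via `se_type = "classical"`. Confidence intervals and p-values
are conventional Wald intervals based on the normal reference
distribution; no bias-corrected robust intervals are produced. This is a
deliberate simplification: conventional Wald inference is transparent and
matches common applied practice, but it ignores smoothing bias, which is
why the package ships a bandwidth-sensitivity battery
(`bandwidth_sensitivity()`, `donut_rd()`, `placebo_cutoff_scan()`) rather
than a single headline interval. The Monte-Carlo calibration in the test
suite checks that, under the package's own generative model with a linear
mean function, the 95% interval covers the truth at close to nominal
rate.

## Bandwidth selection

`select_bandwidth()` implements a documented plug-in selector in the
Imbens–Kalyanaraman style rather than wrapping an external optimizer, so
that every constant is visible and testable:

1. pilot bandwidth $h_1 = 1.84 \,\hat\sigma_x\, n^{-1/5}$;
2. density at the cutoff estimated by the share of observations within
   $h_1$ of $c$, divided by $2 h_1$;
3. side-specific residual variances from linear fits inside the pilot
   windows;
4. curvature on each side from global cubic fits
   ($\hat m_2 = 2 \hat\beta_2$);
5. regularization terms $r = 2160\, \hat\sigma^2 / (n_{\text{pilot}}
   h_1^4)$ guarding against near-zero curvature;
6. $h_{\text{opt}} = 3.4375 \left[ \frac{\hat\sigma_l^2 +
   \hat\sigma_r^2}{\hat f(c)\left((\hat m_{2,r} - \hat m_{2,l})^2 + r_l +
   r_r\right)} \right]^{1/5} n^{-1/5}$.

The selector is shift-invariant and scale-equivariant by construction
(both properties are asserted in the tests), and shrinks at the
$n^{-1/5}$ rate. `scale_bandwidth()` produces exact multiples for
sensitivity analyses.

## Validity diagnostics

- **Manipulation of the running variable.** `density_discontinuity_test()`
  is a binned local-linear density test in the McCrary style: histogram
  bins of width $2\hat\sigma_x n^{-1/2}$ with an edge aligned at the
  cutoff, side-specific triangular-kernel local linear smooths of the
  normalized bin heights evaluated at $c$, and a Wald test of
  $\theta = \log \hat f_r(c) - \log \hat f_l(c)$ with
  $\mathrm{SE}(\theta) = \sqrt{\tfrac{24}{5}\left(\tfrac{1}{\hat f_r} +
  \tfrac{1}{\hat f_l}\right)/(n h)}$.
- **Covariate balance.** `balance_table()` reports per-level proportions
  on each side of the cutoff within the analysis window with Wilson score
  intervals (preferred over Wald intervals for proportions near 0 or 1),
  and a chi-square test per covariate that switches to Fisher's exact
  test when any expected cell count falls below 5.
- **Covariate placebos.** `covariate_placebo_rd()` re-runs the RD
  estimator with a predetermined covariate as the outcome; a
  discontinuity there would indicate sorting.
- **Attrition.** `attrition_continuity_test()` fits the RD model to the
  follow-up indicator at several bandwidth multiples. A level difference
  in follow-up between sides is compatible with validity; a local jump at
  the cutoff is not, and the test targets only the latter.

## Binary outcomes

For binary outcomes, `fit_binary_rd()` estimates a risk ratio via a
modified Poisson regression: log-link Poisson estimating equations solved
by iteratively reweighted least squares with the kernel weights entering
as prior weights, and a robust sandwich variance (the standard remedy for
the Poisson variance being misspecified for 0/1 data). The discontinuity
is reported as $\mathrm{rr} = \exp(\hat\alpha_1)$. With data collapsed to
one support point per side, `slope_terms = FALSE` drops the collinear
slope columns and the estimator reduces exactly to the 2×2 ratio of side
means, which the tests verify. Fitted risks above 1 are flagged on the
result. Physical activity is dichotomized by the conventional
`classify_activity()` rule (≥ 600 MET-minutes/week).

## The synthetic cohort generator

All estimation code is exercised against `simulate_cohort()`, a seeded
generator whose structure mirrors the assumed data-generating process:

- **Running variable**: lognormal with `meanlog = log(24.5)` and
  `sdlog = 0.1602`, giving a right-skewed BMI-like distribution with
  median 24.5 and standard deviation near 4 — mass concentrated around
  the cutoff, as in a community adult cohort. The density is continuous
  at the cutoff by construction; `bunching_mass` relocates a stated
  fraction of just-below-cutoff subjects to just above it to create
  detectable manipulation for power studies of the density test.
- **Outcomes**: side-specific polynomial mean functions in $X - c$, plus
  $\tau \cdot \text{Above}$, plus Gaussian noise. The default
  `noise_sd = 1.5` was fixed before any calibration experiments as a
  plausible standard deviation for three-year BMI change; it is a
  generator default, not a fitted quantity.
- **Binary outcomes**: log-risk intercept, slope in $X - c$, and log-risk
  jump at the cutoff; configurations implying risk above 1 raise an
  error rather than clipping silently.
- **Covariates**: categorical marginals loosely emulating a Southeast
  Asian community cohort (about 40% male, mostly married, predominantly
  one ethnic group, modest smoking prevalence), with optional smooth or
  discontinuous dependence on $X$ for placebo studies.
- **Attrition**: per-side follow-up probabilities (defaults 0.461 below
  and 0.546 above, a realistic differential) with an optional smooth
  dependence on $X$; outcomes of non-followed subjects are set to
  missing, never fabricated, and rows are kept so attrition itself can
  be analyzed.
- **Determinism**: one integer seed controls the whole draw, and the
  draw order (running variable, bunching, covariates, continuous
  outcomes, binary outcomes, attrition) is fixed, so cohorts are
  reproducible byte-for-byte through the CSV round trip.

The default cohort size of 6561 and the default analysis bandwidth of
2.9 (window 22.1–27.9) reflect the scale of the motivating screening
setting and are the sizes at which the package's Monte-Carlo checks are
run; both are ordinary arguments.

## Heterogeneity and power

`interaction_rd()` fully interacts the RD design with a categorical
subgroup: each estimable level gets its own intercept, jump, and side
slopes, while any additive adjustment covariates remain shared. Levels
with too few observations on either side are excluded and reported with
missing estimates rather than silently dropped. Equality of the
subgroup jumps is tested with a joint Wald chi-square on the $L-1$
contrasts against the first level.

`estimate_power()` estimates rejection rates by simulation: for each
effect size in `tau_grid` it draws `replicates` cohorts (at least 100)
with deterministic per-replicate seeds derived from the master seed,
fits the RD model, and reports the rejection frequency with its binomial
Monte-Carlo standard error. Replicates whose fit fails count as
non-rejections and are tallied in `n_failed`.

## Numerical choices

- The weighted least-squares solve uses R's QR path (`lm.wfit`); the
  sandwich pieces are computed explicitly from the weighted design. The
  tests include a brute-force normal-equations oracle agreeing to 1e-8.
- Exact collinearity in a requested design is an error naming the
  offending columns, not a silent drop.
- The IRLS loop for the modified Poisson estimator caps at 100
  iterations with a 1e-8 convergence tolerance and checks for outcome
  separation per side before iterating.
- YAML configuration round trips (`write_sim_config()` /
  `read_sim_config()`) serialize numerics at 17 significant digits so a
  written config reproduces the identical cohort.

## Limitations

- Conventional Wald intervals ignore smoothing bias; results should be
  read alongside the bandwidth-sensitivity and donut batteries.
- The plug-in bandwidth selector follows a documented recipe but is not
  a re-implementation of any specific published software; constants
  differ from other implementations in regularization details.
- The generator's covariates are drawn independently of each other given
  $X$; real cohorts have correlated covariates, which matters only for
  studies of the balance machinery, not for the estimator itself.
- Sharp RD identifies a local effect at the cutoff; nothing here
  extrapolates away from $c$, and no fuzzy-RD (imperfect compliance)
  machinery is provided.
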