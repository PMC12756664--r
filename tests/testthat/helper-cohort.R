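# Shared fixtures: all cohorts are generated in code at test time.

# Brute-force weighted-least-squares oracle: direct normal-equations solve,
# independent of the package's QR-based path.
oracle_wls <- function(X, y, w) {
  XtWX <- t(X) %*% (X * w)
  drop(solve(XtWX, t(X) %*% (w * y)))
}

# Minimal cohort config: no covariates, no attrition, linear means.
plain_cfg <- function(n, seed, tau = 0, noise_sd = 1.5,
                      slope = 0.5, ...) {
  sim_config(n_subjects = n, seed = seed, tau = tau, noise_sd = noise_sd,
             mean_fn_left = c(0, slope), mean_fn_right = c(0, slope),
             covariate_spec = list(),
             attrition_spec = list(p_left = 1, p_right = 1), ...)
}

# Random small analysis table for oracle comparisons.
random_table <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    x = runif(n, 21, 29),
    y = rnorm(n, 0.3 * (runif(n) - 0.5), 1),
    z = rnorm(n),
    grp = sample(c("a", "b", "c"), n, replace = TRUE)
  )
}
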