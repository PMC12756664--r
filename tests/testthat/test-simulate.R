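test_that("degenerate noiseless null gives exactly zero outcomes", {
  cfg <- sim_config(n_subjects = 50, tau = 0, noise_sd = 0,
                    mean_fn_left = 0, mean_fn_right = 0,
                    covariate_spec = list(),
                    attrition_spec = list(p_left = 1, p_right = 1), seed = 3)
  coh <- simulate_cohort(cfg)
  expect_true(all(coh$bmi_change == 0))
})

test_that("injected discontinuity appears exactly at the cutoff under zero noise", {
  cfg <- plain_cfg(500, seed = 4, tau = 0.8, noise_sd = 0)
  coh <- simulate_cohort(cfg)
  resid <- coh$bmi_change - 0.5 * (coh$x - 25)
  expect_equal(unname(resid[coh$above == 0]), rep(0, sum(coh$above == 0)))
  expect_equal(unname(resid[coh$above == 1]), rep(0.8, sum(coh$above == 1)),
               tolerance = 1e-12)
})

test_that("identical config and seed reproduce a byte-identical CSV", {
  cfg <- sim_config(n_subjects = 120, seed = 11,
                    binary_outcome_spec = list(
                      smoker_now = list(intercept = log(0.15), slope = 0,
                                        jump = 0)))
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(a, f1); write_cohort(b, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("cohort CSV round trip is lossless and restores the cutoff", {
  coh <- simulate_cohort(sim_config(n_subjects = 80, seed = 21, cutoff = 23))
  f <- tempfile(fileext = ".csv")
  write_cohort(coh, f)
  back <- read_cohort(f)
  expect_equal(attr(back, "cutoff"), 23)
  expect_equal(as.data.frame(back), as.data.frame(coh))
})

test_that("side means track the configured mean functions", {
  cfg <- plain_cfg(8000, seed = 8, tau = 0, noise_sd = 1.0)
  coh <- simulate_cohort(cfg)
  for (side in 0:1) {
    xs <- coh$x[coh$above == side]
    ys <- coh$bmi_change[coh$above == side]
    expect_lt(abs(mean(ys) - mean(0.5 * (xs - 25))),
              3 * 1.0 / sqrt(length(ys)))
  }
})

test_that("realized attrition stays inside binomial 99% bounds per side", {
  cfg <- sim_config(n_subjects = 6000, seed = 13, covariate_spec = list(),
                    attrition_spec = list(p_left = 0.461, p_right = 0.546))
  coh <- simulate_cohort(cfg)
  for (side in 0:1) {
    p <- if (side == 0) 0.461 else 0.546
    n <- sum(coh$above == side)
    frac <- mean(coh$followed_up[coh$above == side])
    half <- qnorm(0.995) * sqrt(p * (1 - p) / n)
    expect_lt(abs(frac - p), half)
  }
  # outcomes of non-followed rows are missing, rows themselves kept
  expect_equal(nrow(coh), 6000)
  expect_true(all(is.na(coh$bmi_change[coh$followed_up == 0])))
  expect_true(all(!is.na(coh$bmi_change[coh$followed_up == 1])))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(sim_config(n_subjects = 0), "n_subjects")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(bunching_mass = 1), "bunching_mass")
  expect_error(sim_config(attrition_spec = list(p_left = 1.2, p_right = 0.5)),
               "attrition_spec")
  expect_error(sim_config(rv_distribution = list(family = "gamma")),
               "rv_distribution")
})

test_that("binary configurations implying risk above 1 error instead of clipping", {
  cfg <- sim_config(n_subjects = 200, seed = 5, covariate_spec = list(),
                    binary_outcome_spec = list(
                      bad = list(intercept = log(0.9), slope = 0.5, jump = 0)))
  expect_error(simulate_cohort(cfg), "risk > 1")
})

test_that("manipulation injection moves the stated fraction across the cutoff", {
  set.seed(99)
  tb <- tibble::tibble(x = runif(4000, 23, 27))
  tb$above <- assign_treatment(tb$x, 25)
  before_lo <- sum(tb$x >= 24.5 & tb$x < 25)
  before_hi <- sum(tb$x >= 25 & tb$x <= 25.5)
  out <- inject_manipulation(tb, mass = 0.5, width = 0.5, cutoff = 25)
  moved <- round(0.5 * before_lo)
  expect_equal(sum(out$x >= 24.5 & out$x < 25), before_lo - moved)
  expect_equal(sum(out$x >= 25 & out$x <= 25.5), before_hi + moved)
  expect_true(all(out$above == assign_treatment(out$x, 25)))
  # zero mass is the identity
  expect_identical(inject_manipulation(tb, 0, 0.5, 25), tb)
  # empty donor stratum errors rather than silently no-op
  hi_only <- tibble::tibble(x = runif(50, 26, 27),
                            above = rep(1L, 50))
  expect_error(inject_manipulation(hi_only, 0.3, 0.5, 25), "no subjects")
})

test_that("age bins follow the 35-39/40-49/50-59/60-69/70+ convention", {
  expect_equal(categorize_age(c(35, 39, 40, 49.9, 50, 69, 70, 88)),
               c("35-39", "35-39", "40-49", "40-49", "50-59", "60-69",
                 "70+", "70+"))
})

test_that("sim_config round-trips through YAML", {
  cfg <- sim_config(n_subjects = 300, seed = 17, tau = 0.4,
                    mean_fn_left = c(0.1, 0.3), mean_fn_right = c(0.1, 0.3))
  f <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, f)
  back <- read_sim_config(f)
  expect_identical(simulate_cohort(back), simulate_cohort(cfg))
})
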