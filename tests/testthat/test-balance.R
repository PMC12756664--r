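make_window_table <- function(n_above, n_below, k_above, k_below,
                              level = c("male", "female")) {
  # exact within-window composition: side sizes and level counts as given
  tibble::tibble(
    x = c(runif(n_below, 22.1, 24.99), runif(n_above, 25, 27.9)),
    sex = c(rep(level, c(k_below, n_below - k_below)),
            rep(level, c(k_above, n_above - k_above)))
  )
}

test_that("balance percentages and differences reproduce printed-count arithmetic", {
  set.seed(1)
  # side sizes 1568 above / 1456 below with 671 and 680 males respectively
  tb <- make_window_table(1568, 1456, 671, 680)
  bal <- balance_table(tb, rd_spec(bandwidth = 2.9), "sex")
  male <- bal[bal$level == "male", ]
  expect_equal(round(male$prop_above, 1), 42.8)
  expect_equal(round(male$prop_below, 1), 46.7)
  expect_equal(round(male$difference, 1), -3.9)
  # Wilson CI matches the printed interval to a tenth of a point
  expect_lt(abs(male$ci_low_above - 40.4), 0.15)
  expect_lt(abs(male$ci_high_above - 45.3), 0.15)
  # per-side percentages sum to 100 per covariate
  sums <- as.numeric(tapply(bal$prop_above, bal$covariate, sum))
  expect_equal(sums, rep(100, length(sums)), tolerance = 1e-9)
  expect_equal(as.numeric(tapply(bal$prop_below, bal$covariate, sum)),
               rep(100, length(sums)), tolerance = 1e-9)
})

test_that("test choice switches to exact when expected counts are small", {
  set.seed(2)
  tb <- tibble::tibble(
    x = runif(600, 23, 27),
    common = sample(c("a", "b"), 600, replace = TRUE),
    rare = sample(c("a", "b"), 600, replace = TRUE, prob = c(0.005, 0.995)),
    single = "only"
  )
  bal <- balance_table(tb, rd_spec(bandwidth = 2.9),
                       c("common", "rare", "single"))
  expect_equal(unique(bal$test[bal$covariate == "common"]), "chi-square")
  expect_equal(unique(bal$test[bal$covariate == "rare"]), "fisher")
  expect_match(unique(bal$test[bal$covariate == "single"]), "single level")
  expect_true(is.na(unique(bal$test_p[bal$covariate == "single"])))
})

test_that("balance p-values are uniform when the covariate is independent of side", {
  ps <- numeric(200)
  for (i in 1:200) {
    set.seed(6000 + i)
    tb <- tibble::tibble(x = runif(500, 22.5, 27.5),
                         g = sample(c("u", "v"), 500, replace = TRUE))
    ps[i] <- balance_table(tb, rd_spec(bandwidth = 2.9), "g")$test_p[1]
  }
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("covariate placebo RD is exact for constants and recovers injected jumps", {
  coh <- simulate_cohort(plain_cfg(3000, seed = 47))
  coh$always <- "same"
  f0 <- covariate_placebo_rd(coh, rd_spec(bandwidth = 2.9), "always",
                             level = "same")
  expect_equal(f0$tau_hat, 0, tolerance = 1e-12)
  # a 0.10 jump in level probability at the cutoff is recovered
  cfg <- sim_config(n_subjects = 20000, seed = 53,
                    covariate_spec = list(
                      flag = list(type = "categorical",
                                  levels = c("yes", "no"),
                                  probs = c(0.3, 0.7), jump = 0.10)),
                    attrition_spec = list(p_left = 1, p_right = 1))
  coh2 <- simulate_cohort(cfg)
  f1 <- covariate_placebo_rd(coh2, rd_spec(bandwidth = 2.9), "flag",
                             level = "yes")
  expect_lt(abs(f1$tau_hat - 0.10), 2 * f1$se)
  # continuous covariates are used directly
  f2 <- covariate_placebo_rd(coh, rd_spec(bandwidth = 2.9), "x")
  expect_s3_class(f2, "rd_fit")
})

test_that("attrition continuity separates level differences from local jumps", {
  # full follow-up: estimate is exactly zero
  coh <- simulate_cohort(plain_cfg(2000, seed = 61))
  res0 <- attrition_continuity_test(coh, rd_spec(bandwidth = 2.9))
  expect_equal(nrow(res0), 3)
  expect_equal(res0$multiplier, c(1, 0.5, 1.5))
  expect_equal(res0$tau_hat, rep(0, 3), tolerance = 1e-10)
  # smooth-in-x follow-up with different side means but no jump at the cutoff
  cfg <- sim_config(n_subjects = 8000, seed = 67, covariate_spec = list(),
                    attrition_spec = list(p_left = 0.5, p_right = 0.5,
                                          x_slope = 0.02))
  coh2 <- simulate_cohort(cfg)
  lo <- mean(coh2$followed_up[coh2$above == 0])
  hi <- mean(coh2$followed_up[coh2$above == 1])
  expect_gt(hi - lo, 0.03)  # marginal imbalance is real...
  res <- attrition_continuity_test(coh2, rd_spec(bandwidth = 2.9))
  expect_true(all(res$p_value > 0.05))  # ...but there is no local discontinuity
  # missing follow-up flags are refused
  coh2$followed_up[1] <- NA
  expect_error(attrition_continuity_test(coh2, rd_spec(bandwidth = 2.9)),
               "every baseline row")
})
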