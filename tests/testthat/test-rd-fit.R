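test_that("treatment assignment is sharp with the boundary on the treated side", {
  expect_equal(assign_treatment(25.0, 25), 1L)
  expect_equal(assign_treatment(24.999, 25), 0L)
  expect_equal(assign_treatment(27.9, 25), 1L)
  expect_equal(assign_treatment(c(24, 25, 26), 25), c(0L, 1L, 1L))
  expect_error(assign_treatment(NA_real_, 25), "finite")
})

test_that("triangular kernel has unit mode, linear decay and compact support", {
  expect_equal(triangular_weights(25, 25, 2.9), 1)
  expect_equal(triangular_weights(25 + 2.9, 25, 2.9), 0)
  expect_equal(triangular_weights(25 - 2.9 / 2, 25, 2.9), 0.5)
  expect_equal(triangular_weights(35, 25, 2.9), 0)
  expect_error(triangular_weights(25, 25, 0), "positive")
})

test_that("fit matches the brute-force normal-equations oracle on random tables", {
  for (i in 1:25) {
    tb <- random_table(60 + i, seed = 100 + i)
    for (ord in 1:2) {
      spec <- rd_spec(bandwidth = 3.5, order = ord,
                      covariates = if (i %% 2 == 0) c("z", "grp") else character())
      fit <- fit_sharp_rd(tb, "y", spec)
      xc <- tb$x - 25
      w <- pmax(0, 1 - abs(xc) / 3.5)
      keep <- w > 0
      A <- as.numeric(xc[keep] >= 0)
      X <- cbind(1, A, xc[keep], A * xc[keep])
      if (ord == 2) X <- cbind(X, xc[keep]^2, A * xc[keep]^2)
      if (i %% 2 == 0) {
        X <- cbind(X, tb$z[keep],
                   as.numeric(tb$grp[keep] == "b"),
                   as.numeric(tb$grp[keep] == "c"))
      }
      b <- oracle_wls(X, tb$y[keep], w[keep])
      expect_equal(unname(fit$coefficients), unname(b), tolerance = 1e-8)
    }
  }
})

test_that("covariate-free estimate equals the two-side intercept difference", {
  tb <- random_table(150, seed = 7)
  spec <- rd_spec(bandwidth = 3, order = 1)
  fit <- fit_sharp_rd(tb, "y", spec)
  side_intercept <- function(side) {
    xc <- tb$x - 25
    w <- pmax(0, 1 - abs(xc) / 3)
    keep <- w > 0 & (if (side == 1) xc >= 0 else xc < 0)
    oracle_wls(cbind(1, xc[keep]), tb$y[keep], w[keep])[1]
  }
  expect_equal(fit$tau_hat, side_intercept(1) - side_intercept(0),
               tolerance = 1e-10)
})

test_that("noiseless discontinuity is recovered exactly and constant outcomes give zero", {
  coh <- simulate_cohort(plain_cfg(2000, seed = 31, tau = 0.8, noise_sd = 0))
  fit <- fit_sharp_rd(coh, "bmi_change", rd_spec(bandwidth = 2.9))
  expect_equal(fit$tau_hat, 0.8, tolerance = 1e-8)
  coh$flat <- 2
  f0 <- fit_sharp_rd(coh, "flat", rd_spec(bandwidth = 2.9))
  expect_equal(f0$tau_hat, 0, tolerance = 1e-10)
  expect_equal(unname(f0$coefficients[c("xc", "above:xc")]), c(0, 0),
               tolerance = 1e-10)
})

test_that("estimates are translation invariant in x and scale equivariant in y", {
  tb <- random_table(200, seed = 55)
  spec <- rd_spec(bandwidth = 3)
  f1 <- fit_sharp_rd(tb, "y", spec)
  shifted <- tb; shifted$x <- shifted$x + 7
  spec2 <- spec; spec2$cutoff <- 32
  f2 <- fit_sharp_rd(shifted, "y", spec2)
  expect_equal(f1$tau_hat, f2$tau_hat, tolerance = 1e-10)
  scaled <- tb; scaled$y <- 3 * scaled$y
  f3 <- fit_sharp_rd(scaled, "y", spec)
  expect_equal(f3$tau_hat, 3 * f1$tau_hat)
  expect_equal(f3$se, 3 * f1$se)
})

test_that("HC1 variance agrees with the sandwich package on the weighted fit", {
  skip_if_not_installed("sandwich")
  tb <- random_table(180, seed = 61)
  spec <- rd_spec(bandwidth = 3, covariates = "z")
  fit <- fit_sharp_rd(tb, "y", spec)
  xc <- tb$x - 25
  w <- pmax(0, 1 - abs(xc) / 3)
  d <- tb[w > 0, ]; wk <- w[w > 0]
  d$xc <- d$x - 25; d$A <- as.numeric(d$xc >= 0)
  lmfit <- lm(y ~ A + xc + A:xc + z, data = d, weights = wk)
  V <- sandwich::vcovHC(lmfit, type = "HC1")
  expect_equal(fit$se, unname(sqrt(V["A", "A"])), tolerance = 1e-8)
  expect_equal(fit$tau_hat, unname(coef(lmfit)["A"]), tolerance = 1e-10)
})

test_that("degenerate designs fail with informative errors", {
  tb <- random_table(100, seed = 71)
  tb$z2 <- tb$z  # exact duplicate column
  expect_error(fit_sharp_rd(tb, "y", rd_spec(bandwidth = 3,
                                             covariates = c("z", "z2"))),
               "collinear")
  tiny <- tibble::tibble(x = c(24.9, 25.1), y = c(1, 2))
  expect_error(fit_sharp_rd(tiny, "y", rd_spec(bandwidth = 1)),
               "too few")
  expect_error(fit_sharp_rd(tb, "nope", rd_spec(bandwidth = 3)), "nope")
  expect_error(fit_sharp_rd(tb, "y", rd_spec(bandwidth = 3,
                                             covariates = "missing_cov")),
               "missing_cov")
})

test_that("the estimate grid is 2 x 5 and isolates per-cell failures", {
  coh <- simulate_cohort(sim_config(n_subjects = 2500, seed = 41, tau = 0.8,
                                    noise_sd = 0,
                                    attrition_spec = list(p_left = 1,
                                                          p_right = 1)))
  g <- fit_rd_grid(coh, "bmi_change", rd_spec(bandwidth = 2.9))
  expect_equal(nrow(g), 10)
  expect_equal(sort(unique(g$order)), c(1L, 2L))
  expect_equal(length(unique(g$covariate_set)), 5)
  expect_true(all(is.na(g$error)))
  expect_equal(g$tau_hat, rep(0.8, 10), tolerance = 1e-8)
  # a failing cell reports its error without aborting the others
  sets <- list(none = character(), broken = "no_such_column")
  g2 <- fit_rd_grid(coh, "bmi_change", rd_spec(bandwidth = 2.9),
                    covariate_sets = sets)
  expect_equal(nrow(g2), 4)
  expect_true(all(!is.na(g2$error[g2$covariate_set == "broken"])))
  expect_true(all(is.na(g2$error[g2$covariate_set == "none"])))
})

test_that("tidy and glance expose the fit in broom style", {
  coh <- simulate_cohort(plain_cfg(800, seed = 91, tau = 0.3))
  fit <- fit_sharp_rd(coh, "bmi_change", rd_spec(bandwidth = 2.9))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_setequal(names(td),
                  c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_true("above" %in% td$term)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$ci_low <= gl$tau_hat && gl$tau_hat <= gl$ci_high)
  expect_gte(gl$n_left, 2)
  expect_gte(gl$n_right, 2)
  expect_true(gl$p_value >= 0 && gl$p_value <= 1)
})
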