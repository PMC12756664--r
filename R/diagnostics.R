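#' Density manipulation test at the cutoff (McCrary-style)
#'
#' Tests whether the running-variable density is continuous at the cutoff,
#' the key observable symptom of manipulation (e.g. recorders nudging
#' borderline BMI values over the referral threshold). Two steps:
#'
#' 1. an undersmoothed histogram with bin width `2 * SD(x) * n^(-1/2)` and
#'    edges aligned so no bin straddles the cutoff;
#' 2. side-specific triangular-kernel local linear regressions of the
#'    normalized bin heights on bin midpoints, evaluated at the cutoff,
#'    using the pilot-rule bandwidth `1.84 * SD(x) * n^(-1/5)`.
#'
#' The statistic is the log-density difference
#' `log f_right - log f_left`, with the asymptotic standard error
#' `sqrt((24/5) * (1/f_right + 1/f_left) / (n * h))` and a normal-
#' approximation p-value.
#'
#' @param x Running-variable values (at least 50 per side).
#' @param cutoff Cutoff value (default 25).
#' @return A `density_test` object: `f_left`, `f_right` (density per
#'   running-variable unit), `log_diff`, `se_log_diff`, `p_value`, and the
#'   `binning` used.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_subjects = 5000, seed = 11))
#' density_discontinuity_test(cohort$x)
density_discontinuity_test <- function(x, cutoff = 25) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (sum(x < cutoff) < 50 || sum(x >= cutoff) < 50) {
    stop("need at least 50 observations on each side of the cutoff",
         call. = FALSE)
  }
  b <- 2 * sd(x) * n^(-1 / 2)
  lo <- floor((min(x) - cutoff) / b) - 1
  hi <- ceiling((max(x) - cutoff) / b) + 1
  edges <- cutoff + b * (lo:hi)
  counts <- tabulate(findInterval(x, edges, rightmost.closed = FALSE),
                     nbins = length(edges) - 1)
  mids <- edges[-length(edges)] + b / 2
  heights <- counts / (n * b)

  h <- 1.84 * sd(x) * n^(-1 / 5)
  local_density <- function(side_mask) {
    w <- triangular_weights(mids, cutoff, h) * side_mask
    use <- w > 0
    if (sum(use) < 2) {
      stop("too few histogram bins inside the bandwidth on one side",
           call. = FALSE)
    }
    X <- cbind(1, mids[use] - cutoff)
    unname(lm.wfit(X, heights[use], w[use])$coefficients[1])
  }
  f_left <- local_density(mids < cutoff)
  f_right <- local_density(mids >= cutoff)
  if (f_left <= 0 || f_right <= 0) {
    stop(sprintf(
      "non-positive boundary density estimate (left %.3g, right %.3g)",
      f_left, f_right), call. = FALSE)
  }
  log_diff <- log(f_right) - log(f_left)
  se <- sqrt((24 / 5) * (1 / f_right + 1 / f_left) / (n * h))
  structure(
    list(f_left = f_left, f_right = f_right,
         log_diff = log_diff, se_log_diff = se,
         statistic = log_diff / se,
         p_value = 2 * pnorm(-abs(log_diff / se)),
         binning = list(bin_width = b, n_bins = length(mids), bandwidth = h,
                        first_edge = edges[1]),
         n = n, cutoff = cutoff,
         method_label = "McCrary-style binned local linear"),
    class = "density_test"
  )
}

#' @export
print.density_test <- function(x, ...) {
  cat(sprintf("Running-variable density test [%s]\n", x$method_label))
  cat(sprintf("  f(left) = %.4g, f(right) = %.4g at cutoff %g\n",
              x$f_left, x$f_right, x$cutoff))
  cat(sprintf("  log difference = %.4g (SE %.4g), p = %.3g\n",
              x$log_diff, x$se_log_diff, x$p_value))
  invisible(x)
}

wilson_ci <- function(k, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(low = center - half, high = center + half)
}

#' Covariate balance across the cutoff within the bandwidth
#'
#' For each categorical covariate, the side-specific level percentages
#' (with Wilson 95% CIs) and their difference within the analysis window
#' `[c - h, c + h]`, plus one test per covariate: chi-square, switching to
#' Fisher's exact test when any expected cell count is below 5. A covariate
#' with a single observed level is flagged, not tested.
#'
#' @param data Cohort tibble.
#' @param spec An [rd_spec()] with a set bandwidth.
#' @param covariates Character vector of categorical covariate columns.
#' @return Tibble with one row per covariate level: `covariate`, `level`,
#'   `n_above`, `prop_above`, `ci_low_above`, `ci_high_above`, the same for
#'   below, `difference` (percentage points, above minus below), `test`
#'   and `test_p` (repeated within covariate).
#' @export
balance_table <- function(data, spec = rd_spec(bandwidth = 2.9),
                          covariates) {
  if (is.null(spec$bandwidth)) {
    stop("balance_table needs a spec with a set bandwidth", call. = FALSE)
  }
  c0 <- spec$cutoff; h <- spec$bandwidth
  win <- data[abs(data$x - c0) <= h, , drop = FALSE]
  side <- ifelse(win$x >= c0, "above", "below")
  purrr::map_dfr(covariates, function(cv) {
    v <- as.character(win[[cv]])
    keep <- !is.na(v)
    vv <- v[keep]; ss <- side[keep]
    lev <- sort(unique(vv))
    n_above <- sum(ss == "above"); n_below <- sum(ss == "below")
    if (length(lev) < 2) {
      test <- "none (single level)"; test_p <- NA_real_
    } else {
      tab <- table(factor(vv, levels = lev), factor(ss, levels = c("above", "below")))
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        test <- "fisher"
        test_p <- tryCatch(
          fisher.test(tab)$p.value,
          error = function(e) fisher.test(tab, simulate.p.value = TRUE,
                                          B = 10000)$p.value
        )
      } else {
        test <- "chi-square"
        test_p <- suppressWarnings(chisq.test(tab)$p.value)
      }
    }
    purrr::map_dfr(lev, function(l) {
      ka <- sum(vv == l & ss == "above"); kb <- sum(vv == l & ss == "below")
      cia <- wilson_ci(ka, n_above); cib <- wilson_ci(kb, n_below)
      pa <- 100 * ka / n_above; pb <- 100 * kb / n_below
      tibble::tibble(
        covariate = cv, level = l,
        n_above = ka, prop_above = pa,
        ci_low_above = 100 * cia["low"], ci_high_above = 100 * cia["high"],
        n_below = kb, prop_below = pb,
        ci_low_below = 100 * cib["low"], ci_high_below = 100 * cib["high"],
        difference = pa - pb,
        test = test, test_p = test_p
      )
    })
  })
}

#' Placebo RD on a covariate
#'
#' Treats a covariate (or one level of a categorical covariate, recoded
#' 0/1) as the outcome and estimates its discontinuity at the cutoff with
#' the same local linear machinery (a linear probability fit for indicator
#' outcomes). Under valid assignment the covariate is continuous at the
#' cutoff and the estimate should be indistinguishable from zero.
#'
#' @param data Cohort tibble.
#' @param spec An [rd_spec()]; covariate adjustment is ignored.
#' @param covariate Covariate column name.
#' @param level For categorical covariates, the level recoded as 1.
#' @return An `rd_fit` for the placebo outcome.
#' @export
covariate_placebo_rd <- function(data, spec = rd_spec(bandwidth = 2.9),
                                 covariate, level = NULL) {
  spec$covariates <- character()
  v <- data[[covariate]]
  if (is.null(v)) stop(sprintf("covariate `%s` not found", covariate),
                       call. = FALSE)
  if (is.numeric(v)) {
    data$.placebo <- v
    nm <- covariate
  } else {
    if (is.null(level)) {
      stop("`level` is required for a categorical covariate", call. = FALSE)
    }
    data$.placebo <- as.numeric(as.character(v) == level)
    nm <- paste0(covariate, "=", level)
  }
  fit <- fit_sharp_rd(data, ".placebo", spec)
  fit$outcome <- paste0("placebo:", nm)
  fit
}

#' Attrition continuity at the cutoff
#'
#' Fits the sharp RD with the follow-up indicator as outcome at the main
#' bandwidth and at 50% and 150% of it. A discontinuity in follow-up
#' probability at the cutoff would undermine local comparability even when
#' overall attrition differs by side.
#'
#' @param data Cohort tibble with a `followed_up` column covering every
#'   baseline row.
#' @param spec An [rd_spec()] with a set bandwidth.
#' @param multipliers Bandwidth multipliers (default 1, 0.5, 1.5).
#' @return Tibble of [glance.rd_fit()] rows with a `multiplier` column.
#' @export
attrition_continuity_test <- function(data, spec = rd_spec(bandwidth = 2.9),
                                      multipliers = c(1, 0.5, 1.5)) {
  if (is.null(data$followed_up)) {
    stop("`followed_up` column is required", call. = FALSE)
  }
  if (anyNA(data$followed_up)) {
    stop("`followed_up` must be observed for every baseline row",
         call. = FALSE)
  }
  if (is.null(spec$bandwidth)) {
    stop("attrition_continuity_test needs a spec with a set bandwidth",
         call. = FALSE)
  }
  spec$covariates <- character()
  purrr::map_dfr(multipliers, function(m) {
    s <- spec
    s$bandwidth <- scale_bandwidth(spec$bandwidth, m)
    dplyr::bind_cols(tibble::tibble(multiplier = m),
                     glance(fit_sharp_rd(data, "followed_up", s)))
  })
}
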