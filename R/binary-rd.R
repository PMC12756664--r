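#' Risk-ratio RD for a binary outcome (modified Poisson)
#'
#' Fits the centered RD design
#' `log E[Y] = a0 + a1*above + a2*(x - c) + a3*above*(x - c)` to a 0/1
#' outcome by Poisson-family log-link estimating equations with triangular
#' kernel weights as observation weights, and a robust sandwich variance
#' (the "modified Poisson" approach for binary outcomes). The risk ratio at
#' the cutoff is `exp(a1)`.
#'
#' Iteratively reweighted least squares is capped at 100 iterations with
#' convergence tolerance 1e-8 on the coefficient change. Fitted risks above
#' 1 are permitted transiently during iteration; if any remain at
#' convergence the result is flagged (`risk_above_one = TRUE`).
#'
#' @param data Cohort tibble.
#' @param outcome Binary (0/1) outcome column name.
#' @param spec An [rd_spec()] with a set bandwidth (the binary fits are
#'   unadjusted: the covariate set is ignored).
#' @param slope_terms Keep the running-variable trend and its interaction
#'   in the design (default). With `slope_terms = FALSE` the design reduces
#'   to intercept + side, which collapses to the closed-form 2x2 risk ratio
#'   under equal weights; it is also required when each side carries a
#'   single distinct `x` value (the trend is then unidentifiable).
#' @return An `rr_fit` object: `log_rr`, `rr`, `se_log_rr`, CI on the risk-
#'   ratio scale, `p_value`, side counts.
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 4000, seed = 5,
#'                   binary_outcome_spec = list(
#'                     smoker = list(intercept = log(0.2), slope = 0,
#'                                   jump = log(1.5))))
#' fit_binary_rd(simulate_cohort(cfg), "smoker", rd_spec(bandwidth = 2.9))
fit_binary_rd <- function(data, outcome, spec = rd_spec(bandwidth = 2.9),
                          slope_terms = TRUE) {
  stopifnot(inherits(spec, "rd_spec"))
  if (is.null(spec$bandwidth)) {
    stop("fit_binary_rd needs a spec with a set bandwidth", call. = FALSE)
  }
  y_all <- data[[outcome]]
  if (is.null(y_all)) stop(sprintf("outcome column `%s` not found", outcome),
                           call. = FALSE)
  if (!all(y_all %in% c(0, 1, NA))) {
    stop(sprintf("outcome `%s` must be 0/1", outcome), call. = FALSE)
  }
  s <- spec
  s$covariates <- character()
  d <- build_rd_design(data, outcome, s)
  if (!slope_terms) {
    d$X <- d$X[, c("(Intercept)", "above"), drop = FALSE]
  }
  above <- d$X[, "above"]
  for (side in c(0, 1)) {
    ys <- d$y[above == side]
    if (all(ys == 0) || all(ys == 1)) {
      stop(sprintf(
        "outcome `%s` is all-%d on the %s side within the window (separation)",
        outcome, ys[1], if (side == 0) "left" else "right"), call. = FALSE)
    }
  }

  fit <- poisson_irls(d$X, d$y, d$w, maxit = 100, tol = 1e-8)
  b <- fit$coefficients
  mu <- fit$fitted
  # robust sandwich: score_i = w_i (y_i - mu_i) x_i, bread = (X' diag(w mu) X)^-1
  bread <- chol2inv(chol(crossprod(d$X * sqrt(d$w * mu))))
  meat <- crossprod(d$X * (d$w * (d$y - mu)))
  V <- bread %*% meat %*% bread
  dimnames(V) <- list(colnames(d$X), colnames(d$X))

  log_rr <- unname(b["above"])
  se <- sqrt(V["above", "above"])
  z <- qnorm(1 - spec$alpha_level / 2)
  structure(
    list(outcome = outcome, log_rr = log_rr, rr = exp(log_rr),
         se_log_rr = se,
         ci_low = exp(log_rr - z * se), ci_high = exp(log_rr + z * se),
         p_value = 2 * pnorm(-abs(log_rr / se)),
         n_left = d$n_left, n_right = d$n_right,
         h_used = spec$bandwidth, kernel = spec$kernel,
         cutoff = spec$cutoff, alpha_level = spec$alpha_level,
         coefficients = b, vcov = V,
         risk_above_one = any(mu > 1),
         iterations = fit$iterations, converged = fit$converged),
    class = "rr_fit"
  )
}

# Log-link Poisson-family IRLS on a dense design with prior weights.
poisson_irls <- function(X, y, w, maxit = 100, tol = 1e-8) {
  # start from the weighted log mean on each design's intercept
  b <- c(log(max(sum(w * y) / sum(w), 1e-6)), rep(0, ncol(X) - 1))
  names(b) <- colnames(X)
  converged <- FALSE
  it <- 0
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% b)
    mu <- exp(eta)
    z <- eta + (y - mu) / mu
    ww <- w * mu
    fit <- lm.wfit(X, z, ww)
    b_new <- fit$coefficients
    if (anyNA(b_new)) {
      stop(sprintf("rank-deficient design; collinear column(s): %s",
                   paste(names(b_new)[is.na(b_new)], collapse = ", ")),
           call. = FALSE)
    }
    delta <- max(abs(b_new - b))
    b <- b_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop(sprintf(
      "modified Poisson fit did not converge in %d iterations (last coefficient change %.3g)",
      maxit, delta), call. = FALSE)
  }
  list(coefficients = b, fitted = exp(drop(X %*% b)),
       iterations = it, converged = converged)
}

#' @export
print.rr_fit <- function(x, ...) {
  cat(sprintf("Modified Poisson RD fit: %s  (%s kernel, h = %.4g)\n",
              x$outcome, x$kernel, x$h_used))
  cat(sprintf("  RR = %.4g  (%g%% CI %.4g to %.4g, p = %.3g)\n",
              x$rr, 100 * (1 - x$alpha_level), x$ci_low, x$ci_high,
              x$p_value))
  cat(sprintf("  n: %d below / %d above cutoff\n", x$n_left, x$n_right))
  if (x$risk_above_one) cat("  note: fitted risks > 1 at convergence\n")
  invisible(x)
}

#' @method tidy rr_fit
#' @export
tidy.rr_fit <- function(x, ...) {
  est <- x$coefficients
  se <- sqrt(diag(x$vcov))
  tibble::tibble(term = names(est), estimate = unname(est),
                 std.error = unname(se), statistic = unname(est / se),
                 p.value = 2 * pnorm(-abs(unname(est / se))))
}

#' @method glance rr_fit
#' @export
glance.rr_fit <- function(x, ...) {
  tibble::tibble(outcome = x$outcome, rr = x$rr, log_rr = x$log_rr,
                 se_log_rr = x$se_log_rr, ci_low = x$ci_low,
                 ci_high = x$ci_high, p_value = x$p_value,
                 n_left = x$n_left, n_right = x$n_right, h = x$h_used,
                 risk_above_one = x$risk_above_one)
}

#' WHO physical-activity classification
#'
#' @param met_min Weekly activity in metabolic-equivalent task minutes.
#' @return 1 iff `met_min >= 600` (meets the recommendation), else 0.
#' @export
classify_activity <- function(met_min) {
  as.integer(met_min >= 600)
}

#' Secondary-outcome battery
#'
#' Runs the appropriate RD fit over a dictionary of secondary outcomes:
#' continuous outcomes (e.g. blood pressure, glucose) through
#' [fit_sharp_rd()], binary outcomes (behaviors, health-care use,
#' mental-health indicators) through [fit_binary_rd()], consolidating
#' everything into one report. The estimate column carries the mean
#' difference for continuous outcomes and the risk ratio for binary ones.
#'
#' @param data Cohort tibble.
#' @param spec An [rd_spec()] with a set bandwidth.
#' @param outcomes Named character vector mapping outcome column names to
#'   `"continuous"` or `"binary"`.
#' @return Tibble with one row per outcome: `outcome`, `type`, `scale`
#'   (`"difference"` or `"risk_ratio"`), `estimate`, `ci_low`, `ci_high`,
#'   `p_value`, side counts, and `error` (NA on success).
#' @export
secondary_outcome_battery <- function(data, spec = rd_spec(bandwidth = 2.9),
                                      outcomes) {
  purrr::imap_dfr(outcomes, function(type, nm) {
    res <- tryCatch({
      if (type == "continuous") {
        f <- fit_sharp_rd(data, nm, spec)
        tibble::tibble(scale = "difference", estimate = f$tau_hat,
                       ci_low = f$ci_low, ci_high = f$ci_high,
                       p_value = f$p_value, n_left = f$n_left,
                       n_right = f$n_right, error = NA_character_)
      } else if (type == "binary") {
        f <- fit_binary_rd(data, nm, spec)
        tibble::tibble(scale = "risk_ratio", estimate = f$rr,
                       ci_low = f$ci_low, ci_high = f$ci_high,
                       p_value = f$p_value, n_left = f$n_left,
                       n_right = f$n_right, error = NA_character_)
      } else {
        stop(sprintf("unknown outcome type `%s`", type), call. = FALSE)
      }
    }, error = function(e) {
      tibble::tibble(scale = NA_character_, estimate = NA_real_,
                     ci_low = NA_real_, ci_high = NA_real_,
                     p_value = NA_real_, n_left = NA_integer_,
                     n_right = NA_integer_, error = conditionMessage(e))
    })
    dplyr::bind_cols(tibble::tibble(outcome = nm, type = type), res)
  })
}
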