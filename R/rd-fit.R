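#' Sharp treatment assignment at a cutoff
#'
#' Deterministic assignment: the boundary belongs to the treated side, so
#' a subject at exactly the cutoff receives the referral.
#'
#' @param x Running-variable values (finite).
#' @param cutoff Cutoff value.
#' @return Integer vector, 1 iff `x >= cutoff`.
#' @export
assign_treatment <- function(x, cutoff) {
  if (any(!is.finite(x))) stop("`x` must be finite", call. = FALSE)
  as.integer(x >= cutoff)
}

#' Triangular kernel weights
#'
#' `w = max(0, 1 - |x - cutoff| / h)`: weight 1 at the cutoff, falling
#' linearly to 0 at distance `h`.
#'
#' @param x Running-variable values.
#' @param cutoff Cutoff value.
#' @param h Bandwidth (> 0).
#' @return Weights in `[0, 1]`.
#' @export
triangular_weights <- function(x, cutoff, h) {
  if (!is.numeric(h) || length(h) != 1 || h <= 0) {
    stop("bandwidth `h` must be a single positive number", call. = FALSE)
  }
  pmax(0, 1 - abs(x - cutoff) / h)
}

#' Specify a sharp RD analysis
#'
#' Bundles the tuning choices of one sharp-RD fit: cutoff, bandwidth,
#' local polynomial order, kernel, covariate set, donut radius, test size
#' and standard-error type.
#'
#' @param cutoff Running-variable cutoff (default 25 kg/m2).
#' @param bandwidth Positive bandwidth in running-variable units, or `NULL`
#'   to select one from the data with [select_bandwidth()] at fit time.
#' @param order Local polynomial order: 1 (linear) or 2 (quadratic).
#' @param kernel `"triangular"` (default) or `"uniform"`.
#' @param covariates Character vector of covariate column names entering
#'   additively with a shared intercept (never interacted with side);
#'   categorical covariates expand to indicators against the first sorted
#'   level as reference.
#' @param donut_radius Observations with `|x - cutoff| < donut_radius` are
#'   excluded (strict; points at exactly the radius are retained). Must
#'   satisfy `0 <= donut_radius < bandwidth`.
#' @param alpha_level Two-sided test size for confidence intervals.
#' @param se_type `"HC1"` (heteroskedasticity-robust sandwich, default) or
#'   `"classical"`.
#' @return An `rd_spec` object.
#' @export
rd_spec <- function(cutoff = 25, bandwidth = NULL, order = 1,
                    kernel = c("triangular", "uniform"),
                    covariates = character(), donut_radius = 0,
                    alpha_level = 0.05, se_type = c("HC1", "classical")) {
  kernel <- match.arg(kernel)
  se_type <- match.arg(se_type)
  if (!order %in% c(1, 2)) stop("`order` must be 1 or 2", call. = FALSE)
  if (!is.null(bandwidth)) {
    if (!is.numeric(bandwidth) || bandwidth <= 0) {
      stop("`bandwidth` must be > 0", call. = FALSE)
    }
    if (donut_radius >= bandwidth) {
      stop("`donut_radius` must be < bandwidth", call. = FALSE)
    }
  }
  if (donut_radius < 0) stop("`donut_radius` must be >= 0", call. = FALSE)
  structure(
    list(cutoff = cutoff, bandwidth = bandwidth, order = as.integer(order),
         kernel = kernel, covariates = covariates,
         donut_radius = donut_radius, alpha_level = alpha_level,
         se_type = se_type),
    class = "rd_spec"
  )
}

kernel_weights <- function(x, cutoff, h, kernel) {
  if (kernel == "triangular") {
    triangular_weights(x, cutoff, h)
  } else {
    as.numeric(abs(x - cutoff) < h)
  }
}

# Builds the centered local-polynomial design:
# (1, above, xc, above*xc [, xc^2, above*xc^2]) + additive covariate columns
# with a shared intercept and no side interaction.
build_rd_design <- function(data, outcome, spec) {
  x <- data$x
  y <- data[[outcome]]
  if (is.null(y)) stop(sprintf("outcome column `%s` not found", outcome),
                       call. = FALSE)
  h <- spec$bandwidth
  xc <- x - spec$cutoff
  w <- kernel_weights(x, spec$cutoff, h, spec$kernel)
  keep <- w > 0 & !is.na(y) & abs(xc) >= spec$donut_radius

  n_dropped_cov <- 0L
  if (length(spec$covariates) > 0) {
    missing_cols <- setdiff(spec$covariates, names(data))
    if (length(missing_cols) > 0) {
      stop(sprintf("covariate column(s) not found: %s",
                   paste(missing_cols, collapse = ", ")), call. = FALSE)
    }
    cc <- complete.cases(data[spec$covariates])
    n_dropped_cov <- sum(keep & !cc)
    keep <- keep & cc
  }

  idx <- which(keep)
  xc <- xc[idx]; y <- y[idx]; w <- w[idx]
  above <- as.numeric(x[idx] >= spec$cutoff)
  n_left <- sum(above == 0); n_right <- sum(above == 1)
  min_side <- spec$order + 1
  if (n_left < min_side || n_right < min_side) {
    stop(sprintf(
      "too few usable observations per side (left %d, right %d; need >= %d)",
      n_left, n_right, min_side), call. = FALSE)
  }

  X <- cbind(`(Intercept)` = 1, above = above, xc = xc,
             `above:xc` = above * xc)
  if (spec$order == 2) {
    X <- cbind(X, `xc^2` = xc^2, `above:xc^2` = above * xc^2)
  }
  for (cv in spec$covariates) {
    v <- data[[cv]][idx]
    if (is.numeric(v)) {
      cv_mat <- matrix(v, ncol = 1, dimnames = list(NULL, cv))
    } else {
      lev <- sort(unique(as.character(v)))
      if (length(lev) < 2) next  # constant covariate carries no information
      cv_mat <- sapply(lev[-1], function(l) as.numeric(v == l))
      colnames(cv_mat) <- paste0(cv, lev[-1])
    }
    X <- cbind(X, cv_mat)
  }
  list(X = X, y = y, w = w, n_left = n_left, n_right = n_right,
       n_dropped_covariates = n_dropped_cov)
}

# Weighted least squares with sandwich (HC1) or classical variance.
wls_fit <- function(X, y, w, se_type) {
  fit <- lm.wfit(X, y, w)
  b <- fit$coefficients
  if (anyNA(b)) {
    stop(sprintf("rank-deficient design; collinear column(s): %s",
                 paste(names(b)[is.na(b)], collapse = ", ")), call. = FALSE)
  }
  n <- nrow(X); k <- ncol(X)
  e <- y - drop(X %*% b)
  XtWX <- crossprod(X * sqrt(w))
  bread <- chol2inv(chol(XtWX))
  if (se_type == "HC1") {
    meat <- crossprod(X * (w * e))
    V <- bread %*% meat %*% bread * n / (n - k)
  } else {
    sigma2 <- sum(w * e^2) / (n - k)
    V <- bread * sigma2
  }
  dimnames(V) <- list(colnames(X), colnames(X))
  list(coefficients = b, vcov = V, residuals = e)
}

#' Fit a sharp regression discontinuity
#'
#' Kernel-weighted local polynomial least squares on the centered design
#' `y ~ 1 + above + (x - c) + above:(x - c)` (plus quadratic terms when
#' `order = 2`, plus additive covariates with a shared intercept). The
#' discontinuity estimate is the coefficient on `above`, interpreted as the
#' local average intention-to-treat effect of crossing the threshold.
#' Standard errors are heteroskedasticity-robust (HC1) by default, with a
#' conventional Wald normal confidence interval.
#'
#' Observations with zero kernel weight, missing outcome, inside the donut,
#' or with missing covariates (listwise, count recorded) are excluded.
#'
#' @param data Cohort tibble with columns `x` and the outcome.
#' @param outcome Outcome column name.
#' @param spec An [rd_spec()]; if its bandwidth is `NULL` one is selected
#'   from the data via [select_bandwidth()].
#' @return An `rd_fit` object; see [tidy.rd_fit()] and [glance.rd_fit()].
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_subjects = 1000, tau = 0.8, seed = 7))
#' fit <- fit_sharp_rd(cohort, "bmi_change", rd_spec(bandwidth = 2.9))
#' glance(fit)
fit_sharp_rd <- function(data, outcome, spec = rd_spec()) {
  stopifnot(inherits(spec, "rd_spec"))
  if (is.null(spec$bandwidth)) {
    spec$bandwidth <- select_bandwidth(data, outcome, spec$cutoff)$h_opt
    if (spec$donut_radius >= spec$bandwidth) {
      stop("selected bandwidth is smaller than the donut radius", call. = FALSE)
    }
  }
  d <- build_rd_design(data, outcome, spec)
  f <- wls_fit(d$X, d$y, d$w, spec$se_type)
  tau_hat <- unname(f$coefficients["above"])
  se <- sqrt(f$vcov["above", "above"])
  z <- qnorm(1 - spec$alpha_level / 2)
  structure(
    list(tau_hat = tau_hat, se = se,
         ci_low = tau_hat - z * se, ci_high = tau_hat + z * se,
         p_value = 2 * pnorm(-abs(tau_hat / se)),
         n_left = d$n_left, n_right = d$n_right,
         h_used = spec$bandwidth, order = spec$order,
         kernel = spec$kernel, cutoff = spec$cutoff,
         donut_radius = spec$donut_radius,
         covariate_set = spec$covariates,
         alpha_level = spec$alpha_level, se_type = spec$se_type,
         coefficients = f$coefficients, vcov = f$vcov,
         n_dropped_covariates = d$n_dropped_covariates,
         outcome = outcome),
    class = "rd_fit"
  )
}

#' @export
print.rd_fit <- function(x, ...) {
  cat(sprintf(
    "Sharp RD fit: %s  (order %d, %s kernel, h = %.4g, cutoff = %g)\n",
    x$outcome, x$order, x$kernel, x$h_used, x$cutoff))
  cat(sprintf("  tau = %.4g  (SE %.4g, %g%% CI %.4g to %.4g, p = %.3g)\n",
              x$tau_hat, x$se, 100 * (1 - x$alpha_level),
              x$ci_low, x$ci_high, x$p_value))
  cat(sprintf("  n: %d below / %d above cutoff", x$n_left, x$n_right))
  if (length(x$covariate_set) > 0) {
    cat(sprintf("; covariates: %s", paste(x$covariate_set, collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' Tidy a sharp RD fit
#'
#' @param x An `rd_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per model coefficient (`term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`).
#' @method tidy rd_fit
#' @export
tidy.rd_fit <- function(x, ...) {
  est <- x$coefficients
  se <- sqrt(diag(x$vcov))
  tibble::tibble(
    term = names(est), estimate = unname(est), std.error = unname(se),
    statistic = unname(est / se),
    p.value = 2 * pnorm(-abs(unname(est / se)))
  )
}

#' One-row summary of a sharp RD fit
#'
#' @param x An `rd_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `tau_hat`, `se`, `ci_low`, `ci_high`,
#'   `p_value`, effective side counts, bandwidth, order, kernel and the
#'   covariate-set label.
#' @method glance rd_fit
#' @export
glance.rd_fit <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome, tau_hat = x$tau_hat, se = x$se,
    ci_low = x$ci_low, ci_high = x$ci_high, p_value = x$p_value,
    n_left = x$n_left, n_right = x$n_right, h = x$h_used,
    order = x$order, kernel = x$kernel, donut_radius = x$donut_radius,
    covariates = if (length(x$covariate_set) > 0) {
      paste(x$covariate_set, collapse = "+")
    } else "none"
  )
}

#' Cumulative covariate sets for the adjustment grid
#'
#' The grid moves from unadjusted to fully adjusted: none; demographic
#' (age group, sex); plus marital status and race; plus socioeconomic
#' (education, occupation, income); plus behavioral (smoking, alcohol,
#' physical activity).
#'
#' @return Named list of character vectors.
#' @export
default_covariate_sets <- function() {
  list(
    none = character(),
    demographic = c("age_group", "sex"),
    `demographic+social` = c("age_group", "sex", "marital", "race"),
    `demographic+social+socioeconomic` =
      c("age_group", "sex", "marital", "race",
        "education", "occupation", "income"),
    `demographic+social+socioeconomic+behavioral` =
      c("age_group", "sex", "marital", "race",
        "education", "occupation", "income",
        "smoking", "alcohol", "activity")
  )
}

#' Fit the estimate grid across polynomial orders and covariate sets
#'
#' One sharp-RD fit per cell of `{orders} x {covariate sets}`, rendered as
#' a long tibble (one row per cell). Per-cell failures are reported in an
#' `error` column without aborting the rest of the grid.
#'
#' @param data Cohort tibble.
#' @param outcome Outcome column name.
#' @param spec Base [rd_spec()]; its order/covariates are overridden per cell.
#' @param orders Polynomial orders to fit (default 1 and 2).
#' @param covariate_sets Named list of covariate-name vectors
#'   (default [default_covariate_sets()]).
#' @return Tibble with columns `order`, `covariate_set`, the [glance.rd_fit()]
#'   fields, and `error` (NA on success).
#' @export
fit_rd_grid <- function(data, outcome, spec = rd_spec(),
                        orders = c(1, 2),
                        covariate_sets = default_covariate_sets()) {
  if (is.null(spec$bandwidth)) {
    spec$bandwidth <- select_bandwidth(data, outcome, spec$cutoff)$h_opt
  }
  grid <- tidyr::expand_grid(order = orders,
                             covariate_set = names(covariate_sets))
  purrr::pmap_dfr(grid, function(order, covariate_set) {
    cell_spec <- spec
    cell_spec$order <- as.integer(order)
    cell_spec$covariates <- covariate_sets[[covariate_set]]
    res <- tryCatch(
      glance(fit_sharp_rd(data, outcome, cell_spec)),
      error = function(e) {
        tibble::tibble(outcome = outcome, tau_hat = NA_real_, se = NA_real_,
                       ci_low = NA_real_, ci_high = NA_real_,
                       p_value = NA_real_, n_left = NA_integer_,
                       n_right = NA_integer_, h = cell_spec$bandwidth,
                       order = as.integer(order), kernel = cell_spec$kernel,
                       donut_radius = cell_spec$donut_radius,
                       covariates = NA_character_, error = conditionMessage(e))
      }
    )
    if (!"error" %in% names(res)) res$error <- NA_character_
    dplyr::bind_cols(tibble::tibble(covariate_set = covariate_set),
                     res[setdiff(names(res), "covariates")])
  })
}
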