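#' Simulate a synthetic screening cohort
#'
#' Draws a subject-level cohort with the statistical structure a sharp
#' regression-discontinuity analysis assumes: a continuous running variable
#' `x` (baseline BMI), sharp assignment `above = 1` iff `x >= cutoff`,
#' side-specific smooth conditional outcome means with an injectable
#' discontinuity `tau`, covariates continuous at the cutoff (unless the
#' configuration says otherwise), binary outcomes generated on the log-risk
#' scale, and attrition applied last: outcomes of subjects with
#' `followed_up = 0` are set missing, never fabricated, and their baseline
#' rows are kept so attrition-continuity tests can use the full table.
#'
#' Generation is fully deterministic given the configuration (which carries
#' the seed): stages draw in a fixed documented order (running variable,
#' bunching relocation, covariates, continuous outcomes, binary outcomes,
#' attrition).
#'
#' @param config A [sim_config()] object.
#' @return A tibble (the cohort table) with columns `subject_id`, `x`,
#'   `above`, one column per outcome, one per covariate (plus `age_group`
#'   when a continuous `age` covariate is configured), and `followed_up`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_subjects = 200, seed = 42))
#' table(cohort$above)
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  n <- as.integer(config$n_subjects)
  c0 <- config$cutoff

  x <- draw_running_variable(config$rv_distribution, n)

  cohort <- tibble::tibble(
    subject_id = sprintf("S%06d", seq_len(n)),
    x = x,
    above = assign_treatment(x, c0)
  )

  if (config$bunching_mass > 0) {
    cohort <- inject_manipulation(cohort, mass = config$bunching_mass,
                                  width = config$bunching_width, cutoff = c0)
  }

  xc <- cohort$x - c0
  above <- cohort$above

  for (nm in names(config$covariate_spec)) {
    cohort[[nm]] <- draw_covariate(config$covariate_spec[[nm]], nm, xc, above)
  }
  if ("age" %in% names(cohort) && is.numeric(cohort$age)) {
    cohort$age_group <- categorize_age(cohort$age)
  }

  cohort[[config$outcome_name]] <- draw_continuous_outcome(
    xc, above, config$mean_fn_left, config$mean_fn_right,
    config$tau, config$noise_sd
  )
  for (nm in names(config$extra_continuous_spec)) {
    sp <- config$extra_continuous_spec[[nm]]
    cohort[[nm]] <- draw_continuous_outcome(
      xc, above, sp$mean_fn_left, sp$mean_fn_right, sp$tau, sp$noise_sd
    )
  }

  for (nm in names(config$binary_outcome_spec)) {
    sp <- config$binary_outcome_spec[[nm]]
    risk <- exp(sp$intercept + sp$slope * xc + sp$jump * above)
    if (any(risk > 1)) {
      stop(sprintf(
        "binary_outcome_spec$%s implies risk > 1 (max %.3f) at observed x; refusing to clip",
        nm, max(risk)
      ), call. = FALSE)
    }
    cohort[[nm]] <- rbinom(nrow(cohort), 1L, risk)
  }

  at <- config$attrition_spec
  p_follow <- ifelse(above == 1, at$p_right, at$p_left) +
    (at$x_slope %||% 0) * xc
  if (any(p_follow < 0 | p_follow > 1)) {
    stop("attrition_spec implies follow-up probability outside [0, 1]",
         call. = FALSE)
  }
  cohort$followed_up <- rbinom(nrow(cohort), 1L, p_follow)

  outcome_cols <- c(config$outcome_name,
                    names(config$extra_continuous_spec),
                    names(config$binary_outcome_spec))
  lost <- cohort$followed_up == 0L
  for (nm in outcome_cols) cohort[[nm]][lost] <- NA

  attr(cohort, "cutoff") <- c0
  cohort
}

draw_running_variable <- function(rv, n) {
  x <- switch(rv$family,
    lognormal = rlnorm(n, rv$meanlog, rv$sdlog),
    normal    = rnorm(n, rv$mean, rv$sd),
    uniform   = runif(n, rv$min, rv$max)
  )
  # truncated resampling keeps x strictly positive for the normal family
  bad <- which(x <= 0)
  while (length(bad) > 0) {
    x[bad] <- switch(rv$family,
      lognormal = rlnorm(length(bad), rv$meanlog, rv$sdlog),
      normal    = rnorm(length(bad), rv$mean, rv$sd),
      uniform   = runif(length(bad), rv$min, rv$max)
    )
    bad <- which(x <= 0)
  }
  x
}

draw_covariate <- function(sp, nm, xc, above) {
  if (identical(sp$type, "continuous")) {
    v <- sp$mean + (sp$x_slope %||% 0) * xc + (sp$jump %||% 0) * above +
      rnorm(length(xc), 0, sp$sd)
    if (!is.null(sp$min)) v <- pmax(v, sp$min)
    return(v)
  }
  levels <- as.character(unlist(sp$levels))
  probs <- as.numeric(unlist(sp$probs))
  if (length(levels) != length(probs) || abs(sum(probs) - 1) > 1e-8) {
    stop(sprintf("covariate_spec$%s: levels/probs mismatch or probs not summing to 1", nm),
         call. = FALSE)
  }
  slope <- sp$x_slope %||% 0
  jump <- sp$jump %||% 0
  if (slope == 0 && jump == 0) {
    return(sample(levels, length(xc), replace = TRUE, prob = probs))
  }
  # tilt the first level's probability smoothly in xc (plus optional jump),
  # renormalizing the remaining levels proportionally
  p1 <- probs[1] + slope * xc + jump * above
  if (any(p1 < 0 | p1 > 1)) {
    stop(sprintf("covariate_spec$%s: x-dependent probability leaves [0, 1]", nm),
         call. = FALSE)
  }
  rest <- probs[-1] / sum(probs[-1])
  u <- runif(length(xc))
  out <- character(length(xc))
  first <- u < p1
  out[first] <- levels[1]
  if (any(!first)) {
    out[!first] <- sample(levels[-1], sum(!first), replace = TRUE, prob = rest)
  }
  out
}

draw_continuous_outcome <- function(xc, above, fn_left, fn_right, tau, noise_sd) {
  mu <- ifelse(above == 1, poly_eval(fn_right, xc), poly_eval(fn_left, xc)) +
    tau * above
  mu + rnorm(length(xc), 0, noise_sd)
}

poly_eval <- function(coefs, x) {
  out <- numeric(length(x))
  for (k in seq_along(coefs)) out <- out + coefs[k] * x^(k - 1)
  out
}

#' Age bins used in cohort descriptives
#'
#' Categorizes continuous age (years) into the bins 35-39, 40-49, 50-59,
#' 60-69 and 70+ used throughout the descriptive and subgroup analyses.
#'
#' @param age Numeric vector of ages in years.
#' @return Character vector of bin labels.
#' @export
categorize_age <- function(age) {
  as.character(cut(age, breaks = c(-Inf, 40, 50, 60, 70, Inf),
                   labels = c("35-39", "40-49", "50-59", "60-69", "70+"),
                   right = FALSE))
}

#' Inject running-variable manipulation near the cutoff
#'
#' Relocates a fraction `mass` of subjects with `x` in
#' `[cutoff - width, cutoff)` to uniform positions in
#' `[cutoff, cutoff + width]`, recomputing the treatment indicator and
#' leaving every other field unchanged. Emulates recorder interference that
#' piles mass just above the threshold, the failure mode the density
#' manipulation test is designed to detect.
#'
#' @param table A cohort tibble with columns `x` and `above`.
#' @param mass Fraction in `(0, 1)` of donor-stratum subjects to move
#'   (`mass = 0` returns the table unchanged).
#' @param width Stratum half-width in running-variable units (> 0).
#' @param cutoff Cutoff; defaults to the table's recorded cutoff or 25.
#' @return The modified cohort tibble.
#' @export
inject_manipulation <- function(table, mass, width, cutoff = NULL) {
  cutoff <- cutoff %||% attr(table, "cutoff") %||% 25
  if (mass == 0) return(table)
  if (mass < 0 || mass >= 1) stop("`mass` must lie in [0, 1)", call. = FALSE)
  if (width <= 0) stop("`width` must be > 0", call. = FALSE)
  donors <- which(table$x >= cutoff - width & table$x < cutoff)
  if (length(donors) == 0) {
    stop(sprintf("no subjects with x in [%g, %g) to manipulate",
                 cutoff - width, cutoff), call. = FALSE)
  }
  n_move <- round(mass * length(donors))
  if (n_move > 0) {
    moved <- donors[seq_len(n_move)]
    table$x[moved] <- runif(n_move, cutoff, cutoff + width)
    table$above <- assign_treatment(table$x, cutoff)
  }
  table
}

#' Read or write a cohort table as CSV
#'
#' The CSV carries a versioned comment header (`# rdscreen cohort v1,
#' cutoff=<c>`) followed by a standard header row; missing values are empty
#' fields. The round trip is lossless for all fields.
#'
#' @param table Cohort tibble.
#' @param path File path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns the cohort tibble with its `cutoff` attribute restored.
#' @export
write_cohort <- function(table, path) {
  cutoff <- attr(table, "cutoff") %||% 25
  con <- file(path, "w")
  writeLines(sprintf("# rdscreen cohort v1, cutoff=%.10g", cutoff), con)
  close(con)
  readr::write_csv(table, path, append = TRUE, col_names = TRUE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  first <- readLines(path, n = 1)
  cutoff <- 25
  skip <- 0
  if (grepl("^# rdscreen cohort", first)) {
    cutoff <- as.numeric(sub(".*cutoff=", "", first))
    skip <- 1
  }
  tb <- readr::read_csv(path, skip = skip, na = "",
                        show_col_types = FALSE, progress = FALSE)
  attr(tb, "cutoff") <- cutoff
  tb
}
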