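#' Build a synthetic-cohort generative configuration
#'
#' Defines the full generative model behind [simulate_cohort()]: the
#' running-variable (baseline BMI) distribution, side-specific conditional
#' mean functions for the primary continuous outcome, an injectable
#' discontinuity `tau` at the cutoff, covariate marginals (optionally with
#' smooth dependence on the running variable), binary outcomes on the
#' log-risk scale, side-specific attrition, and optional bunching mass at
#' the cutoff.
#'
#' Defaults emulate a community BMI-screening cohort: a right-skewed,
#' unimodal baseline BMI distribution (log-normal, median 24.5 kg/m2,
#' SD about 4 kg/m2), a cutoff of 25 kg/m2, a 5-year BMI-change outcome with
#' residual SD 1.5 kg/m2, covariates continuous at the cutoff, and
#' side-specific follow-up probabilities 0.461 (below) and 0.546 (above).
#'
#' @param n_subjects Number of baseline subjects (>= 1).
#' @param cutoff Running-variable cutoff; assignment is sharp at `x >= cutoff`.
#' @param rv_distribution Named list describing the running-variable family:
#'   `list(family = "lognormal", meanlog, sdlog)`,
#'   `list(family = "normal", mean, sd)` or
#'   `list(family = "uniform", min, max)`.
#' @param mean_fn_left,mean_fn_right Numeric coefficient vectors of the
#'   conditional mean polynomial for the primary outcome in centered
#'   coordinates `(x - cutoff)`, constant term first.
#' @param tau Discontinuity added to the right-side mean (outcome units).
#' @param noise_sd Residual standard deviation of the primary outcome (>= 0).
#' @param outcome_name Column name of the primary continuous outcome.
#' @param covariate_spec Named list of covariate generators. Each element is
#'   `list(type = "categorical", levels, probs, x_slope = 0)` (the `x_slope`
#'   tilts the probability of the first level linearly in `x - cutoff`) or
#'   `list(type = "continuous", mean, sd, x_slope = 0, jump = 0)` where
#'   `jump` adds a discontinuity at the cutoff (for stress-testing balance
#'   diagnostics). A continuous covariate named `age` also yields a derived
#'   `age_group` column via [categorize_age()].
#' @param binary_outcome_spec Named list of binary outcomes, each
#'   `list(intercept, slope, jump)` on the log-risk scale:
#'   `log P(Y = 1 | x) = intercept + slope * (x - cutoff) + jump * above`.
#'   Configurations implying risk > 1 at any generated `x` are an error.
#' @param extra_continuous_spec Named list of additional continuous outcomes,
#'   each `list(mean_fn_left, mean_fn_right, tau, noise_sd)`.
#' @param attrition_spec `list(p_left, p_right, x_slope = 0)`: follow-up
#'   probability per side, optionally with a smooth linear trend in
#'   `x - cutoff`; all implied probabilities must lie in `[0, 1]`.
#' @param bunching_mass Fraction in `[0, 1)` of subjects just below the cutoff
#'   relocated to at/above it (running-variable manipulation); 0 keeps the
#'   density continuous at the cutoff by construction.
#' @param bunching_width Half-width (running-variable units) of the bunching
#'   donor/recipient strata.
#' @param seed Integer seed; identical `(config, seed)` gives byte-identical
#'   cohorts.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [simulate_cohort()], [inject_manipulation()]
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 500, tau = 0.8, seed = 1)
#' cohort <- simulate_cohort(cfg)
sim_config <- function(n_subjects = 6561,
                       cutoff = 25,
                       rv_distribution = list(family = "lognormal",
                                              meanlog = log(24.5),
                                              sdlog = 0.1602),
                       mean_fn_left = c(0, 0.15),
                       mean_fn_right = c(0, 0.15),
                       tau = 0,
                       noise_sd = 1.5,
                       outcome_name = "bmi_change",
                       covariate_spec = default_covariate_spec(),
                       binary_outcome_spec = list(),
                       extra_continuous_spec = list(),
                       attrition_spec = list(p_left = 0.461, p_right = 0.546,
                                             x_slope = 0),
                       bunching_mass = 0,
                       bunching_width = 0.5,
                       seed = 1L) {
  cfg <- list(
    n_subjects = n_subjects, cutoff = cutoff,
    rv_distribution = rv_distribution,
    mean_fn_left = mean_fn_left, mean_fn_right = mean_fn_right,
    tau = tau, noise_sd = noise_sd, outcome_name = outcome_name,
    covariate_spec = covariate_spec,
    binary_outcome_spec = binary_outcome_spec,
    extra_continuous_spec = extra_continuous_spec,
    attrition_spec = attrition_spec,
    bunching_mass = bunching_mass, bunching_width = bunching_width,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Default covariate marginals for the synthetic cohort
#'
#' Categorical marginals qualitatively emulating a rural Malaysian adult
#' cohort (40% male, 85% married, 14% ever-smokers, ...) plus a continuous
#' `age` covariate. All covariates are independent of the running variable,
#' so covariate continuity at the cutoff holds by construction.
#'
#' @return Named list usable as `covariate_spec` in [sim_config()].
#' @export
default_covariate_spec <- function() {
  list(
    age = list(type = "continuous", mean = 54, sd = 11, min = 35),
    sex = list(type = "categorical", levels = c("male", "female"),
               probs = c(0.40, 0.60)),
    marital = list(type = "categorical",
                   levels = c("married", "not_married"),
                   probs = c(0.85, 0.15)),
    race = list(type = "categorical",
                levels = c("malay", "chinese", "indian", "other"),
                probs = c(0.61, 0.25, 0.12, 0.02)),
    education = list(type = "categorical",
                     levels = c("none", "primary", "secondary", "tertiary"),
                     probs = c(0.06, 0.47, 0.43, 0.04)),
    income = list(type = "categorical",
                  levels = c("<1000", "1000-1999", "2000-2999", ">=3000"),
                  probs = c(0.43, 0.34, 0.13, 0.10)),
    occupation = list(type = "categorical",
                      levels = c("employed", "homemaker", "not_working"),
                      probs = c(0.45, 0.35, 0.20)),
    smoking = list(type = "categorical", levels = c("yes", "no"),
                   probs = c(0.14, 0.86)),
    alcohol = list(type = "categorical", levels = c("yes", "no"),
                   probs = c(0.026, 0.974)),
    activity = list(type = "categorical", levels = c("meets", "below"),
                    probs = c(0.14, 0.86))
  )
}

validate_sim_config <- function(cfg) {
  stop_cfg <- function(field, msg) {
    stop(sprintf("invalid sim_config field `%s`: %s", field, msg),
         call. = FALSE)
  }
  if (!is.numeric(cfg$n_subjects) || length(cfg$n_subjects) != 1 ||
      cfg$n_subjects < 1 || cfg$n_subjects != floor(cfg$n_subjects)) {
    stop_cfg("n_subjects", "must be a single integer >= 1")
  }
  if (!is.numeric(cfg$cutoff) || !is.finite(cfg$cutoff) || cfg$cutoff <= 0) {
    stop_cfg("cutoff", "must be a finite positive number")
  }
  rv <- cfg$rv_distribution
  if (is.null(rv$family) ||
      !rv$family %in% c("lognormal", "normal", "uniform")) {
    stop_cfg("rv_distribution", "family must be lognormal, normal or uniform")
  }
  need <- switch(rv$family,
                 lognormal = c("meanlog", "sdlog"),
                 normal = c("mean", "sd"),
                 uniform = c("min", "max"))
  for (p in need) {
    if (!is.numeric(rv[[p]]) || !is.finite(rv[[p]])) {
      stop_cfg("rv_distribution", sprintf("parameter `%s` missing or non-finite", p))
    }
  }
  if (rv$family %in% c("lognormal", "normal") && rv[[need[2]]] <= 0) {
    stop_cfg("rv_distribution", sprintf("`%s` must be > 0", need[2]))
  }
  if (rv$family == "uniform" && (rv$min >= rv$max || rv$min <= 0)) {
    stop_cfg("rv_distribution", "need 0 < min < max")
  }
  if (!is.numeric(cfg$noise_sd) || cfg$noise_sd < 0) {
    stop_cfg("noise_sd", "must be >= 0")
  }
  if (!is.numeric(cfg$tau) || !is.finite(cfg$tau)) {
    stop_cfg("tau", "must be a finite number")
  }
  for (side in c("mean_fn_left", "mean_fn_right")) {
    if (!is.numeric(cfg[[side]]) || length(cfg[[side]]) < 1 ||
        any(!is.finite(cfg[[side]]))) {
      stop_cfg(side, "must be a non-empty finite coefficient vector")
    }
  }
  at <- cfg$attrition_spec
  at$x_slope <- at$x_slope %||% 0
  for (p in c("p_left", "p_right")) {
    if (!is.numeric(at[[p]]) || at[[p]] < 0 || at[[p]] > 1) {
      stop_cfg("attrition_spec", sprintf("`%s` must lie in [0, 1]", p))
    }
  }
  if (!is.numeric(cfg$bunching_mass) || cfg$bunching_mass < 0 ||
      cfg$bunching_mass >= 1) {
    stop_cfg("bunching_mass", "must lie in [0, 1)")
  }
  if (!is.numeric(cfg$bunching_width) || cfg$bunching_width <= 0) {
    stop_cfg("bunching_width", "must be > 0")
  }
  for (nm in names(cfg$binary_outcome_spec)) {
    sp <- cfg$binary_outcome_spec[[nm]]
    for (p in c("intercept", "slope", "jump")) {
      if (!is.numeric(sp[[p]]) || !is.finite(sp[[p]])) {
        stop_cfg(sprintf("binary_outcome_spec$%s", nm),
                 sprintf("`%s` missing or non-finite", p))
      }
    }
  }
  invisible(cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read or write a simulation configuration as YAML
#'
#' Round-trips a [sim_config()] through a structured YAML file so that
#' cohorts can be regenerated outside R sessions.
#'
#' @param config A `sim_config` object.
#' @param path File path.
#' @return `write_sim_config()` returns `path` invisibly;
#'   `read_sim_config()` returns a validated `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(unclass(config), path, precision = 17)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  # numeric vectors round-trip as lists; flatten scalar-list fields
  for (f in c("mean_fn_left", "mean_fn_right")) {
    raw[[f]] <- as.numeric(unlist(raw[[f]]))
  }
  do.call(sim_config, raw)
}
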