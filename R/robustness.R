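#' Placebo-cutoff scan
#'
#' Re-estimates the discontinuity at cutoffs where no effect should exist.
#' For a placebo cutoff strictly below the true one, only untreated-side
#' observations (`x <` true cutoff) enter the fit, so both pseudo-groups
#' are genuinely untreated; symmetrically above. The true cutoff itself
#' reproduces the main estimate exactly.
#'
#' @param data Cohort tibble.
#' @param outcome Outcome column name.
#' @param spec An [rd_spec()] with a set bandwidth; `spec$cutoff` is the
#'   true cutoff.
#' @param cutoffs Placebo cutoffs (default 24, 24.5, 25.5, 26).
#' @return Tibble of [glance.rd_fit()] rows with a `placebo_cutoff` column.
#' @export
placebo_cutoff_scan <- function(data, outcome, spec = rd_spec(bandwidth = 2.9),
                                cutoffs = c(24, 24.5, 25.5, 26)) {
  true_c <- spec$cutoff
  purrr::map_dfr(cutoffs, function(pc) {
    sub <- if (pc < true_c) {
      data[data$x < true_c, , drop = FALSE]
    } else if (pc > true_c) {
      data[data$x >= true_c, , drop = FALSE]
    } else {
      data
    }
    s <- spec
    s$cutoff <- pc
    dplyr::bind_cols(tibble::tibble(placebo_cutoff = pc),
                     glance(fit_sharp_rd(sub, outcome, s)))
  })
}

#' Donut RD
#'
#' Refits after deleting observations strictly inside a radius of the
#' cutoff, guarding against local sorting or measurement heaping exactly at
#' the threshold. Points at exactly the radius are retained.
#'
#' @param data Cohort tibble.
#' @param outcome Outcome column name.
#' @param spec An [rd_spec()] with a set bandwidth.
#' @param radii Donut radii in running-variable units (default 0.5, 1.0, 1.5).
#' @return Tibble of [glance.rd_fit()] rows with `radius` and `n_excluded`
#'   (count of observations with `|x - c| < radius`) columns.
#' @export
donut_rd <- function(data, outcome, spec = rd_spec(bandwidth = 2.9),
                     radii = c(0.5, 1.0, 1.5)) {
  purrr::map_dfr(radii, function(r) {
    if (r >= spec$bandwidth) {
      stop(sprintf("donut radius %g is not smaller than the bandwidth %g",
                   r, spec$bandwidth), call. = FALSE)
    }
    s <- spec
    s$donut_radius <- r
    g <- tryCatch(glance(fit_sharp_rd(data, outcome, s)),
                  error = function(e) {
                    stop(sprintf("donut radius %g: %s", r,
                                 conditionMessage(e)), call. = FALSE)
                  })
    dplyr::bind_cols(
      tibble::tibble(radius = r,
                     n_excluded = sum(abs(data$x - spec$cutoff) < r)),
      g
    )
  })
}

#' Bandwidth sensitivity analysis
#'
#' Refits at multiples of the main bandwidth; the result is renderable as a
#' forest plot ([plot_sensitivity()]) showing how the estimate and its CI
#' move as the window widens or narrows.
#'
#' @param data Cohort tibble.
#' @param outcome Outcome column name.
#' @param spec An [rd_spec()] with a set bandwidth.
#' @param multipliers Bandwidth multipliers (default 0.5, 0.8, 1.0, 1.2, 1.5).
#' @return Tibble of [glance.rd_fit()] rows with a `multiplier` column.
#' @export
bandwidth_sensitivity <- function(data, outcome,
                                  spec = rd_spec(bandwidth = 2.9),
                                  multipliers = c(0.5, 0.8, 1.0, 1.2, 1.5)) {
  purrr::map_dfr(multipliers, function(m) {
    s <- spec
    s$bandwidth <- scale_bandwidth(spec$bandwidth, m)
    dplyr::bind_cols(tibble::tibble(multiplier = m),
                     glance(fit_sharp_rd(data, outcome, s)))
  })
}

#' Age-coding specification check
#'
#' Two covariate-adjusted fits differing only in how age enters: binned
#' (35-39, 40-49, 50-59, 60-69, 70+) versus continuous in years. Agreement
#' indicates the estimate is not an artifact of the age coding.
#'
#' @param data Cohort tibble with `age` (numeric) and `age_group` columns.
#' @param outcome Outcome column name.
#' @param spec An [rd_spec()]; any age variable in its covariate set is
#'   replaced by the respective coding, other covariates are kept.
#' @return Tibble of [glance.rd_fit()] rows with an `age_coding` column.
#' @export
age_specification_check <- function(data, outcome,
                                    spec = rd_spec(bandwidth = 2.9,
                                                   covariates = c("age_group", "sex"))) {
  base_cov <- setdiff(spec$covariates, c("age", "age_group"))
  purrr::map_dfr(c(categorical = "age_group", continuous = "age"),
                 .id = "age_coding", function(age_col) {
    s <- spec
    s$covariates <- c(age_col, base_cov)
    glance(fit_sharp_rd(data, outcome, s))
  })
}
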