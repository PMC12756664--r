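#' Descriptive characteristics table
#'
#' Counts and integer percentages per covariate level, for the full sample
#' and for the subsample within the analysis window `[c - h, c + h]`.
#' Levels present in the full sample but empty in the window are rendered
#' with zero counts, never omitted.
#'
#' @param data Cohort tibble.
#' @param spec An [rd_spec()] with a set bandwidth.
#' @param covariates Categorical covariate columns to tabulate.
#' @return Tibble: `covariate`, `level`, `n_full`, `pct_full`, `n_window`,
#'   `pct_window` (percentages rounded to integers).
#' @export
descriptive_table <- function(data, spec = rd_spec(bandwidth = 2.9),
                              covariates) {
  win <- abs(data$x - spec$cutoff) <= spec$bandwidth
  tot_full <- nrow(data); tot_win <- sum(win)
  purrr::map_dfr(covariates, function(cv) {
    v <- as.character(data[[cv]])
    lev <- sort(unique(v[!is.na(v)]))
    purrr::map_dfr(lev, function(l) {
      kf <- sum(v == l, na.rm = TRUE)
      kw <- sum(v == l & win, na.rm = TRUE)
      tibble::tibble(covariate = cv, level = l,
                     n_full = kf, pct_full = round(100 * kf / tot_full),
                     n_window = kw, pct_window = round(100 * kw / tot_win))
    })
  })
}

#' Sample-flow arithmetic
#'
#' Derives the analytic sample size and flow percentages from the cohort
#' counts: analytic n = followed minus records missing the running
#' variable; exclusion percentage (1 decimal) is relative to the followed
#' sample; follow-up percentage (integer) is relative to the eligible
#' baseline. Optionally reports the side-specific follow-up difference
#' (below minus above, percentage points).
#'
#' @param eligible Eligible baseline count.
#' @param followed Successfully followed-up count.
#' @param missing_rv Followed-up records missing the running variable.
#' @param followup_rate_below,followup_rate_above Optional side-specific
#'   follow-up percentages used to compute `followup_diff`.
#' @return One-row tibble: `eligible`, `followed`, `missing_rv`,
#'   `analytic_n`, `exclusion_pct`, `followup_pct` and (when the side rates
#'   are given) `followup_diff`.
#' @export
#' @examples
#' sample_flow(13769, 7024, 463)
sample_flow <- function(eligible, followed, missing_rv,
                        followup_rate_below = NULL,
                        followup_rate_above = NULL) {
  if (missing_rv > followed || followed > eligible) {
    stop("need missing_rv <= followed <= eligible", call. = FALSE)
  }
  out <- tibble::tibble(
    eligible = eligible, followed = followed, missing_rv = missing_rv,
    analytic_n = followed - missing_rv,
    exclusion_pct = round(100 * missing_rv / followed, 1),
    followup_pct = round(100 * followed / eligible)
  )
  if (!is.null(followup_rate_below) && !is.null(followup_rate_above)) {
    out$followup_diff <- round(followup_rate_below - followup_rate_above, 1)
  }
  out
}

#' Analysis window implied by a cutoff and bandwidth
#'
#' @param cutoff Cutoff value.
#' @param h Bandwidth.
#' @return One-row tibble with `low = cutoff - h` and `high = cutoff + h`.
#' @export
#' @examples
#' analysis_window(25, 2.9)  # 22.1 to 27.9
analysis_window <- function(cutoff, h) {
  if (h <= 0) stop("`h` must be > 0", call. = FALSE)
  tibble::tibble(low = cutoff - h, high = cutoff + h)
}

#' Clinically meaningful BMI change at a given weight-loss fraction
#'
#' Clinical guidelines treat a >= 5% body-weight reduction as meaningful;
#' since BMI is proportional to weight at fixed height, that corresponds
#' to a BMI change of `fraction * bmi`.
#'
#' @param bmi Baseline BMI value(s) (kg/m2).
#' @param fraction Weight-change fraction (default 0.05).
#' @return BMI change in kg/m2, rounded to 1 decimal.
#' @export
#' @examples
#' clinically_meaningful_bmi_change(c(22.1, 27.9))  # 1.1 and 1.4
clinically_meaningful_bmi_change <- function(bmi, fraction = 0.05) {
  round(fraction * bmi, 1)
}

#' Compose a full analysis report directory
#'
#' Runs the complete pipeline on one cohort — descriptives, balance,
#' estimate grid, density/attrition diagnostics, robustness battery — and
#' writes CSV/JSON artifacts plus a manifest (package version, R version,
#' seed, specification) into `out_dir`.
#'
#' @param data Cohort tibble.
#' @param outcome Primary outcome column name.
#' @param spec An [rd_spec()]; a `NULL` bandwidth is selected from the data.
#' @param out_dir Output directory (created if needed).
#' @param covariates Categorical covariates for descriptives and balance.
#' @param seed Seed recorded in the manifest (not used for computation;
#'   every report stage here is deterministic given the data).
#' @return Invisibly, a named list of the artifact paths.
#' @export
run_report <- function(data, outcome, spec = rd_spec(),
                       out_dir, covariates = c("sex", "marital", "smoking"),
                       seed = NA_integer_) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(spec$bandwidth)) {
    spec$bandwidth <- select_bandwidth(data, outcome, spec$cutoff)$h_opt
  }
  covariates <- intersect(covariates, names(data))
  paths <- list()
  wr <- function(obj, name) {
    p <- file.path(out_dir, name)
    readr::write_csv(obj, p, na = "")
    paths[[name]] <<- p
  }
  wr(descriptive_table(data, spec, covariates), "descriptives.csv")
  wr(balance_table(data, spec, covariates), "balance.csv")
  wr(fit_rd_grid(data, outcome, spec), "estimate_grid.csv")
  wr(attrition_continuity_test(data, spec), "attrition.csv")
  wr(placebo_cutoff_scan(data, outcome, spec), "placebo_cutoffs.csv")
  wr(donut_rd(data, outcome, spec,
              radii = c(0.5, 1.0, 1.5)[c(0.5, 1.0, 1.5) < spec$bandwidth]),
     "donut.csv")
  wr(bandwidth_sensitivity(data, outcome, spec), "bandwidth_sensitivity.csv")

  dens <- density_discontinuity_test(data$x, spec$cutoff)
  p_dens <- file.path(out_dir, "density_test.json")
  jsonlite::write_json(
    list(f_left = dens$f_left, f_right = dens$f_right,
         log_diff = dens$log_diff, se_log_diff = dens$se_log_diff,
         p_value = dens$p_value, method = dens$method_label),
    p_dens, auto_unbox = TRUE, digits = NA)
  paths[["density_test.json"]] <- p_dens

  main <- glance(fit_sharp_rd(data, outcome, spec))
  wr(main, "main_estimate.csv")

  manifest <- list(
    package = "rdscreen",
    package_version = as.character(utils::packageVersion("rdscreen")),
    r_version = R.version.string,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    spec = list(cutoff = spec$cutoff, bandwidth = spec$bandwidth,
                order = spec$order, kernel = spec$kernel,
                donut_radius = spec$donut_radius,
                alpha_level = spec$alpha_level, se_type = spec$se_type),
    outcome = outcome, n_rows = nrow(data)
  )
  p_man <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, p_man, auto_unbox = TRUE, digits = NA)
  paths[["manifest.json"]] <- p_man
  invisible(paths)
}
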