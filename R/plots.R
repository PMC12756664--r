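#' RD plot: binned scatter with side-specific fits
#'
#' Binned outcome means within the analysis window (bins never straddle
#' the cutoff; default 20 per side), side-specific fitted lines from the
#' local polynomial fit with pointwise Wald confidence bands, and a dashed
#' vertical line at the cutoff.
#'
#' @param data Cohort tibble.
#' @param outcome Outcome column name.
#' @param spec An [rd_spec()] with a set bandwidth.
#' @param fit Optional covariate-free `rd_fit` to draw; refitted from the
#'   data when `NULL` or when the supplied fit is covariate-adjusted.
#' @param bins_per_side Number of bins on each side of the cutoff.
#' @return A ggplot object.
#' @export
plot_rd <- function(data, outcome, spec = rd_spec(bandwidth = 2.9),
                    fit = NULL, bins_per_side = 20) {
  c0 <- spec$cutoff; h <- spec$bandwidth
  if (is.null(h)) stop("plot_rd needs a spec with a set bandwidth",
                       call. = FALSE)
  if (is.null(fit) || length(fit$covariate_set) > 0) {
    s <- spec; s$covariates <- character()
    fit <- fit_sharp_rd(data, outcome, s)
  }
  y <- data[[outcome]]
  keep <- !is.na(y) & abs(data$x - c0) <= h
  xw <- data$x[keep]; yw <- y[keep]

  edges_l <- seq(c0 - h, c0, length.out = bins_per_side + 1)
  edges_r <- seq(c0, c0 + h, length.out = bins_per_side + 1)
  bin_of <- ifelse(
    xw < c0,
    findInterval(xw, edges_l, rightmost.closed = TRUE),
    bins_per_side + findInterval(xw, edges_r, rightmost.closed = TRUE)
  )
  mids <- c(edges_l[-1] - diff(edges_l) / 2, edges_r[-1] - diff(edges_r) / 2)
  binned <- tibble::tibble(bin = bin_of, y = yw) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean_y = mean(.data$y), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(x = mids[.data$bin])

  pred_side <- function(side) {
    xc <- if (side == 0) seq(-h, 0, length.out = 100) else
      seq(0, h, length.out = 100)
    terms <- c("(Intercept)", "above", "xc", "above:xc")
    if (fit$order == 2) terms <- c(terms, "xc^2", "above:xc^2")
    X0 <- cbind(1, side, xc, side * xc)
    if (fit$order == 2) X0 <- cbind(X0, xc^2, side * xc^2)
    b <- fit$coefficients[terms]
    V <- fit$vcov[terms, terms]
    mu <- drop(X0 %*% b)
    se <- sqrt(rowSums((X0 %*% V) * X0))
    z <- qnorm(1 - fit$alpha_level / 2)
    tibble::tibble(x = c0 + xc, fit = mu, lo = mu - z * se, hi = mu + z * se,
                   side = if (side == 0) "below" else "above")
  }
  lines <- dplyr::bind_rows(pred_side(0), pred_side(1))

  ggplot2::ggplot() +
    ggplot2::geom_point(data = binned,
                        ggplot2::aes(x = .data$x, y = .data$mean_y),
                        alpha = 0.7) +
    ggplot2::geom_line(data = lines,
                       ggplot2::aes(x = .data$x, y = .data$fit,
                                    group = .data$side), linewidth = 1) +
    ggplot2::geom_line(data = lines,
                       ggplot2::aes(x = .data$x, y = .data$lo,
                                    group = .data$side), linewidth = 0.3) +
    ggplot2::geom_line(data = lines,
                       ggplot2::aes(x = .data$x, y = .data$hi,
                                    group = .data$side), linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = c0, linetype = "dashed") +
    ggplot2::labs(x = "Running variable (baseline BMI, kg/m²)",
                  y = outcome) +
    ggplot2::theme_minimal()
}

#' Running-variable density histogram
#'
#' Histogram of the running variable with bin edges aligned at the cutoff
#' and a dashed vertical cutoff line, the visual companion to
#' [density_discontinuity_test()].
#'
#' @param x Running-variable values (or a cohort tibble with column `x`).
#' @param cutoff Cutoff value.
#' @param bin_width Bin width; defaults to the density test's rule
#'   `2 * SD(x) * n^(-1/2)`.
#' @return A ggplot object.
#' @export
plot_density <- function(x, cutoff = 25, bin_width = NULL) {
  if (is.data.frame(x)) x <- x$x
  x <- x[is.finite(x)]
  b <- bin_width %||% (2 * sd(x) * length(x)^(-1 / 2))
  ggplot2::ggplot(tibble::tibble(x = x), ggplot2::aes(x = .data$x)) +
    ggplot2::geom_histogram(binwidth = b, boundary = cutoff,
                            fill = "grey60", color = "white") +
    ggplot2::geom_vline(xintercept = cutoff, linetype = "dashed") +
    ggplot2::labs(x = "Running variable (baseline BMI, kg/m²)",
                  y = "Count") +
    ggplot2::theme_minimal()
}

#' Forest plot of bandwidth-sensitivity estimates
#'
#' @param sensitivity Output of [bandwidth_sensitivity()] (or any tibble
#'   with `multiplier`, `tau_hat`, `ci_low`, `ci_high`).
#' @return A ggplot object.
#' @export
plot_sensitivity <- function(sensitivity) {
  ggplot2::ggplot(sensitivity,
                  ggplot2::aes(x = factor(.data$multiplier),
                               y = .data$tau_hat)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::labs(x = "Bandwidth multiplier", y = "Discontinuity estimate") +
    ggplot2::theme_minimal()
}

#' Forest plot of subgroup discontinuity estimates
#'
#' @param object A `subgroup_estimate` from [interaction_rd()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot subgroup_estimate
#' @export
autoplot.subgroup_estimate <- function(object, ...) {
  est <- object[object$estimable, , drop = FALSE]
  ggplot2::ggplot(est, ggplot2::aes(x = .data$level, y = .data$tau_hat)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = unique(est$subgroup), y = "Discontinuity estimate") +
    ggplot2::theme_minimal()
}
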