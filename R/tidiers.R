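#' Tidy a psychometric fit
#'
#' @param x A `psychometric_fit` from [fit_cumgauss()].
#' @param ... Unused.
#' @return A tibble with one row per parameter (`pse`, `threshold`).
#' @export
tidy.psychometric_fit <- function(x, ...) {
  tibble::tibble(
    term = c("pse", "threshold"),
    estimate = c(x$mu, x$sigma),
    std_error = c(x$se_mu, x$se_sigma)
  )
}

#' @rdname tidy.psychometric_fit
#' @return `glance()` returns a one-row model summary.
#' @export
glance.psychometric_fit <- function(x, ...) {
  tibble::tibble(mu = x$mu, sigma = x$sigma, loglik = x$loglik,
                 n_trials = x$n_trials, converged = x$converged)
}

#' Tidy a probit microstimulation test
#'
#' @param x A `probit_stim_test`.
#' @param ... Unused.
#' @return The coefficient tibble (`term`, `estimate`, `std_error`,
#'   `statistic`, `p_value`).
#' @export
tidy.probit_stim_test <- function(x, ...) x$coefficients

#' @rdname tidy.probit_stim_test
#' @export
glance.probit_stim_test <- function(x, ...) {
  tibble::tibble(p_pse = x$p_pse, p_slope = x$p_slope,
                 converged = x$converged, n_trials = x$n_trials)
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "<psychometric_fit> PSE = %.4g, threshold = %.4g (n = %d, %s)\n",
    x$mu, x$sigma, x$n_trials,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
print.probit_stim_test <- function(x, ...) {
  cat(sprintf("<probit_stim_test> p_pse = %.3g, p_slope = %.3g (n = %d)\n",
              x$p_pse, x$p_slope, x$n_trials))
  invisible(x)
}

#' Plot a psychometric fit with its data
#'
#' Observed choice proportions per level (point size by trial count) with
#' the fitted cumulative Gaussian.
#'
#' @param object A `psychometric_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psychometric_fit <- function(object, ...) {
  d <- dplyr::mutate(object$data, prop = .data$n_success / .data$n_total)
  xs <- seq(min(d$level), max(d$level), length.out = 200)
  curve <- tibble::tibble(level = xs,
                          prop = stats::pnorm((xs - object$mu) / object$sigma))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$level, y = .data$prop)) +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_total), alpha = 0.8) +
    ggplot2::scale_size_area(max_size = 3, guide = "none") +
    ggplot2::labs(x = "stimulus level", y = "proportion positive choice") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Control vs stimulated psychometric overlay for one session
#'
#' Fits and overlays the control and microstimulated psychometric functions
#' of one axis, the standard per-site display of a stimulation effect.
#'
#' @param trials One session's trial table.
#' @param plane "roll" or "translation".
#' @param construction Psychometric construction.
#' @return A ggplot object.
#' @export
plot_stim_effect <- function(trials, plane = c("roll", "translation"),
                             construction = c("normal", "general")) {
  plane <- match.arg(plane)
  construction <- match.arg(construction)
  pieces <- purrr::map(c(FALSE, TRUE), function(ms) {
    f <- fit_psychometric(trials, plane, construction, microstim = ms)
    d <- dplyr::mutate(f$data, prop = .data$n_success / .data$n_total,
                       microstim = ms)
    xs <- seq(min(d$level), max(d$level), length.out = 200)
    curve <- tibble::tibble(level = xs,
                            prop = stats::pnorm((xs - f$mu) / f$sigma),
                            microstim = ms)
    list(d = d, curve = curve)
  })
  pts <- dplyr::bind_rows(purrr::map(pieces, "d"))
  cvs <- dplyr::bind_rows(purrr::map(pieces, "curve"))
  lab <- c(`FALSE` = "control", `TRUE` = "microstim")
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$level, y = .data$prop,
                                    colour = factor(.data$microstim))) +
    ggplot2::geom_line(data = cvs) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "darkorange"),
                                 labels = lab, name = NULL) +
    ggplot2::labs(x = paste(plane, "axis"),
                  y = "proportion positive choice") +
    ggplot2::theme_minimal()
}

#' Sliding-window PSE-shift profile plot
#'
#' @param binned Output of [bin_dpse_by_preference()].
#' @return A ggplot object.
#' @export
plot_dpse_by_preference <- function(binned) {
  ggplot2::ggplot(binned, ggplot2::aes(x = .data$center, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "preferred direction (deg)",
                  y = "normalized PSE shift") +
    ggplot2::theme_minimal()
}
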