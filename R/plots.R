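# ggplot2 displays for sessions, traces, fits, sweeps and comparisons.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a staircase session
#'
#' Level trajectory over trials; filled points are correct responses.
#'
#' @param object A `staircase_session`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot staircase_session
#' @export
autoplot.staircase_session <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$trial, y = .data$level)) +
    ggplot2::geom_step(direction = "hv", colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(shape = factor(.data$response,
                                                    levels = c(1, 0),
                                                    labels = c("correct", "incorrect")))) +
    ggplot2::scale_shape_manual(values = c(correct = 16, incorrect = 1)) +
    ggplot2::labs(x = "Trial", y = "Disparity (log10 arcsec)", shape = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an adaptive-procedure estimate trace
#'
#' Stimulus placements (points) and the running threshold estimate
#' (line).
#'
#' @param object An `estimate_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot estimate_trace
#' @export
autoplot.estimate_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$trial)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$stimulus,
                                     shape = factor(.data$response,
                                                    levels = c(1, 0),
                                                    labels = c("correct", "incorrect"))),
                        colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$theta_hat), colour = "black") +
    ggplot2::scale_shape_manual(values = c(correct = 16, incorrect = 1)) +
    ggplot2::labs(x = "Trial", y = "log10 arcsec", shape = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a psychometric fit
#'
#' Observed proportions correct per level (point area proportional to the
#' number of trials) with the fitted logistic curve and the threshold at
#' the criterion.
#'
#' @param object A `psyfit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot psyfit
#' @export
autoplot.psyfit <- function(object, ...) {
  dat <- dplyr::mutate(object$data, p = .data$k / .data$n)
  xs <- seq(min(dat$level) - 0.2, max(dat$level) + 0.2, length.out = 200)
  curve <- tibble::tibble(
    level = xs,
    p = model_probability(xs, object$theta_hat, object$sigma_hat,
                          object$lambda_hat, object$task, object$criterion))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$level, y = .data$p)) +
    ggplot2::geom_line(data = curve, colour = "red") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.6) +
    ggplot2::geom_vline(xintercept = object$theta_hat, linetype = 2) +
    ggplot2::geom_hline(yintercept = object$criterion, linetype = 3) +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::labs(x = "Disparity (log10 arcsec)", y = "Proportion correct",
                  size = "Trials") +
    ggplot2::theme_minimal()
}

#' Plot a percentile-sweep result
#'
#' Mean bias (+/- 1 pooled SD) against the assumed spread, with the
#' optimal spread (minimum |bias x SD|) marked.
#'
#' @param object A `sweep_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sweep_result
#' @export
autoplot.sweep_result <- function(object, ...) {
  opt <- attr(object, "optimal_sigma")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$sigma_m, y = .data$mean_bias)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "red") +
    ggplot2::geom_vline(xintercept = opt, linetype = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_bias - .data$sd_bias,
                                        ymax = .data$mean_bias + .data$sd_bias),
                           width = 0.02, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Assumed spread (log10 arcsec)",
                  y = "Threshold bias (log10 arcsec)") +
    ggplot2::theme_minimal()
}

#' Plot a procedure comparison
#'
#' Mean threshold bias and SD against the number of trials, one line per
#' procedure.
#'
#' @param object A `procedure_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot procedure_comparison
#' @export
autoplot.procedure_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("mean_bias", "sd_bias"),
                              names_to = "metric", values_to = "value")
  long$metric <- factor(long$metric, c("mean_bias", "sd_bias"),
                        c("Threshold bias", "SD"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n_trials, y = .data$value,
                                     colour = .data$procedure)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Number of trials", y = "log10 arcsec",
                  colour = "Procedure") +
    ggplot2::theme_minimal()
}
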