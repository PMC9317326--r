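#' Plot group-by-visit uncertainty means
#'
#' Mean regression RMSE per group and visit with +/- 1 SE error bars —
#' the headline figure of the crossover analysis.
#'
#' @param summaries An [rmse_table()] tibble.
#' @return A ggplot object.
#' @export
plot_rmse_means <- function(summaries) {
  cells <- cell_means(summaries) |>
    dplyr::mutate(se = .data$sd_rmse / sqrt(.data$n),
                  visit = factor(.data$visit))
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$visit, y = .data$mean_rmse,
                                      group = .data$group,
                                      colour = .data$group)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(0.15)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean_rmse - .data$se,
                   ymax = .data$mean_rmse + .data$se),
      position = ggplot2::position_dodge(0.15)) +
    ggplot2::labs(x = "Visit", y = "Uncertainty (regression RMSE, cm)",
                  colour = "Group") +
    ggplot2::theme_minimal()
}

#' Plot one unit's deviation-vs-shift scatter with its fitted line
#'
#' The per-participant view behind the uncertainty metric: each trial's
#' imposed shift against its response deviation, the OLS line, and the
#' slope/RMSE annotation.
#'
#' @param trials Trial rows for a single participant-visit (or any subset
#'   with `shift` and `deviation`).
#' @return A ggplot object.
#' @export
plot_deviation_fit <- function(trials) {
  s <- fit_deviation_regression(trials)
  ggplot2::ggplot(trials, ggplot2::aes(x = .data$shift, y = .data$deviation)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(intercept = s$intercept, slope = s$slope,
                         colour = "red") +
    ggplot2::labs(
      x = "Imposed cursor shift (cm)", y = "Radial deviation (cm)",
      subtitle = sprintf("slope %.3f, RMSE %.3f cm, n = %d",
                         s$slope, s$rmse, s$n_trials)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot a CoP trace
#'
#' Sway path in the support plane with the base-of-support boundary.
#'
#' @param object A `cop_trace`.
#' @param bos A [base_of_support()] to draw, or `NULL`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cop_trace <- function(object, bos = base_of_support(), ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$ml, y = .data$ap)) +
    ggplot2::geom_path(alpha = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Medio-lateral (cm)", y = "Antero-posterior (cm)") +
    ggplot2::theme_minimal()
  if (!is.null(bos) && bos$shape == "ellipse") {
    th <- seq(0, 2 * pi, length.out = 200)
    ring <- tibble::tibble(ml = bos$center[1] + bos$a_ml * cos(th),
                           ap = bos$center[2] + bos$b_ap * sin(th))
    p <- p + ggplot2::geom_path(data = ring, linetype = "dashed",
                                colour = "grey40")
  }
  p
}

#' Autoplot a VTC series
#'
#' Per-sample virtual time-to-contact over the trial, capped samples
#' highlighted.
#'
#' @param object A `vtc_series` from [vtc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vtc_series <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$t, y = .data$tau,
                               colour = .data$capped)) +
    ggplot2::geom_line(ggplot2::aes(group = 1)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::labs(x = "Time (s)", y = "Virtual time-to-contact (s)") +
    ggplot2::theme_minimal()
}
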