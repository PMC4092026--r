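#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Box-plot panel of grid metrics and accuracy
#'
#' Reproduces the study's box-and-whisker view: one panel per quantity
#' (the four metrics and test accuracy), boxes over the seeds of each
#' rule-by-topology cell. Invalid spectral-radius runs are dropped from that
#' panel.
#'
#' @param object A `reservoir_grid` from [run_grid()].
#' @param quantities Which quantities to facet (default all five).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reservoir_grid <- function(object,
                                    quantities = c("separation",
                                                   "kernel_quality",
                                                   "lyapunov",
                                                   "spectral_radius",
                                                   "test_accuracy"),
                                    ...) {
  ok <- object[is.na(object$error), ]
  long <- tidyr::pivot_longer(
    ok[, c("rule", "topology", "spectral_radius_valid", quantities)],
    cols = dplyr::all_of(quantities),
    names_to = "quantity", values_to = "value")
  long <- dplyr::filter(long, .data$quantity != "spectral_radius" |
                          .data$spectral_radius_valid)
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$rule, y = .data$value,
                               fill = .data$topology)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "plasticity rule", y = NULL, fill = "connectivity") +
    ggplot2::theme_minimal()
}

#' Scatter of each metric against test accuracy
#'
#' The per-run metric values plotted against readout test accuracy, one panel
#' per metric, with invalid spectral radii shown at zero as in the grid
#' correlations.
#'
#' @param records A `reservoir_grid`.
#' @return A ggplot object.
#' @export
plot_metric_correlation <- function(records) {
  ok <- records[is.na(records$error), ]
  ok$spectral_radius <- ifelse(ok$spectral_radius_valid,
                               ok$spectral_radius, 0)
  long <- tidyr::pivot_longer(
    ok[, c("rule", "test_accuracy", "separation", "kernel_quality",
           "lyapunov", "spectral_radius")],
    cols = c("separation", "kernel_quality", "lyapunov", "spectral_radius"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value,
                                     y = .data$test_accuracy,
                                     colour = .data$rule)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~metric, scales = "free_x") +
    ggplot2::labs(x = "metric value", y = "test accuracy",
                  colour = "plasticity rule") +
    ggplot2::theme_minimal()
}

#' Plot a stretch of the tri-function benchmark signal
#'
#' @param object A `tri_function_signal`.
#' @param n_steps How many initial steps to show (default 500).
#' @param ... Unused.
#' @return A ggplot object colouring the signal by active generator.
#' @export
autoplot.tri_function_signal <- function(object, n_steps = 500L, ...) {
  d <- object[seq_len(min(n_steps, nrow(object))), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$step, y = .data$value,
                                  colour = .data$generator, group = 1)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "timestep", y = "signal", colour = "generator") +
    ggplot2::theme_minimal()
}
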