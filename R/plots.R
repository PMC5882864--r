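#' Plot a psychometric curve
#'
#' @param object A `choicenet_psychfit`.
#' @param ... Unused.
#' @return A ggplot: per-bin fraction of left choices against the
#'   expected-value difference, with the fitted tanh sigmoid.
#' @export
autoplot.choicenet_psychfit <- function(object, ...) {
  grid <- tibble::tibble(ev_diff = seq(-2, 2, length.out = 201))
  grid$p_left <- 0.5 * (1 + tanh(object$k * (grid$ev_diff - object$b)))
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$ev_diff, y = .data$p_left)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(x = "EV(left) - EV(right)", y = "P(choose left)",
                  size = "trials") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Plot tuning fractions by layer
#'
#' @param fractions Output of [tuning_fractions()].
#' @param variables Variables to show (default reward, probability, choice,
#'   position of the left offer).
#' @return A ggplot of the fraction of tuned units per hidden layer.
#' @export
plot_tuning_fractions <- function(fractions,
                                  variables = c("rew_L", "prob_L",
                                                "choice", "pos")) {
  d <- dplyr::filter(fractions, .data$variable %in% variables)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$layer),
                                  y = 100 * .data$fraction,
                                  colour = .data$variable,
                                  group = .data$variable)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "hidden layer", y = "% tuned units", colour = NULL) +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::theme_minimal()
}

#' Plot layer-wise beta correlations
#'
#' @param correlations Output of [beta_correlation()] (rows for several
#'   layers and variable pairs).
#' @return A ggplot of Pearson rho against hidden layer, one line per
#'   variable pair and mode.
#' @export
plot_beta_correlations <- function(correlations) {
  d <- dplyr::mutate(correlations,
                     pair = paste0(.data$var_x, " ~ ", .data$var_y,
                                   ifelse(.data$mode == "unsigned",
                                          " (|beta|)", "")))
  d <- dplyr::filter(d, !is.na(.data$layer))
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$layer), y = .data$rho,
                                  colour = .data$pair, group = .data$pair)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "hidden layer", y = "Pearson rho", colour = NULL) +
    ggplot2::coord_cartesian(ylim = c(-1, 1)) +
    ggplot2::theme_minimal()
}

#' Plot the lesion sweep
#'
#' @param lesions Output of [lesion_sweep()].
#' @param measure `"accuracy"` (default) or `"crossing_slope"`.
#' @return A ggplot of the ensemble-mean measure against lesion fraction,
#'   one line per target.
#' @export
plot_lesions <- function(lesions, measure = c("accuracy", "crossing_slope")) {
  measure <- match.arg(measure)
  d <- lesions |>
    dplyr::group_by(.data$target, .data$fraction) |>
    dplyr::summarise(value = mean(.data[[measure]]),
                     se = stats::sd(.data[[measure]]) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fraction, y = .data$value,
                                  colour = .data$target,
                                  group = .data$target)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$value - .data$se,
                                        ymax = .data$value + .data$se),
                           width = 0.01) +
    ggplot2::labs(x = "lesion fraction", y = measure, colour = "target") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
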