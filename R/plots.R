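#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot observed versus fitted proportions for one group
#'
#' Grouped bars per task (DB, KA, FB): observed proportion correct next to
#' the fitted model value, the standard presentation for ToM-scale fits.
#'
#' @param object A `tom_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tom_fit
#' @export
autoplot.tom_fit <- function(object, ...) {
  df <- predicted_vs_observed(object) |>
    tidyr::pivot_longer(c("observed", "fitted"),
                        names_to = "source", values_to = "proportion") |>
    dplyr::mutate(task = factor(.data$task, levels = c("DB", "KA", "FB")),
                  source = factor(.data$source,
                                  levels = c("observed", "fitted")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$task, y = .data$proportion,
                                   fill = .data$source)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::scale_fill_manual(values = c(observed = "#E69F00",
                                          fitted = "#009E73")) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "task", y = "proportion correct", fill = NULL,
                  title = object$data$label) +
    ggplot2::theme_minimal()
}

#' Plot observed versus fitted proportions for every group of a report
#'
#' @param object A `tom_report` object.
#' @param ... Unused.
#' @return A ggplot object, facetted by group.
#' @method autoplot tom_report
#' @export
autoplot.tom_report <- function(object, ...) {
  df <- object$comparison |>
    tidyr::pivot_longer(c("observed", "fitted"),
                        names_to = "source", values_to = "proportion") |>
    dplyr::mutate(task = factor(.data$task, levels = c("DB", "KA", "FB")),
                  source = factor(.data$source,
                                  levels = c("observed", "fitted")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$task, y = .data$proportion,
                                   fill = .data$source)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::facet_wrap(~group) +
    ggplot2::scale_fill_manual(values = c(observed = "#E69F00",
                                          fitted = "#009E73")) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "task", y = "proportion correct", fill = NULL) +
    ggplot2::theme_minimal()
}

#' False-belief probability surface over the two ability parameters
#'
#' Visualises the bilinear multiplicative prediction: at fixed noise, the
#' false-belief probability is linear in each of `pi_B` and `pi_V` with slope
#' set by the other.
#'
#' @param delta,epsilon Noise parameters held fixed (default 0).
#' @param n_grid Grid points per axis.
#' @return A ggplot object (filled raster with contours).
#' @export
plot_false_belief_surface <- function(delta = 0, epsilon = 0, n_grid = 101L) {
  grid <- tidyr::expand_grid(pi_B = seq(0, 1, length.out = n_grid),
                             pi_V = seq(0, 1, length.out = n_grid))
  grid$pi_FB <- grid$pi_B * grid$pi_V * (1 - epsilon) +
    (1 - grid$pi_B * grid$pi_V) * delta
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$pi_B, y = .data$pi_V,
                                     fill = .data$pi_FB)) +
    ggplot2::geom_raster() +
    ggplot2::geom_contour(ggplot2::aes(z = .data$pi_FB),
                          colour = "white", linewidth = 0.2) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = expression(pi[B]), y = expression(pi[V]),
                  fill = expression(pi[FB])) +
    ggplot2::theme_minimal()
}
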