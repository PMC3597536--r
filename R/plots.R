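# ggplot2 views of the result objects.

#' Plot a differentiation trajectory
#'
#' Cluster-number (UCN/DCN) and Oct4+ fraction curves against
#' normalised time.
#'
#' @param object An `eb_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eb_trajectory <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("ucn", "dcn"), names_to = "metric",
                        values_to = "clusters")
  ggplot2::ggplot(df, ggplot2::aes(.data$tau, .data$clusters,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_line(ggplot2::aes(y = .data$frac_pos *
                                      max(df$clusters)),
                       linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(
      values = c(ucn = "#00B0B0", dcn = "#202090"),
      labels = c(ucn = "UCN (Oct4+)", dcn = "DCN (Oct4-)")) +
    ggplot2::labs(x = expression(tau), y = "cluster number",
                  colour = NULL,
                  caption = "dashed: Oct4+ fraction (rescaled)") +
    ggplot2::theme_minimal()
}

#' Plot a growth trajectory
#'
#' Cell count on a log scale against time, with the fitted exponential
#' doubling time in the subtitle.
#'
#' @param object An `eb_growth`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eb_growth <- function(object, ...) {
  fit <- fit_doubling_time(object)
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$time, .data$n_cells)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (h)", y = "cells",
                  subtitle = sprintf("fitted doubling time %.1f h (R² = %.3f)",
                                     fit$doubling_time, fit$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot a virtual section
#'
#' Disk plot of a section with the standard colours: Oct4+ cyan,
#' Oct4- dark blue.
#'
#' @param section A [virtual_section()] result.
#' @return A ggplot.
#' @export
plot_section <- function(section) {
  df <- as_tibble(section)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$radius,
                                     colour = .data$state)) +
    ggplot2::scale_colour_manual(values = c(POS = "#00FFFF",
                                            NEG = "#0D0D8C")) +
    ggplot2::scale_size_identity() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)", colour = "Oct4") +
    ggplot2::theme_minimal()
}

#' Plot a pattern-class distribution
#'
#' Stacked class fractions over time.
#'
#' @param dist Output of [pattern_distribution()].
#' @param time_col Time column name.
#' @return A ggplot.
#' @export
plot_pattern_distribution <- function(dist, time_col = "tau") {
  ggplot2::ggplot(dist, ggplot2::aes(.data[[time_col]], .data$fraction,
                                     fill = .data$class)) +
    ggplot2::geom_col(width = diff(range(dist[[time_col]])) /
                        max(1, dplyr::n_distinct(dist[[time_col]])) * 0.9) +
    ggplot2::scale_fill_brewer(palette = "Spectral") +
    ggplot2::labs(y = "fraction of snapshots") +
    ggplot2::theme_minimal()
}
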