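phase_colors <- c(rapid = "#2e7d32", shotgun = "#f9a825", inactive = "#757575")

#' Plot TE abundance trajectories of replicate invasions
#'
#' One line per replicate, colored by invasion phase (rapid / shotgun /
#' inactive).
#'
#' @param object A `te_invasion_set`.
#' @param y Trajectory column to plot (default mean insertions per
#'   individual).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.te_invasion_set <- function(object, y = "mean_n", ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation, y = .data[[y]],
                                   group = .data$replicate,
                                   color = .data$phase)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::scale_color_manual(values = phase_colors, drop = FALSE) +
    ggplot2::labs(x = "generation", y = y, color = "phase") +
    ggplot2::theme_minimal()
}

#' @rdname run_invasion
#' @param object A `te_invasion`.
#' @param y Trajectory column to plot.
#' @export
autoplot.te_invasion <- function(object, y = "mean_n", ...) {
  df <- object$trajectory
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation, y = .data[[y]],
                                   color = .data$phase, group = 1)) +
    ggplot2::geom_line() +
    ggplot2::scale_color_manual(values = phase_colors, drop = FALSE) +
    ggplot2::labs(x = "generation", y = y, color = "phase") +
    ggplot2::theme_minimal()
}

#' @rdname establishment_experiment
#' @param object A `te_establishment`.
#' @export
autoplot.te_establishment <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$bias, y = .data$frequency)) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$expected),
                        linetype = "dashed", color = "red") +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "insertion bias",
                  y = "establishment frequency") +
    ggplot2::theme_minimal()
}

#' @rdname fitness_sweep
#' @export
autoplot.te_sweep <- function(object, ...) {
  pal <- c("fail-w" = "grey80", "fail-0" = "#1b5e20",
           "dark-red" = "#7f0000", "red" = "#d32f2f",
           "yellow" = "#fbc02d", "green" = "#66bb6a")
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(x = factor(.data$clusters_kb),
                               y = factor(.data$bias),
                               fill = .data$category)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_manual(values = pal, drop = FALSE) +
    ggplot2::labs(x = "piRNA cluster size (kb/chromosome)",
                  y = "insertion bias", fill = "min fitness") +
    ggplot2::theme_minimal()
}

#' @rdname competition_experiment
#' @param object A `te_competition`.
#' @export
autoplot.te_competition <- function(object, ...) {
  df <- object$pairs
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bias_high, y = .data$bias_low,
                                   fill = .data$S)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = df[df$absent, ], color = "grey50", size = 1) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  limits = c(-1, 1), na.value = "grey90") +
    ggplot2::labs(x = "bias of more cluster-biased TE",
                  y = "bias of less cluster-biased TE",
                  fill = "S") +
    ggplot2::theme_minimal()
}
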