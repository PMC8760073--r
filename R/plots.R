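# ggplot2 displays for the main result types.

#' Plot a spike density function
#'
#' @param object An `sdf` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sdf <- function(object, ...) {
  ggplot(object, aes(time, rate)) +
    geom_line(color = "steelblue") +
    labs(x = "Time (ms)", y = "Rate (Hz)", title = "Spike density function")
}

#' Plot session-average ranked tuning curves with fitted lines
#'
#' @param object A `ranked_slope` result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ranked_slope <- function(object, ...) {
  curve <- attr(object, "curve")
  ggplot(curve, aes(rank_, mean_rate, color = period)) +
    geom_point() +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                linewidth = 0.5) +
    scale_x_continuous(breaks = 1:9) +
    labs(x = "Location rank (1 = preferred)", y = "Mean normalized rate",
         color = "Period", title = "Ranked target selectivity")
}

#' Plot the greedy ensemble accuracy curve
#'
#' @param object A `greedy_ensemble` result.
#' @param chance Chance level to mark.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.greedy_ensemble <- function(object, chance = 1 / 3, ...) {
  ggplot(object, aes(size, accuracy)) +
    geom_line() +
    geom_point() +
    geom_hline(yintercept = chance, linetype = "dashed", color = "grey50") +
    labs(x = "Ensemble size", y = "Decoding accuracy",
         title = "Greedy ensemble construction")
}

#' Plot the waveform-width mixture with the class boundary
#'
#' @param object A `width_mixture` fit.
#' @param binwidth Histogram bin width (µs).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.width_mixture <- function(object, binwidth = 20, ...) {
  xs <- seq(min(object$widths), max(object$widths), length.out = 400)
  dens <- bind_rows(
    tibble(x = xs, component = "narrow",
           dens = object$weights[1] * dnorm(xs, object$means[1],
                                            object$sds[1])),
    tibble(x = xs, component = "broad",
           dens = object$weights[2] * dnorm(xs, object$means[2],
                                            object$sds[2]))
  )
  p <- ggplot(tibble(width = object$widths), aes(width)) +
    geom_histogram(aes(y = after_stat(density)), binwidth = binwidth,
                   fill = "grey80", color = "grey60") +
    geom_line(data = dens, aes(x, dens, color = component)) +
    labs(x = "Trough-to-peak width (µs)", y = "Density",
         title = "Waveform width mixture")
  if (!is.na(object$threshold)) {
    p <- p + geom_vline(xintercept = object$threshold,
                        linetype = "dotted")
  }
  p
}

#' Tile map of trajectory grid occupancy
#'
#' @param object A `trajectory_occupancy` result.
#' @param condition Target location to display, or `NULL` to facet all.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trajectory_occupancy <- function(object, condition = NULL, ...) {
  d <- object$percent
  if (!is.null(condition)) d <- d |> filter(target_location == condition)
  ggplot(d, aes(cell_col, cell_row, fill = percent)) +
    geom_tile() +
    facet_wrap(~target_location) +
    scale_fill_viridis_c(limits = c(0, 100)) +
    coord_equal() +
    labs(x = "Column", y = "Row", fill = "% trials",
         title = "Trajectory grid occupancy")
}

#' Scatter of theoretical versus empirical decoding accuracy
#'
#' @param sweep A [random_ensemble_sweep()] result.
#' @return A ggplot.
#' @export
plot_dpe_dpt <- function(sweep) {
  ggplot(sweep, aes(dpt, dpe, color = factor(size))) +
    geom_abline(linetype = "dashed", color = "grey50") +
    geom_point(alpha = 0.5) +
    coord_equal(xlim = c(0.4, 1), ylim = c(0.4, 1)) +
    labs(x = "Theoretical accuracy (DPt)", y = "Empirical accuracy (DPe)",
         color = "Ensemble size")
}

#' Population signal and projected precision by period
#'
#' @param sweep A [random_ensemble_sweep()] result.
#' @param top_only Restrict to top-quartile ensembles.
#' @return A ggplot.
#' @export
plot_popcode_periods <- function(sweep, top_only = TRUE) {
  d <- if (top_only) sweep |> filter(top75) else sweep
  d |>
    tidyr::pivot_longer(c(ps, pp), names_to = "component",
                        values_to = "value") |>
    mutate(period = factor(period, levels = PERIOD_LEVELS)) |>
    ggplot(aes(period, value, fill = period)) +
    geom_boxplot(outlier.size = 0.5) +
    facet_wrap(~component, scales = "free_y",
               labeller = as_labeller(c(ps = "Population signal",
                                        pp = "Projected precision"))) +
    guides(fill = "none") +
    labs(x = NULL, y = NULL)
}
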