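# Narrow- vs broad-spiking classification from spike-waveform
# trough-to-peak width: spline upsampling, outlier removal, 1- vs
# 2-Gaussian model selection and an intersection threshold.

#' Trough-to-peak width of a mean waveform
#'
#' Upsamples the waveform with a cubic spline (x100 by default) and
#' measures the absolute time between the global voltage minimum and
#' maximum, in microseconds. Waveforms without both a positive and a
#' negative deflection (non-biphasic) are rejected.
#'
#' @param mean_waveform Numeric voltage vector.
#' @param sample_interval_us Sampling interval of the waveform (µs; 33.3
#'   at 30 kHz).
#' @param upsample Upsampling factor.
#' @return Width in µs, or `NA` with a `reason` attribute when the
#'   waveform is not biphasic.
#' @export
waveform_width <- function(mean_waveform, sample_interval_us = 1e6 / 30000,
                           upsample = 100) {
  v <- as.numeric(mean_waveform)
  if (length(v) < 4 || max(v) <= 0 || min(v) >= 0) {
    out <- NA_real_
    attr(out, "reason") <- "not biphasic"
    return(out)
  }
  t <- (seq_along(v) - 1) * sample_interval_us
  up <- spline(t, v, n = length(v) * upsample)
  abs(up$x[which.max(up$y)] - up$x[which.min(up$y)])
}

# Crossing point of two weighted Gaussian densities between their means.
gaussian_crossing <- function(m1, s1, w1, m2, s2, w2) {
  if (m1 > m2) {
    tmp <- c(m1, s1, w1)
    m1 <- m2; s1 <- s2; w1 <- w2
    m2 <- tmp[1]; s2 <- tmp[2]; w2 <- tmp[3]
  }
  if (isTRUE(all.equal(m1, m2))) return(NA_real_)
  a <- 1 / (2 * s2^2) - 1 / (2 * s1^2)
  b <- m1 / s1^2 - m2 / s2^2
  cc <- m2^2 / (2 * s2^2) - m1^2 / (2 * s1^2) + log(w1 / s1) - log(w2 / s2)
  roots <- if (abs(a) < 1e-12) {
    if (abs(b) < 1e-12) numeric(0) else -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) numeric(0)
    else (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  inside <- roots[roots > m1 & roots < m2]
  if (length(inside) == 0) NA_real_ else inside[1]
}

#' Fit the waveform-width mixture and select a class boundary
#'
#' Fits both a single Gaussian and a two-component Gaussian mixture to
#' the widths by maximum likelihood and compares them with the Akaike
#' Information Criterion. When the two-component model wins, the NS/BS
#' boundary is placed at the intersection of the two weighted component
#' densities between the component means (the valley of the fitted
#' bimodal density).
#'
#' @param widths Numeric vector of trough-to-peak widths (µs), outliers
#'   already removed; at least 50 values required.
#' @return Object of class `width_mixture`: component parameters, AIC of
#'   both models, the winning model and the threshold (`NA` when the
#'   single-Gaussian model wins or the fit is degenerate).
#' @export
fit_width_mixture <- function(widths) {
  widths <- widths[!is.na(widths)]
  if (length(widths) < 50) {
    abort("Need at least 50 widths to fit the mixture.",
          class = "wmdecode_input_error")
  }
  n <- length(widths)
  # 1-Gaussian MLE
  m <- mean(widths)
  s <- sqrt(sum((widths - m)^2) / n)
  ll1 <- sum(dnorm(widths, m, s, log = TRUE))
  aic1 <- 2 * 2 - 2 * ll1
  # 2-Gaussian mixture (unequal variances)
  fit2 <- Mclust(widths, G = 2, modelNames = "V", verbose = FALSE)
  if (is.null(fit2)) {
    abort("Two-component mixture fit failed to converge.",
          class = "wmdecode_fit_error")
  }
  mu <- fit2$parameters$mean
  sdv <- sqrt(fit2$parameters$variance$sigmasq)
  if (length(sdv) == 1) sdv <- rep(sdv, 2)
  pro <- fit2$parameters$pro
  ord <- order(mu)
  mu <- mu[ord]; sdv <- sdv[ord]; pro <- pro[ord]
  aic2 <- 2 * 5 - 2 * fit2$loglik

  model <- if (aic2 < aic1) "2-gaussian" else "1-gaussian"
  threshold <- NA_real_
  degenerate <- FALSE
  if (model == "2-gaussian") {
    threshold <- gaussian_crossing(mu[1], sdv[1], pro[1],
                                   mu[2], sdv[2], pro[2])
    if (is.na(threshold)) {
      degenerate <- TRUE
      warn("Degenerate mixture fit: no crossing between component means; all units fall in one class.")
    }
  }
  structure(
    list(means = mu, sds = sdv, weights = pro,
         single = c(mean = m, sd = s),
         aic_1g = aic1, aic_2g = aic2, model = model,
         threshold = threshold, degenerate = degenerate,
         n = n, widths = widths),
    class = "width_mixture"
  )
}

#' @export
print.width_mixture <- function(x, ...) {
  cat(sprintf("<width_mixture> n=%d, model=%s (AIC 1G=%.1f, 2G=%.1f)\n",
              x$n, x$model, x$aic_1g, x$aic_2g))
  if (!is.na(x$threshold)) {
    cat(sprintf("  components: %.0f +/- %.0f (w=%.2f) | %.0f +/- %.0f (w=%.2f)\n",
                x$means[1], x$sds[1], x$weights[1],
                x$means[2], x$sds[2], x$weights[2]))
    cat(sprintf("  NS/BS threshold: %.1f us\n", x$threshold))
  }
  invisible(x)
}

#' @rdname fit_width_mixture
#' @param x A `width_mixture`.
#' @param ... Unused.
#' @export
tidy.width_mixture <- function(x, ...) {
  tibble(component = c("narrow", "broad"),
         mean = x$means, sd = x$sds, weight = x$weights)
}

#' @rdname fit_width_mixture
#' @export
glance.width_mixture <- function(x, ...) {
  tibble(model = x$model, aic_1g = x$aic_1g, aic_2g = x$aic_2g,
         threshold = x$threshold, n = x$n)
}

#' Classify units as narrow- or broad-spiking
#'
#' Measures every single unit's trough-to-peak width ([waveform_width()]),
#' removes outlier widths above `outlier_us`, fits the width mixture and
#' labels units below the fitted threshold `NS` and at or above it `BS`
#' (widths exactly at the boundary go to `BS`). Units with non-biphasic
#' waveforms or outlier widths are labelled `excluded`.
#'
#' The mixture needs at least 50 widths; when one session is too small,
#' fit the mixture on widths pooled across sessions and pass it in via
#' `mixture`.
#'
#' @param units Units table with `unit_id`, `is_single`,
#'   `sample_interval_us` and the `mean_waveform` list-column.
#' @param outlier_us Outlier cut on width (µs) applied before fitting.
#' @param single_only Restrict to well-isolated single units.
#' @param mixture Optional precomputed [fit_width_mixture()] result (e.g.
#'   pooled across sessions); when `NULL` the mixture is fit to this
#'   table's widths.
#' @return Tibble `unit_id`, `width`, `class` with the `width_mixture`
#'   fit in `attr(, "fit")`.
#' @export
classify_waveforms <- function(units, outlier_us = 675, single_only = TRUE,
                               mixture = NULL) {
  u <- if (single_only) units |> filter(is_single) else units
  widths <- purrr::map2_dbl(u$mean_waveform, u$sample_interval_us,
                            function(wf, si) waveform_width(wf, si))
  tab <- tibble(unit_id = u$unit_id, width = widths) |>
    mutate(excluded = is.na(width) | width > outlier_us)
  fit <- mixture %||% fit_width_mixture(tab$width[!tab$excluded])
  tab <- tab |>
    mutate(class = dplyr::case_when(
      excluded ~ "excluded",
      is.na(fit$threshold) ~ "BS",
      width < fit$threshold ~ "NS",
      TRUE ~ "BS"
    )) |>
    select(unit_id, width, class)
  attr(tab, "fit") <- fit
  tab
}
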