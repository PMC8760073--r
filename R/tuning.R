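# Single-unit spatial tuning: epoch rates, balanced-subsample ANOVA
# selectivity, ranked tuning slopes, spike density functions, plane fits.

epoch_window <- function(trials, epoch) {
  switch(match.arg(epoch, EPOCH_LEVELS),
    cue = cbind(trials$cue_on, trials$delay_on),
    delay = cbind(trials$delay_on, trials$response_on),
    response = cbind(trials$response_on,
                     pmin(trials$response_on + 2000, trials$trial_end))
  )
}

#' Epoch-averaged firing rates
#'
#' Counts each unit's spikes inside the trial's half-open epoch window
#' `[on, off)` and divides by the window duration. The cue window is
#' 3000 ms, the delay 2000 ms and the response window the first 2000 ms of
#' navigation.
#'
#' @param spikes Tibble `unit_id`, `time` (ms).
#' @param trials Trials table (see [session_recording()]).
#' @param epoch `"cue"`, `"delay"` or `"response"`.
#' @param unit_ids Units to include (default: all in `spikes`).
#' @return Long tibble `trial_id`, `unit_id`, `rate` (Hz) with explicit
#'   zeros for silent trials.
#' @export
epoch_rates <- function(spikes, trials, epoch = "delay",
                        unit_ids = sort(unique(spikes$unit_id))) {
  win <- epoch_window(trials, epoch)
  dur <- win[, 2] - win[, 1]
  if (any(dur <= 0)) {
    abort("Zero-length epoch window.", class = "wmdecode_input_error")
  }
  ord <- order(win[, 1])
  on_sorted <- win[ord, 1]
  off_sorted <- win[ord, 2]
  trial_sorted <- trials$trial_id[ord]

  sp <- spikes |> filter(unit_id %in% unit_ids)
  idx <- findInterval(sp$time, on_sorted)
  ok <- idx >= 1 & sp$time < off_sorted[pmax(idx, 1)]
  counts <- tibble(unit_id = sp$unit_id[ok],
                   trial_id = trial_sorted[idx[ok]]) |>
    count(unit_id, trial_id, name = "n_spikes")

  tidyr::expand_grid(trial_id = trials$trial_id, unit_id = unit_ids) |>
    left_join(counts, by = c("unit_id", "trial_id")) |>
    left_join(tibble(trial_id = trials$trial_id, dur_ms = dur),
              by = "trial_id") |>
    mutate(rate = dplyr::coalesce(.data$n_spikes, 0L) / (.data$dur_ms / 1000)) |>
    select(trial_id, unit_id, rate)
}

#' Per-trial epoch rates joined with trial condition labels
#'
#' Convenience accessor: epoch rates for every unit in the session, long
#' format, with `location`, `target_column`, `target_side`, `outcome` and
#' `period` attached. This is the table most decoding and population-code
#' entry points consume.
#'
#' @param session A `session_recording`.
#' @param epoch Task epoch.
#' @return Long tibble `trial_id`, `unit_id`, `rate`, `location`,
#'   `target_column`, `target_side`, `outcome`, `period`.
#' @export
session_epoch_rates <- function(session, epoch = "delay") {
  epoch_rates(session$spikes, session$trials, epoch,
              unit_ids = sort(session$units$unit_id)) |>
    left_join(session$trials |>
                select(trial_id, location = target_location,
                       target_column, target_side, outcome, period),
              by = "trial_id")
}

ow_p <- function(rate, loc) {
  if (length(unique(loc)) < 2 || var(rate) == 0) return(NA_real_)
  p <- tryCatch(
    oneway.test(rate ~ factor(loc), var.equal = TRUE)$p.value,
    error = function(e) NA_real_
  )
  if (is.nan(p)) NA_real_ else p
}

#' Spatial-selectivity test with balanced subsampling
#'
#' One-way fixed-effects ANOVA of per-trial epoch rates on target location,
#' run per unit and period. To equalize sample size across injection
#' periods, each location is subsampled without replacement to the unit's
#' minimum per-period-per-location trial count; the procedure is repeated
#' `n_subsample` times and the median p-value taken. When trial counts are
#' already equal the subsample is the full data and the median equals the
#' plain ANOVA p-value.
#'
#' Preferred / least-preferred locations are the locations with the
#' largest / smallest full-data mean rate; ties are broken toward the
#' lowest location index and flagged.
#'
#' @param rates Long tibble with columns `unit_id`, `period`, `location`,
#'   `rate` (one row per trial).
#' @param alpha Selectivity threshold on the median p (0.05 for the tuning
#'   census; 0.1 for the cell-type inclusion analysis).
#' @param n_subsample Number of balanced subsample repetitions.
#' @param seed Master seed; each unit consumes a derived child seed.
#' @return Tibble with one row per unit x period: `anova_p` (median over
#'   subsamples), `selective`, `skipped`, `n_per_location`,
#'   `preferred_location`, `least_preferred_location`, `tie` and a
#'   `location_means` list-column.
#' @export
anova_selectivity <- function(rates, alpha = 0.05, n_subsample = 50,
                              seed = 1) {
  stopifnot(all(c("unit_id", "period", "location", "rate") %in% names(rates)))
  purrr::map_dfr(split(rates, rates$unit_id), function(ur) {
    uid <- ur$unit_id[[1]]
    cnt <- ur |> count(period, location)
    n_min <- min(cnt$n)
    periods <- unique(ur$period)

    means <- ur |>
      group_by(period, location) |>
      summarise(mean_rate = mean(rate), .groups = "drop")
    prefs <- means |>
      group_by(period) |>
      summarise(
        preferred_location = location[which.max(mean_rate)],
        least_preferred_location = location[which.min(mean_rate)],
        tie = sum(mean_rate == max(mean_rate)) > 1 |
          sum(mean_rate == min(mean_rate)) > 1,
        .groups = "drop"
      )

    if (n_min < 2) {
      return(tibble(unit_id = uid, period = periods,
                    n_per_location = n_min, anova_p = NA_real_,
                    selective = NA, skipped = TRUE) |>
               left_join(prefs, by = "period") |>
               mutate(location_means = purrr::map(period, function(p) {
                 means |> filter(period == p) |> select(location, mean_rate)
               })))
    }

    # index lists per period x location for fast repeated subsampling
    grp <- split(seq_len(nrow(ur)), paste(ur$period, ur$location))
    grp_period <- vapply(grp, function(i) ur$period[i[1]], character(1))
    pmat <- with_seed_(derive_seed(seed, paste0("anova-", uid)), {
      t(vapply(seq_len(n_subsample), function(i) {
        idx <- unlist(lapply(grp, function(g) {
          g[sample.int(length(g), n_min)]
        }), use.names = FALSE)
        keep_period <- rep(grp_period, each = n_min)
        vapply(periods, function(p) {
          rows <- idx[keep_period == p]
          ow_p(ur$rate[rows], ur$location[rows])
        }, numeric(1))
      }, numeric(length(periods))))
    })
    if (length(periods) == 1) pmat <- matrix(pmat, ncol = 1)
    med <- apply(pmat, 2, median)

    tibble(unit_id = uid, period = periods, n_per_location = n_min,
           anova_p = unname(med),
           selective = ifelse(is.na(med), NA, med < alpha),
           skipped = is.na(med)) |>
      left_join(prefs, by = "period") |>
      mutate(location_means = purrr::map(period, function(p) {
        means |> filter(period == p) |> select(location, mean_rate)
      }))
  })
}

#' Tuning census for a session
#'
#' Convenience wrapper: computes epoch rates for all units and runs
#' [anova_selectivity()].
#'
#' @param session A `session_recording`.
#' @param epoch Task epoch.
#' @inheritParams anova_selectivity
#' @return See [anova_selectivity()].
#' @export
tuning_census <- function(session, epoch = "delay", alpha = 0.05,
                          n_subsample = 50, seed = 1) {
  session_epoch_rates(session, epoch) |>
    select(unit_id, period, location, rate) |>
    anova_selectivity(alpha = alpha, n_subsample = n_subsample, seed = seed)
}

#' Ranked target-selectivity slope
#'
#' Each unit's nine location mean rates are ranked from preferred (rank 1)
#' to least preferred (rank 9) within each period, optionally normalized
#' by the unit's maximum mean rate, averaged across units, and a least
#' squares line is fitted to the session-average ranked curve. A more
#' negative slope indicates sharper tuning; flattened tuning pulls the
#' slope toward zero.
#'
#' @param rates Long tibble `unit_id`, `period`, `location`, `rate`.
#' @param normalize Divide each unit's mean rates by its maximum across
#'   periods before averaging.
#' @return Tibble `period`, `slope`, `intercept`, `r_squared`, `n_units`
#'   of class `ranked_slope`, with the session-average ranked curves in
#'   `attr(, "curve")`.
#' @export
ranked_slope <- function(rates, normalize = TRUE) {
  means <- rates |>
    group_by(unit_id, period, location) |>
    summarise(mean_rate = mean(rate), .groups = "drop")
  n_loc <- means |> count(unit_id, period)
  if (any(n_loc$n != 9)) {
    abort("Every unit x period needs mean rates for all 9 locations.",
          class = "wmdecode_input_error")
  }
  if (normalize) {
    means <- means |>
      group_by(unit_id) |>
      mutate(mean_rate = if (max(mean_rate) > 0) {
        mean_rate / max(mean_rate)
      } else {
        mean_rate
      }) |>
      ungroup()
  }
  ranked <- means |>
    group_by(unit_id, period) |>
    arrange(desc(mean_rate), location, .by_group = TRUE) |>
    mutate(rank_ = dplyr::row_number()) |>
    ungroup()
  curve <- ranked |>
    group_by(period, rank_) |>
    summarise(mean_rate = mean(mean_rate), n_units = n(), .groups = "drop")
  out <- curve |>
    group_by(period) |>
    summarise(
      {
        fit <- lm(mean_rate ~ rank_)
        tibble(slope = coef(fit)[["rank_"]],
               intercept = coef(fit)[["(Intercept)"]],
               r_squared = suppressWarnings(summary(fit)$r.squared))
      },
      n_units = n_units[1],
      .groups = "drop"
    )
  attr(out, "curve") <- curve
  class(out) <- c("ranked_slope", class(out))
  out
}

#' Spike density function
#'
#' Convolves a spike train with a Gaussian kernel (default SD 150 ms),
#' returning an instantaneous rate in Hz. The kernel is not renormalized
#' at window edges, so mass within the window is conserved only away from
#' the edges by at least a few kernel SDs.
#'
#' @param spike_times Numeric vector of spike times (ms).
#' @param from,to Evaluation window (ms).
#' @param sd_ms Kernel standard deviation (ms).
#' @param step_ms Evaluation step (ms).
#' @return Tibble `time`, `rate` (Hz) of class `sdf`.
#' @export
sdf <- function(spike_times, from, to, sd_ms = 150, step_ms = 10) {
  times <- seq(from, to, by = step_ms)
  rate <- numeric(length(times))
  if (length(spike_times) > 0) {
    # only spikes within 5 SD of the window contribute
    sp <- spike_times[spike_times > from - 5 * sd_ms &
                        spike_times < to + 5 * sd_ms]
    for (s in sp) {
      rate <- rate + dnorm(times - s, 0, sd_ms)
    }
    rate <- rate * 1000  # per-ms density -> Hz
  }
  structure(tibble(time = times, rate = rate), class = c("sdf", "tbl_df",
                                                         "tbl", "data.frame"))
}

#' Second-order polynomial surface over the target grid
#'
#' Fits `f(x, y) = p00 + p10 x + p01 y + p20 x^2 + p02 y^2 + p11 xy` by
#' least squares to the nine per-location mean rates; used for
#' visualization of spatial tuning, not for inference.
#'
#' @param location_rates Tibble with columns `x`, `y`, `rate` (typically
#'   the nine location means, rates normalized by the pre-period maximum).
#' @return Object of class `plane_fit` wrapping the `lm` fit.
#' @export
plane_fit <- function(location_rates) {
  stopifnot(all(c("x", "y", "rate") %in% names(location_rates)))
  if (nrow(location_rates) < 6) {
    abort("Need at least 6 (x, y, rate) points for 6 coefficients.",
          class = "wmdecode_input_error")
  }
  fit <- lm(rate ~ x + y + I(x^2) + I(y^2) + I(x * y),
            data = location_rates)
  if (fit$rank < 6) {
    abort("Design is rank-deficient: degenerate target coordinates.",
          class = "wmdecode_input_error")
  }
  structure(list(model = fit,
                 coefficients = setNames(
                   coef(fit),
                   c("p00", "p10", "p01", "p20", "p02", "p11"))),
            class = "plane_fit")
}

#' @export
print.plane_fit <- function(x, ...) {
  cat("<plane_fit> f(x,y) = p00 + p10 x + p01 y + p20 x^2 + p02 y^2 + p11 xy\n")
  print(round(x$coefficients, 6))
  invisible(x)
}

#' @rdname plane_fit
#' @param x A `plane_fit`.
#' @param ... Unused.
#' @export
tidy.plane_fit <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients))
}

#' @rdname plane_fit
#' @export
glance.plane_fit <- function(x, ...) {
  s <- summary(x$model)
  tibble(r.squared = s$r.squared, sigma = s$sigma,
         df.residual = x$model$df.residual)
}

#' Cell-type firing-rate contrast at preferred / least-preferred locations
#'
#' For delay-tuned units of each waveform class, compares per-unit mean
#' delay rates between the pre and early post-injection periods at the
#' location preferred (or least preferred) in the pre period, using
#' one-tailed Wilcoxon rank-sum tests. The tails encode the directional
#' hypotheses: firing at preferred locations decreases
#' (`alternative = "greater"` for pre vs early-post) and firing at
#' least-preferred locations increases (`alternative = "less"`).
#'
#' @param rates Long tibble `unit_id`, `period`, `location`, `rate`
#'   (delay-epoch per-trial rates).
#' @param classification Tibble `unit_id`, `class` (`"NS"`/`"BS"`), e.g.
#'   from [classify_waveforms()].
#' @param tuning Optional result of [anova_selectivity()]; when given,
#'   only units selective in the pre period at `alpha` are included.
#' @param alpha Inclusion threshold on the pre-period median ANOVA p.
#' @return Tibble with one row per class x location type: unit counts,
#'   period means and the one-tailed rank-sum p-value.
#' @export
preferred_rate_contrast <- function(rates, classification, tuning = NULL,
                                    alpha = 0.1) {
  keep <- classification |> filter(.data$class %in% c("NS", "BS"))
  if (!is.null(tuning)) {
    incl <- tuning |>
      filter(period == "pre", !is.na(anova_p), anova_p < alpha) |>
      pull(unit_id)
    keep <- keep |> filter(unit_id %in% incl)
  }
  pre_means <- rates |>
    filter(period == "pre") |>
    group_by(unit_id, location) |>
    summarise(mean_rate = mean(rate), .groups = "drop")
  pref <- pre_means |>
    group_by(unit_id) |>
    summarise(
      preferred = location[which.max(mean_rate)],
      least_preferred = location[which.min(mean_rate)],
      .groups = "drop"
    )

  purrr::map_dfr(c("NS", "BS"), function(cl) {
    ids <- keep$unit_id[keep$class == cl]
    purrr::map_dfr(c("preferred", "least_preferred"), function(lt) {
      sel <- pref |> filter(unit_id %in% ids)
      loc_of <- setNames(sel[[lt]], sel$unit_id)
      per_unit <- rates |>
        filter(unit_id %in% sel$unit_id,
               period %in% c("pre", "early_post")) |>
        filter(location == loc_of[as.character(unit_id)]) |>
        group_by(unit_id, period) |>
        summarise(mean_rate = mean(rate), .groups = "drop") |>
        tidyr::pivot_wider(names_from = period, values_from = mean_rate)
      if (nrow(per_unit) < 2 ||
          !all(c("pre", "early_post") %in% names(per_unit))) {
        return(tibble(class = cl, location_type = lt, n_units = nrow(per_unit),
                      mean_pre = NA_real_, mean_early = NA_real_,
                      p_value = NA_real_, alternative = NA_character_))
      }
      alt <- if (lt == "preferred") "greater" else "less"
      wt <- suppressWarnings(
        wilcox.test(per_unit$pre, per_unit$early_post, alternative = alt)
      )
      tibble(class = cl, location_type = lt, n_units = nrow(per_unit),
             mean_pre = mean(per_unit$pre),
             mean_early = mean(per_unit$early_post),
             p_value = wt$p.value, alternative = alt)
    })
  })
}
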