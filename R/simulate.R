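# Synthetic session generator: emulates the statistical structure the
# analyses assume (9-location tuning in two waveform classes, correlated
# trial-to-trial variability, epoch structure, behavior, gaze, waveforms)
# with ground truth emitted alongside.

#' Generator configuration
#'
#' Defaults describe a drug-injection working-memory session: spatially
#' tuned units in two waveform classes, a behavioral performance drop and
#' wider navigation trajectories in the early post-injection period, and a
#' cell-type-specific rate perturbation (narrow-spiking units lose firing
#' at their preferred locations, broad-spiking units gain firing at their
#' least-preferred locations) that partially relaxes in the late
#' post-injection period. Saline and perception conditions default to no
#' perturbation and period-independent behavior.
#'
#' @param condition Session condition; drives the condition-specific
#'   defaults below.
#' @param n_ns,n_bs Number of narrow- and broad-spiking units.
#' @param multiunit_fraction Fraction of units flagged as multiunits.
#' @param trials_per_location Trials per target location per injection
#'   period.
#' @param peak_rate,baseline_rate Tuning-curve peak and floor (Hz).
#' @param bandwidth Spatial SD of the Gaussian tuning bump (arena units).
#' @param amp_jitter_sd Log-normal SD of per-unit tuning amplitude.
#' @param fano Conditional Fano factor of spike counts (1 = Poisson).
#' @param rho Strength of the shared per-trial gain latent; controls
#'   pairwise spike-count correlations.
#' @param g_ns Multiplier on the tuning amplitude of NS units in the early
#'   post-injection period (< 1 suppresses preferred-location firing).
#' @param delta_bs Additive rate (Hz) at the least-preferred locations of
#'   BS units in the early post-injection period.
#' @param late_recovery Fraction of the early-post effect removed in the
#'   late post-injection period (0.5 = halfway back to baseline).
#' @param p_correct Named per-period probability of a correct trial.
#' @param dispersion Named per-period lateral trajectory dispersion (arena
#'   units).
#' @param nav_time_mean Named per-period mean navigation time (s).
#' @param nav_time_sd SD of navigation time (s).
#' @param width_ns_mean,width_bs_mean,width_sd Waveform trough-to-peak
#'   width mixture (microseconds); means must be ordered NS < BS.
#' @param fixation_rate Fixations per second during cue/delay.
#' @param on_target_bias Probability that a fixation lands on the target's
#'   screen location rather than uniformly on screen.
#' @param fix_dur_mean Mean fixation duration (ms).
#' @param iti_ms Inter-trial interval (ms).
#' @param start_line_y Arena y coordinate of the line separating the start
#'   enclave from the arena body.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(condition = "ketamine_wm",
                             n_ns = 8, n_bs = 24,
                             multiunit_fraction = 0.25,
                             trials_per_location = 12,
                             peak_rate = 12, baseline_rate = 2,
                             bandwidth = 290,
                             amp_jitter_sd = 0.25,
                             fano = 1.4, rho = 0.15,
                             g_ns = NULL, delta_bs = NULL,
                             late_recovery = 0.5,
                             p_correct = NULL,
                             dispersion = NULL,
                             nav_time_mean = NULL,
                             nav_time_sd = 0.4,
                             width_ns_mean = 220, width_bs_mean = 420,
                             width_sd = 40,
                             fixation_rate = 2, on_target_bias = 0.3,
                             fix_dur_mean = 250,
                             iti_ms = 1500,
                             start_line_y = -500) {
  condition <- match.arg(condition, CONDITIONS)
  drug <- condition == "ketamine_wm"
  g_ns <- g_ns %||% if (drug) 0.5 else 1
  delta_bs <- delta_bs %||% if (drug) 4 else 0
  p_correct <- p_correct %||% if (drug) {
    c(pre = 0.9, early_post = 0.65, late_post = 0.85)
  } else {
    c(pre = 0.9, early_post = 0.9, late_post = 0.9)
  }
  dispersion <- dispersion %||% if (drug) {
    c(pre = 30, early_post = 80, late_post = 45)
  } else {
    c(pre = 30, early_post = 30, late_post = 30)
  }
  nav_time_mean <- nav_time_mean %||% if (drug) {
    c(pre = 3.0, early_post = 4.0, late_post = 3.3)
  } else {
    c(pre = 3.0, early_post = 3.0, late_post = 3.0)
  }

  cfg <- list(
    condition = condition, n_ns = n_ns, n_bs = n_bs,
    multiunit_fraction = multiunit_fraction,
    trials_per_location = trials_per_location,
    peak_rate = peak_rate, baseline_rate = baseline_rate,
    bandwidth = bandwidth, amp_jitter_sd = amp_jitter_sd,
    fano = fano, rho = rho,
    g_ns = g_ns, delta_bs = delta_bs, late_recovery = late_recovery,
    p_correct = p_correct[PERIOD_LEVELS],
    dispersion = dispersion[PERIOD_LEVELS],
    nav_time_mean = nav_time_mean[PERIOD_LEVELS],
    nav_time_sd = nav_time_sd,
    width_ns_mean = width_ns_mean, width_bs_mean = width_bs_mean,
    width_sd = width_sd,
    fixation_rate = fixation_rate, on_target_bias = on_target_bias,
    fix_dur_mean = fix_dur_mean, iti_ms = iti_ms,
    start_line_y = start_line_y
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  if (cfg$baseline_rate < 0 || cfg$peak_rate < cfg$baseline_rate) {
    abort("Rates must satisfy 0 <= baseline_rate <= peak_rate.",
          class = "wmdecode_config_error")
  }
  if (cfg$g_ns < 0 || cfg$g_ns > 1) {
    abort("g_ns must lie in [0, 1].", class = "wmdecode_config_error")
  }
  if (cfg$delta_bs < 0) {
    abort("delta_bs must be >= 0.", class = "wmdecode_config_error")
  }
  if (any(is.na(cfg$p_correct)) || any(cfg$p_correct <= 0) ||
      any(cfg$p_correct > 1)) {
    abort("p_correct must lie in (0, 1] for every period.",
          class = "wmdecode_config_error")
  }
  if (cfg$width_ns_mean >= cfg$width_bs_mean) {
    abort("Width mixture means must be ordered: NS mean < BS mean.",
          class = "wmdecode_config_error")
  }
  if (cfg$rho < 0 || cfg$fano < 1) {
    abort("Require rho >= 0 and fano >= 1.",
          class = "wmdecode_config_error")
  }
  invisible(cfg)
}

# Gaussian bump over the grid, normalized to 1 at the preferred location.
tuning_kernel <- function(pref_location, bandwidth, grid = target_grid()) {
  p <- grid[grid$location == pref_location, ]
  d2 <- (grid$x - p$x)^2 + (grid$y - p$y)^2
  exp(-d2 / (2 * bandwidth^2))
}

# Expected tuned rate (Hz) per location for one unit in one period.
period_rates <- function(base, amp, kern, class_label, period, cfg) {
  effect <- switch(period, pre = 0, early_post = 1,
                   late_post = 1 - cfg$late_recovery)
  if (effect == 0 || cfg$condition != "ketamine_wm") {
    return(base + amp * kern)
  }
  if (class_label == "NS") {
    g <- 1 - (1 - cfg$g_ns) * effect
    base + g * amp * kern
  } else {
    base + amp * kern + cfg$delta_bs * effect * (1 - kern)
  }
}

draw_counts <- function(mu, fano) {
  n <- length(mu)
  out <- integer(n)
  pos <- mu > 0
  if (fano > 1) {
    out[pos] <- rnbinom(sum(pos), mu = mu[pos], size = mu[pos] / (fano - 1))
  } else {
    out[pos] <- rpois(sum(pos), mu[pos])
  }
  out
}

# Biphasic waveform template with a given trough-to-peak width (us).
waveform_template <- function(width_us, dt_us = 1e6 / 30000, n = 48,
                              amp = 50) {
  t <- (seq_len(n) - 1) * dt_us
  t0 <- 400
  v <- -amp * exp(-(t - t0)^2 / (2 * 80^2)) +
    0.45 * amp * exp(-(t - t0 - width_us)^2 / (2 * 150^2))
  v
}

#' Generate a synthetic session with ground truth
#'
#' Spike counts follow a doubly stochastic model: the expected epoch rate
#' is the unit's tuning curve at the trial's target, multiplied by a
#' per-trial shared gain `max(0.05, 1 + rho * z)`, `z ~ N(0,1)`; counts are
#' conditionally Poisson (or negative binomial when `fano > 1`) and spike
#' times are placed uniformly within epochs. Trajectories are noisy
#' start-to-target paths whose lateral dispersion follows the period's
#' dispersion parameter; fixations carry a configurable on-target bias;
#' mean waveforms are biphasic templates with the unit's drawn
#' trough-to-peak width.
#'
#' @param cfg A [generator_config()].
#' @param seed Integer seed.
#' @param session_id Session id string.
#' @return A list with elements `session` (a `session_recording`) and
#'   `truth` (tibbles `units`, `tuning`, `trial_gain`, `separation`).
#'   The ground truth is never consumed by analysis stages.
#' @export
generate_session <- function(cfg = generator_config(), seed = 1,
                             session_id = sprintf("synth-%d", seed)) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed_(seed, generate_session_impl(cfg, session_id))
}

generate_session_impl <- function(cfg, session_id) {
  grid <- target_grid()
  half_hour <- 30 * 60 * 1000

  ## --- units -----------------------------------------------------------
  n_units <- cfg$n_ns + cfg$n_bs
  classes <- c(rep("NS", cfg$n_ns), rep("BS", cfg$n_bs))
  widths <- ifelse(
    classes == "NS",
    rnorm(n_units, cfg$width_ns_mean, cfg$width_sd),
    rnorm(n_units, cfg$width_bs_mean, cfg$width_sd)
  )
  widths <- pmin(pmax(widths, 120), 660)
  is_single <- runif(n_units) > cfg$multiunit_fraction
  pref <- sample(1:9, n_units, replace = TRUE)
  amp <- (cfg$peak_rate - cfg$baseline_rate) *
    exp(rnorm(n_units, 0, cfg$amp_jitter_sd))
  units <- tibble(
    unit_id = seq_len(n_units),
    is_single = is_single,
    array_id = rep(c("A1", "A2"), length.out = n_units),
    sample_interval_us = 1e6 / 30000,
    mean_waveform = purrr::map(widths, function(w) {
      waveform_template(w) + rnorm(48, 0, 0.3)
    })
  )

  # true tuning per unit x period x location (delay/cue tuned rate, Hz)
  truth_tuning <- purrr::map_dfr(seq_len(n_units), function(u) {
    kern <- tuning_kernel(pref[u], cfg$bandwidth, grid)
    purrr::map_dfr(PERIOD_LEVELS, function(p) {
      tibble(unit_id = u, period = p, location = grid$location,
             rate = period_rates(cfg$baseline_rate, amp[u], kern,
                                 classes[u], p, cfg))
    })
  })
  if (any(truth_tuning$rate < 0)) {
    abort("Perturbation parameters drive a negative firing rate.",
          class = "wmdecode_config_error")
  }

  ## --- trials ----------------------------------------------------------
  tpl <- cfg$trials_per_location
  make_block <- function(block_period) {
    loc <- sample(rep(1:9, tpl))
    nav <- round(pmin(pmax(rnorm(length(loc), cfg$nav_time_mean[[block_period]],
                                 cfg$nav_time_sd), 0.8), 9.5) * 1000)
    correct <- runif(length(loc)) < cfg$p_correct[[block_period]]
    tibble(
      target_location = loc, period = block_period,
      outcome = ifelse(correct, "correct", "incorrect"),
      nav_ms = unname(nav)
    )
  }
  blocks <- purrr::map(PERIOD_LEVELS, make_block)
  span <- function(b) sum(3000 + 2000 + b$nav_ms + cfg$iti_ms)
  t0 <- 60000
  pre_end <- t0 + span(blocks[[1]])
  injection_time <- pre_end + 30000
  early_start <- injection_time + 60000
  early_end <- early_start + span(blocks[[2]])
  if (early_end > injection_time + half_hour) {
    abort("Early post-injection block does not fit within 30 min; reduce trials_per_location or iti_ms.",
          class = "wmdecode_config_error")
  }
  late_start <- injection_time + half_hour + 10000
  late_end <- late_start + span(blocks[[3]])
  if (late_end > injection_time + 2 * half_hour) {
    abort("Late post-injection block does not fit within 30-60 min.",
          class = "wmdecode_config_error")
  }

  starts <- c(t0, early_start, late_start)
  trials <- purrr::map2_dfr(blocks, starts, function(b, s) {
    ends <- s + cumsum(3000 + 2000 + b$nav_ms + cfg$iti_ms)
    cue_on <- c(s, head(ends, -1))
    b |> mutate(cue_on = cue_on, delay_on = cue_on + 3000,
                response_on = delay_on + 2000,
                trial_end = response_on + nav_ms)
  })
  trials <- trials |>
    mutate(
      trial_id = dplyr::row_number(),
      x = grid$x[target_location],
      y = grid$y[target_location],
      target_column = grid$target_column[target_location],
      target_side = grid$target_side[target_location],
      response_time = ifelse(outcome == "correct", nav_ms / 1000, NA_real_)
    ) |>
    select(trial_id, target_location, x, y, target_column, target_side,
           outcome, cue_on, delay_on, response_on, trial_end, period,
           response_time, nav_ms)

  ## --- spikes ----------------------------------------------------------
  n_trials <- nrow(trials)
  gain <- pmax(0.05, 1 + cfg$rho * rnorm(n_trials))
  rate_lookup <- truth_tuning |>
    tidyr::pivot_wider(names_from = unit_id, values_from = rate) |>
    arrange(period, location)
  rate_mat <- as.matrix(rate_lookup[, as.character(seq_len(n_units))])
  row_key <- paste(rate_lookup$period, rate_lookup$location)
  trial_rows <- match(paste(trials$period, trials$target_location), row_key)

  seg_on <- cbind(trials$cue_on, trials$delay_on, trials$response_on,
                  trials$response_on + 2000)
  seg_off <- cbind(trials$delay_on, trials$response_on,
                   pmin(trials$response_on + 2000, trials$trial_end),
                   trials$trial_end)
  tuned_seg <- c(TRUE, TRUE, TRUE, FALSE)

  spike_parts <- vector("list", 4L)
  for (s in 1:4) {
    dur_s <- pmax(seg_off[, s] - seg_on[, s], 0) / 1000
    r <- if (tuned_seg[s]) rate_mat[trial_rows, , drop = FALSE]
         else matrix(cfg$baseline_rate, n_trials, n_units)
    mu <- r * dur_s * gain  # recycles dur and gain down columns
    counts <- draw_counts(as.vector(mu), cfg$fano)
    total <- sum(counts)
    if (total == 0) next
    unit_of <- rep(rep(seq_len(n_units), each = n_trials), counts)
    on_of <- rep(rep(seg_on[, s], n_units), counts)
    dur_of <- rep(rep(seg_off[, s] - seg_on[, s], n_units), counts)
    spike_parts[[s]] <- tibble(unit_id = unit_of,
                               time = on_of + runif(total) * dur_of)
  }
  spikes <- bind_rows(spike_parts) |> arrange(unit_id, time)

  ## --- trajectories ----------------------------------------------------
  start_xy <- c(0, -750)
  trajectories <- purrr::map_dfr(seq_len(n_trials), function(i) {
    tr <- trials[i, ]
    dest <- if (tr$outcome == "correct") {
      c(tr$x, tr$y)
    } else {
      wrong <- sample(setdiff(1:9, tr$target_location), 1)
      c(grid$x[wrong], grid$y[wrong])
    }
    times <- seq(tr$response_on, tr$trial_end, by = 50)
    sfrac <- (times - tr$response_on) / (tr$trial_end - tr$response_on)
    dvec <- dest - start_xy
    len <- sqrt(sum(dvec^2))
    perp <- c(-dvec[2], dvec[1]) / len
    disp <- cfg$dispersion[[tr$period]]
    b <- rnorm(2)
    off <- disp * (b[1] * sin(pi * sfrac) + 0.4 * b[2] * sin(2 * pi * sfrac)) +
      rnorm(length(sfrac), 0, 3)
    tibble(trial_id = tr$trial_id, time = times,
           x = start_xy[1] + sfrac * dvec[1] + off * perp[1],
           y = start_xy[2] + sfrac * dvec[2] + off * perp[2])
  })

  ## --- gaze ------------------------------------------------------------
  screen <- screen_geometry()
  tpos <- target_screen_xy(screen)
  gaze_parts <- purrr::map(seq_len(n_trials), function(i) {
    tr <- trials[i, ]
    epochs <- tibble(epoch = c("cue", "delay"),
                     on = c(tr$cue_on, tr$delay_on),
                     off = c(tr$delay_on, tr$response_on))
    fx <- purrr::map_dfr(1:2, function(e) {
      dur_s <- (epochs$off[e] - epochs$on[e]) / 1000
      nf <- rpois(1, cfg$fixation_rate * dur_s)
      if (nf == 0) return(NULL)
      onset <- sort(runif(nf, epochs$on[e], epochs$off[e]))
      lim <- c(onset[-1], epochs$off[e])
      dur <- pmin(7 + rexp(nf, 1 / cfg$fix_dur_mean), lim - onset)
      keep <- dur > 6
      if (!any(keep)) return(NULL)
      on_t <- runif(nf) < cfg$on_target_bias
      px <- ifelse(on_t, tpos$sx[tr$target_location] + rnorm(nf, 0, 25),
                   runif(nf, 0, screen$width_px))
      py <- ifelse(on_t, tpos$sy[tr$target_location] + rnorm(nf, 0, 25),
                   runif(nf, 0, screen$height_px))
      tibble(trial_id = tr$trial_id, epoch = epochs$epoch[e],
             x = pmin(pmax(px, 0), screen$width_px),
             y = pmin(pmax(py, 0), screen$height_px),
             start = onset, end = onset + dur)[keep, ]
    })
    if (nrow(fx) < 2) return(list(fx = fx, sc = empty_saccades()))
    sc <- tibble(trial_id = tr$trial_id,
                 start_x = head(fx$x, -1), start_y = head(fx$y, -1),
                 end_x = fx$x[-1], end_y = fx$y[-1],
                 start = head(fx$end, -1), end = fx$start[-1]) |>
      filter(end > start)
    list(fx = fx, sc = sc)
  })
  fixations <- bind_rows(purrr::map(gaze_parts, "fx"))
  saccades <- bind_rows(purrr::map(gaze_parts, "sc"))

  ## --- assemble --------------------------------------------------------
  session <- session_recording(
    session_id = session_id, condition = cfg$condition,
    injection_time = injection_time,
    trials = trials |> select(-nav_ms),
    units = units, spikes = spikes,
    fixations = fixations, saccades = saccades,
    trajectories = trajectories
  )

  sep <- truth_tuning |>
    left_join(grid |> select(location, target_column), by = "location") |>
    filter(target_column != "center") |>
    group_by(period, unit_id, target_column) |>
    summarise(rate = mean(rate), .groups = "drop") |>
    tidyr::pivot_wider(names_from = target_column, values_from = rate) |>
    group_by(period) |>
    summarise(ps_true = sqrt(sum((left - right)^2)), .groups = "drop")

  truth <- list(
    units = tibble(unit_id = seq_len(n_units), class = classes,
                   width = widths, preferred_location = pref,
                   amplitude = amp),
    tuning = truth_tuning,
    trial_gain = tibble(trial_id = trials$trial_id, gain = gain),
    separation = sep
  )
  list(session = session, truth = truth)
}

#' Generate untuned (null) units for calibration
#'
#' Produces per-trial epoch rates for units whose expected rate is
#' identical across the nine locations; used to calibrate the type-I error
#' of the spatial-selectivity test. Counts are Poisson over a delay-length
#' window.
#'
#' @param n Number of units.
#' @param rate Common expected rate (Hz); must be > 0 (a zero rate yields
#'   degenerate all-zero units, which the selectivity test skips).
#' @param trials_per_location Trials per location.
#' @param duration_ms Epoch window length.
#' @param seed Integer seed.
#' @return Long tibble `unit_id`, `period` (`"pre"`), `location`, `rate`
#'   with one row per trial.
#' @export
generate_null_units <- function(n, rate = 5, trials_per_location = 20,
                                duration_ms = 2000, seed = 1) {
  if (n == 0) {
    return(tibble(unit_id = integer(), period = character(),
                  location = integer(), rate = numeric()))
  }
  stopifnot(rate >= 0)
  dur_s <- duration_ms / 1000
  with_seed_(seed, {
    out <- tidyr::expand_grid(unit_id = seq_len(n), location = 1:9,
                              rep = seq_len(trials_per_location))
    out |>
      mutate(period = "pre",
             rate = rpois(nrow(out), rate * dur_s) / dur_s) |>
      select(unit_id, period, location, rate)
  })
}
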