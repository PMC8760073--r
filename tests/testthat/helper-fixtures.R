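# Shared fixtures, generated once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# Small drug-on session: 16 units, 9 x 6 x 3 = 162 trials.
fixture_session <- function() {
  cached("drug_small", generate_session(
    generator_config(n_ns = 4, n_bs = 12, trials_per_location = 6),
    seed = 101
  ))
}

# Saline session without perturbation, same size.
fixture_saline <- function() {
  cached("saline_small", generate_session(
    generator_config(condition = "saline_wm", n_ns = 4, n_bs = 12,
                     trials_per_location = 6),
    seed = 102
  ))
}

fixture_delay_rates <- function() {
  cached("drug_small_rates", {
    s <- fixture_session()$session
    epoch_rates(s$spikes, s$trials, "delay") |>
      dplyr::left_join(
        s$trials |>
          dplyr::select(trial_id, location = target_location,
                        target_column, target_side, period),
        by = "trial_id")
  })
}

# Minimal hand-built trials table (no generator) for behavior tests.
manual_trials <- function(outcomes, period = "pre", rt = NULL) {
  n <- length(outcomes)
  g <- target_grid()
  loc <- rep_len(1:9, n)
  tibble::tibble(
    trial_id = seq_len(n), target_location = loc,
    x = g$x[loc], y = g$y[loc],
    target_column = g$target_column[loc], target_side = g$target_side[loc],
    outcome = outcomes,
    cue_on = (seq_len(n) - 1) * 10000, delay_on = (seq_len(n) - 1) * 10000 + 3000,
    response_on = (seq_len(n) - 1) * 10000 + 5000,
    trial_end = (seq_len(n) - 1) * 10000 + 9000,
    period = period,
    response_time = if (is.null(rt)) {
      ifelse(outcomes == "correct", 4, NA_real_)
    } else {
      rt
    }
  )
}

# One-way fixed-effects F-test computed from sums of squares; independent
# oracle for the ANOVA selectivity path.
manual_oneway_p <- function(rate, loc) {
  groups <- split(rate, loc)
  k <- length(groups)
  n <- length(rate)
  gm <- mean(rate)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  stats::pf(f, k - 1, n - k, lower.tail = FALSE)
}
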