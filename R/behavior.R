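# Behavioral performance, response times and trajectory-dispersion
# analyses.

#' Percent correct by injection period
#'
#' Percent of correct trials per period with an exact binomial test
#' against the chance level of guessing one of the nine targets
#' (`p0 = 1/9`, ~11%), one-sided (above chance).
#'
#' @param trials Trials table.
#' @param p_chance Chance probability.
#' @return Tibble `period`, `n_trials`, `n_correct`, `percent_correct`,
#'   `p_binomial`. Periods with no trials are omitted with a warning.
#' @export
percent_correct <- function(trials, p_chance = 1 / 9) {
  out <- trials |>
    group_by(period) |>
    summarise(n_trials = n(), n_correct = sum(outcome == "correct"),
              .groups = "drop") |>
    mutate(
      percent_correct = 100 * n_correct / n_trials,
      p_binomial = purrr::map2_dbl(n_correct, n_trials, function(x, n) {
        binom.test(x, n, p = p_chance, alternative = "greater")$p.value
      })
    ) |>
    mutate(period = factor(period, levels = PERIOD_LEVELS)) |>
    arrange(period) |>
    mutate(period = as.character(period))
  empty <- setdiff(PERIOD_LEVELS, out$period)
  if (length(empty) > 0 && length(empty) < 3) {
    warn(sprintf("No trials in period(s): %s; omitted.",
                 paste(empty, collapse = ", ")))
  }
  out
}

#' Percent-correct time course in equal trial bins
#'
#' Splits each period's trials (in time order) into `n_bins` equally
#' sized bins and reports percent correct per bin.
#'
#' @param trials Trials table.
#' @param n_bins Bins per period.
#' @return Tibble `period`, `bin`, `n_trials`, `percent_correct`.
#' @export
percent_correct_timecourse <- function(trials, n_bins = 15) {
  trials |>
    arrange(cue_on) |>
    group_by(period) |>
    mutate(bin = ceiling(dplyr::row_number() / (n() / n_bins))) |>
    group_by(period, bin) |>
    summarise(n_trials = n(),
              percent_correct = 100 * mean(outcome == "correct"),
              .groups = "drop")
}

#' Response-time summary
#'
#' Mean and SEM of response time (navigation onset to trial end, seconds)
#' on correct trials, per period. For a single trial the SEM is reported
#' as 0 and flagged.
#'
#' @param trials Trials table.
#' @return Tibble `period`, `n`, `mean_rt`, `sem_rt`, `sem_degenerate`.
#' @export
response_times <- function(trials) {
  trials |>
    filter(outcome == "correct", !is.na(response_time)) |>
    group_by(period) |>
    summarise(
      n = n(),
      mean_rt = mean(response_time),
      sem_rt = ifelse(n() > 1, sd(response_time) / sqrt(n()), 0),
      sem_degenerate = n() == 1,
      .groups = "drop"
    )
}

# Densify a trajectory so consecutive samples are closer than max_step;
# cell entry then cannot be missed by coarse sampling.
densify_path <- function(x, y, max_step) {
  if (length(x) < 2) return(list(x = x, y = y))
  seg_len <- sqrt(diff(x)^2 + diff(y)^2)
  n_sub <- pmax(1L, ceiling(seg_len / max_step))
  xs <- list(); ys <- list()
  for (i in seq_along(seg_len)) {
    f <- seq(0, 1, length.out = n_sub[i] + 1)[-1]
    xs[[i]] <- x[i] + f * (x[i + 1] - x[i])
    ys[[i]] <- y[i] + f * (y[i + 1] - y[i])
  }
  list(x = c(x[1], unlist(xs)), y = c(y[1], unlist(ys)))
}

#' Trajectory grid occupancy
#'
#' Divides the arena into a 5 x 5 grid of equal cells tightly enclosing
#' the nine targets and scores, per trial, whether each cell was entered
#' (1) or not (0) during navigation; entry is scored on the path densified
#' between samples so sampling density cannot miss a crossing. Only
#' trials whose trajectory crosses the line separating the start enclave
#' from the arena are included. Per-trial indicators are then aggregated
#' into the percent of trials entering each cell for each of the nine
#' target conditions (25 x 9 = 225 values for a full session).
#'
#' @param trajectories Trajectory table (`trial_id`, `time`, `x`, `y`).
#' @param trials Trials table.
#' @param grid A [trajectory_grid()].
#' @param start_line_y Arena y coordinate of the start-enclave boundary.
#' @return List of class `trajectory_occupancy` with `per_trial` (long
#'   0/1 indicators), `percent` (condition x cell percentages) and the
#'   trial counts per condition.
#' @export
grid_occupancy <- function(trajectories, trials,
                           grid = trajectory_grid(),
                           start_line_y = -500) {
  crossed <- trajectories |>
    group_by(trial_id) |>
    summarise(crossed = any(y >= start_line_y), n_samples = n(),
              .groups = "drop")
  empty_ids <- setdiff(trials$trial_id, trajectories$trial_id)
  if (length(empty_ids) > 0) {
    warn(sprintf("%d trial(s) without trajectory samples excluded.",
                 length(empty_ids)))
  }
  keep_ids <- crossed$trial_id[crossed$crossed]

  max_step <- min(diff(grid$x_edges)[1], diff(grid$y_edges)[1]) / 50
  per_trial <- trajectories |>
    filter(trial_id %in% keep_ids) |>
    group_by(trial_id) |>
    group_modify(function(d, key) {
      p <- densify_path(d$x, d$y, max_step)
      cells <- grid_cell_index(p$x, p$y, grid$x_edges, grid$y_edges)
      cells <- unique(cells[!is.na(cells)])
      tibble(cell = seq_len(grid$n^2),
             entered = as.integer(seq_len(grid$n^2) %in% cells))
    }) |>
    ungroup()

  percent <- per_trial |>
    left_join(trials |> select(trial_id, target_location), by = "trial_id") |>
    group_by(target_location, cell) |>
    summarise(n_trials = n(), percent = 100 * mean(entered),
              .groups = "drop") |>
    mutate(cell_row = (cell - 1L) %/% grid$n + 1L,
           cell_col = (cell - 1L) %% grid$n + 1L) |>
    select(target_location, cell, cell_row, cell_col, n_trials, percent)

  structure(list(per_trial = per_trial, percent = percent, grid = grid),
            class = "trajectory_occupancy")
}

#' Two-way ANOVA of a session measure across period and condition
#'
#' Generic utility for cross-session comparisons of any per-session (or
#' per-session-per-period) measure with injection period and drug
#' condition as crossed factors, e.g. percent correct or fixation
#' proportions. The printed F and p values depend on the sessions
#' supplied; the utility only wraps the standard fixed-effects fit.
#'
#' @param data Data frame with one row per observation.
#' @param value Name of the response column (string).
#' @param period_col,condition_col Factor column names.
#' @return Tidy tibble of the ANOVA table (term, df, sumsq, statistic,
#'   p.value).
#' @export
period_condition_anova <- function(data, value, period_col = "period",
                                   condition_col = "condition") {
  stopifnot(all(c(value, period_col, condition_col) %in% names(data)))
  d <- data.frame(
    y = data[[value]],
    period = factor(data[[period_col]]),
    condition = factor(data[[condition_col]])
  )
  fit <- stats::aov(y ~ period * condition, data = d)
  tab <- summary(fit)[[1]]
  tibble(term = trimws(rownames(tab)), df = tab$Df, sumsq = tab$`Sum Sq`,
         statistic = tab$`F value`, p.value = tab$`Pr(>F)`)
}

#' Occupancy increase map between two periods
#'
#' Difference in per-cell, per-condition occupancy percentages between
#' two [grid_occupancy()] results, keeping increases only (negative
#' differences are zeroed), mirroring the between-period trajectory
#' spread analysis.
#'
#' @param occ_a,occ_b `trajectory_occupancy` results (a minus b).
#' @return Tibble `target_location`, `cell`, `cell_row`, `cell_col`,
#'   `increase` (percentage points, `>= 0`).
#' @export
occupancy_increase <- function(occ_a, occ_b) {
  a <- occ_a$percent |> select(target_location, cell, cell_row, cell_col,
                               pa = percent)
  b <- occ_b$percent |> select(target_location, cell, pb = percent)
  a |>
    inner_join(b, by = c("target_location", "cell")) |>
    mutate(increase = pmax(.data$pa - .data$pb, 0)) |>
    select(target_location, cell, cell_row, cell_col, increase)
}
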