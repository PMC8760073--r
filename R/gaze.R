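# Gaze-control analyses: on-target fixation proportions, decoding target
# location from fixation maps, decoding eye region from neural activity,
# and saccade reference-frame tuning.

#' Proportion of fixation time on the target
#'
#' On correct trials, sums fixation time falling within a rectangular
#' tolerance window around the target's screen projection (one cell of
#' the 16-cell screen grid) and divides by total fixation time in the
#' epoch.
#'
#' @param fixations Fixation table (`trial_id`, `epoch`, `x`, `y`,
#'   `start`, `end`).
#' @param trials Trials table.
#' @param epoch Task epoch (default delay).
#' @param screen A [screen_geometry()].
#' @param by_period Report per injection period rather than one pooled
#'   value.
#' @return Tibble `period` (or a single row), `on_target_ms`, `total_ms`,
#'   `proportion`, `undefined` (TRUE when no fixation time exists).
#' @export
fixation_on_target_proportion <- function(fixations, trials,
                                          epoch = "delay",
                                          screen = screen_geometry(),
                                          by_period = TRUE) {
  grid16 <- screen_grid(4, 4, screen)
  tpos <- target_screen_xy(screen)
  ep <- epoch
  fx <- fixations |>
    filter(.data$epoch == ep) |>
    inner_join(trials |>
                 filter(outcome == "correct") |>
                 select(trial_id, target_location, period),
               by = "trial_id") |>
    left_join(tpos, by = c("target_location" = "location")) |>
    mutate(duration = end - start,
           on_target = abs(x - sx) <= grid16$cell_w / 2 &
             abs(y - sy) <= grid16$cell_h / 2)
  grouping <- if (by_period) "period" else character(0)
  out <- fx |>
    group_by(across(all_of(grouping))) |>
    summarise(on_target_ms = sum(duration[on_target]),
              total_ms = sum(duration), .groups = "drop") |>
    mutate(proportion = ifelse(total_ms > 0, on_target_ms / total_ms,
                               NA_real_),
           undefined = total_ms == 0)
  if (any(out$undefined)) {
    warn("Zero fixation time in at least one group; proportion undefined.")
  }
  out
}

# Per-trial 16-cell fixation-count features for one epoch.
fixation_count_features <- function(fixations, trials, epoch,
                                    screen = screen_geometry()) {
  grid16 <- screen_grid(4, 4, screen)
  ep <- epoch
  counts <- fixations |>
    filter(.data$epoch == ep, trial_id %in% trials$trial_id) |>
    mutate(cell = grid_cell_index(x, y, grid16$x_edges, grid16$y_edges)) |>
    filter(!is.na(cell)) |>
    count(trial_id, cell)
  full <- tidyr::expand_grid(trial_id = trials$trial_id,
                             cell = seq_len(16)) |>
    left_join(counts, by = c("trial_id", "cell")) |>
    mutate(n = dplyr::coalesce(n, 0L)) |>
    tidyr::pivot_wider(names_from = cell, values_from = n,
                       names_prefix = "cell_") |>
    arrange(trial_id)
  m <- as.matrix(full[, -1])
  rownames(m) <- full$trial_id
  m
}

#' Decode target location from fixation-count maps
#'
#' Divides the screen into 16 equal cells, counts fixations per cell per
#' trial and decodes the target location from the 16-dimensional count
#' vector with the cross-validated linear SVM ([decode_cv()]). Serves as
#' the eye-position control for the neural decoder with the same number
#' of features.
#'
#' @param fixations Fixation table.
#' @param trials Trials table.
#' @param epoch Task epoch.
#' @param scheme Label scheme, see [decoding_labels()].
#' @inheritParams decode_cv
#' @param screen A [screen_geometry()].
#' @return A `decoding_result`.
#' @export
decode_target_from_fixations <- function(fixations, trials,
                                         epoch = "delay",
                                         scheme = "column", k_folds = 5,
                                         n_balance = 20, cost = NULL,
                                         seed = 1,
                                         screen = screen_geometry()) {
  feats <- fixation_count_features(fixations, trials, epoch, screen)
  labels <- decoding_labels(trials, scheme)
  decode_cv(feats, labels, k_folds = k_folds, n_balance = n_balance,
            cost = cost, seed = seed)
}

#' Default screen regions for eye-position decoding
#'
#' Four rectangular regions (one 16-cell grid cell each) around the
#' screen projections of the four corner targets, whose screen positions
#' are well separated.
#'
#' @param screen A [screen_geometry()].
#' @param locations Target locations to surround.
#' @return Tibble `region`, `x_min`, `x_max`, `y_min`, `y_max`.
#' @export
default_eye_regions <- function(screen = screen_geometry(),
                                locations = c(1, 3, 7, 9)) {
  grid16 <- screen_grid(4, 4, screen)
  tpos <- target_screen_xy(screen) |> filter(location %in% locations)
  tibble(region = paste0("R", tpos$location),
         x_min = tpos$sx - grid16$cell_w / 2,
         x_max = tpos$sx + grid16$cell_w / 2,
         y_min = tpos$sy - grid16$cell_h / 2,
         y_max = tpos$sy + grid16$cell_h / 2)
}

#' Decode eye region from neural activity during fixations
#'
#' Labels each fixation (cue or delay epoch, duration > `min_dur_ms`)
#' with the screen region it falls in, computes each unit's firing rate
#' within the fixation window, and decodes the region from the z-scored
#' rates with a linear SVM and 4-fold cross-validation (chance 25%).
#' Sessions missing fixations in one or more regions are rejected.
#'
#' @param session A `session_recording`.
#' @param regions Region table, see [default_eye_regions()].
#' @param epochs Epochs whose fixations are used.
#' @param min_dur_ms Minimum fixation duration retained.
#' @param k_folds CV folds.
#' @param n_balance Balancing repeats.
#' @param cost Fixed SVM cost or `NULL` to tune.
#' @param seed Seed.
#' @return A `decoding_result`.
#' @export
decode_eye_region_from_neurons <- function(session,
                                           regions = default_eye_regions(),
                                           epochs = c("cue", "delay"),
                                           min_dur_ms = 6, k_folds = 4,
                                           n_balance = 20, cost = NULL,
                                           seed = 1) {
  fx <- session$fixations |>
    filter(epoch %in% epochs, end - start > min_dur_ms) |>
    mutate(fix_id = dplyr::row_number())
  reg_of <- function(x, y) {
    out <- rep(NA_character_, length(x))
    for (i in seq_len(nrow(regions))) {
      hit <- x >= regions$x_min[i] & x <= regions$x_max[i] &
        y >= regions$y_min[i] & y <= regions$y_max[i]
      out[hit & is.na(out)] <- regions$region[i]
    }
    out
  }
  fx <- fx |> mutate(region = reg_of(x, y)) |> filter(!is.na(region))
  missing_regions <- setdiff(regions$region, unique(fx$region))
  if (length(missing_regions) > 0) {
    abort(sprintf("Session lacks fixations in region(s): %s; excluded.",
                  paste(missing_regions, collapse = ", ")),
          class = "wmdecode_input_error")
  }

  units <- sort(session$units$unit_id)
  win <- cbind(fx$start, fx$end)
  ord <- order(win[, 1])
  sp <- session$spikes
  idx <- findInterval(sp$time, win[ord, 1])
  ok <- idx >= 1 & sp$time < win[ord, 2][pmax(idx, 1)]
  counts <- tibble(unit_id = sp$unit_id[ok],
                   fix_id = fx$fix_id[ord][idx[ok]]) |>
    count(unit_id, fix_id)
  feats <- tidyr::expand_grid(fix_id = fx$fix_id, unit_id = units) |>
    left_join(counts, by = c("fix_id", "unit_id")) |>
    left_join(fx |> select(fix_id, start, end), by = "fix_id") |>
    mutate(rate = dplyr::coalesce(n, 0L) / ((end - start) / 1000)) |>
    select(fix_id, unit_id, rate) |>
    tidyr::pivot_wider(names_from = unit_id, values_from = rate) |>
    arrange(fix_id)
  m <- as.matrix(feats[, -1])
  decode_cv(m, fx$region[match(feats$fix_id, fx$fix_id)],
            k_folds = k_folds, n_balance = n_balance, cost = cost,
            seed = seed)
}

# --- saccade reference-frame binning ----------------------------------

#' Overlap between saccade-frame tuning and target tuning
#'
#' Joins per-unit saccade-frame tuning flags with delay-epoch target
#' selectivity and reports, per reference frame, what proportion of
#' units falls in each combination (tuned to both, either, or neither) —
#' the table used to ask whether putative eye-position signals and
#' working-memory signals live in the same cells.
#'
#' @param saccade_tuning Result of [saccade_frame_tuning()].
#' @param tuning Result of [anova_selectivity()]/[tuning_census()];
#'   only `period == "pre"` rows are used.
#' @return Tibble `frame`, `saccade_tuned`, `target_tuned`, `n`,
#'   `proportion` (within frame).
#' @export
saccade_target_overlap <- function(saccade_tuning, tuning) {
  target <- tuning |>
    filter(period == "pre", !is.na(selective)) |>
    select(unit_id, target_tuned = selective)
  saccade_tuning |>
    filter(!is.na(tuned)) |>
    inner_join(target, by = "unit_id") |>
    count(frame, saccade_tuned = tuned, .data$target_tuned) |>
    group_by(frame) |>
    mutate(proportion = n / sum(n)) |>
    ungroup()
}

#' Bin saccades in retinocentric and spatiocentric frames with power
#' matching
#'
#' Saccades are assigned to 2 x 2 quadrant bins over a 40 x 30 degree
#' field in two reference frames: retinocentric (displacement end minus
#' start) and spatiocentric (landing position relative to screen center).
#' To equate statistical power across frames, bins are ordered by count
#' within each frame, paired by rank across frames, and the larger bin of
#' each pair randomly downsampled to the smaller count. Bins with fewer
#' than `min_count` saccades are then dropped.
#'
#' @param saccades Saccade table.
#' @param screen A [screen_geometry()].
#' @param field_deg Field extent (degrees, width x height).
#' @param min_count Minimum retained bin count.
#' @param seed Seed for the downsampling.
#' @return Long tibble `frame`, `bin`, `saccade_row` (row index into
#'   `saccades`) after matching, with per-bin counts equal across paired
#'   ranks.
#' @export
saccade_frame_bins <- function(saccades, screen = screen_geometry(),
                               field_deg = c(40, 30), min_count = 10,
                               seed = 1) {
  dx_deg <- (saccades$end_x - saccades$start_x) * screen$deg_per_px_x
  dy_deg <- (saccades$end_y - saccades$start_y) * screen$deg_per_px_y
  ex_deg <- (saccades$end_x - screen$width_px / 2) * screen$deg_per_px_x
  ey_deg <- (saccades$end_y - screen$height_px / 2) * screen$deg_per_px_y
  quadrant <- function(x, y) {
    inside <- abs(x) <= field_deg[1] / 2 & abs(y) <= field_deg[2] / 2
    q <- 1L + (x > 0) + 2L * (y > 0)
    q[!inside] <- NA_integer_
    q
  }
  tab <- bind_rows(
    tibble(frame = "retinocentric", saccade_row = seq_len(nrow(saccades)),
           bin = quadrant(dx_deg, dy_deg)),
    tibble(frame = "spatiocentric", saccade_row = seq_len(nrow(saccades)),
           bin = quadrant(ex_deg, ey_deg))
  ) |>
    filter(!is.na(bin))

  counts <- tab |> count(frame, bin) |>
    group_by(frame) |>
    arrange(desc(n), bin, .by_group = TRUE) |>
    mutate(rank_ = dplyr::row_number()) |>
    ungroup()
  paired <- counts |>
    group_by(rank_) |>
    mutate(n_keep = min(n)) |>
    ungroup()

  with_seed_(seed, {
    kept <- purrr::pmap_dfr(paired, function(frame, bin, n, rank_, n_keep) {
      rows <- tab |> filter(.data$frame == .env$frame, .data$bin == .env$bin)
      rows[sample(nrow(rows), n_keep), ]
    })
    keep_bins <- kept |> count(frame, bin) |> filter(n >= min_count)
    kept |> semi_join(keep_bins, by = c("frame", "bin"))
  })
}

#' Saccade reference-frame tuning per unit
#'
#' Computes each unit's firing rate in a perisaccadic window and tests,
#' per reference frame, whether rates differ across the power-matched
#' quadrant bins (Kruskal-Wallis). Units (sessions) with fewer than
#' `min_bins` acceptable bins in a frame are excluded for that frame.
#'
#' @param spikes Spike table.
#' @param saccades Saccade table.
#' @param unit_ids Units to test.
#' @param screen A [screen_geometry()].
#' @param alpha Tuning threshold.
#' @param window_ms Perisaccadic rate window (from saccade start).
#' @param min_count,min_bins Bin acceptance rules.
#' @param seed Seed for the power matching.
#' @return Tibble `unit_id`, `frame`, `n_bins`, `p_value`, `tuned`.
#' @export
saccade_frame_tuning <- function(spikes, saccades,
                                 unit_ids = sort(unique(spikes$unit_id)),
                                 screen = screen_geometry(), alpha = 0.05,
                                 window_ms = 200, min_count = 10,
                                 min_bins = 3, seed = 1) {
  bins <- saccade_frame_bins(saccades, screen, min_count = min_count,
                             seed = seed)
  win_on <- saccades$start
  win_off <- saccades$start + window_ms
  ord <- order(win_on)
  sp <- spikes |> filter(unit_id %in% unit_ids)
  idx <- findInterval(sp$time, win_on[ord])
  ok <- idx >= 1 & sp$time < win_off[ord][pmax(idx, 1)]
  counts <- tibble(unit_id = sp$unit_id[ok],
                   saccade_row = ord[idx[ok]]) |>
    count(unit_id, saccade_row)

  purrr::map_dfr(unit_ids, function(u) {
    uc <- counts |> filter(unit_id == u)
    purrr::map_dfr(c("retinocentric", "spatiocentric"), function(fr) {
      fb <- bins |> filter(frame == fr)
      nb <- dplyr::n_distinct(fb$bin)
      if (nb < min_bins) {
        return(tibble(unit_id = u, frame = fr, n_bins = nb,
                      p_value = NA_real_, tuned = NA))
      }
      resp <- fb |>
        left_join(uc, by = "saccade_row") |>
        mutate(rate = dplyr::coalesce(n, 0L) / (window_ms / 1000))
      p <- tryCatch(kruskal.test(resp$rate, factor(resp$bin))$p.value,
                    error = function(e) NA_real_)
      tibble(unit_id = u, frame = fr, n_bins = nb, p_value = p,
             tuned = ifelse(is.na(p), NA, p < alpha))
    })
  })
}
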