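# Session container: one recording session as a set of tidy tables.

PERIOD_LEVELS <- c("pre", "early_post", "late_post")
EPOCH_LEVELS <- c("cue", "delay", "response")
CONDITIONS <- c("ketamine_wm", "saline_wm", "ketamine_perception")

#' Injection period levels
#'
#' Injection periods are defined relative to the injection time: `pre`
#' (before injection), `early_post` (injection to 30 min post) and
#' `late_post` (30 to 60 min post).
#'
#' @return Character vector of the three period labels in order.
#' @export
period_levels <- function() PERIOD_LEVELS

#' Construct a session recording
#'
#' Bundles the tables describing one recording session. All times are in
#' milliseconds from session start; epoch windows are half-open `[on, off)`.
#'
#' @param session_id Character id.
#' @param condition One of `"ketamine_wm"`, `"saline_wm"`,
#'   `"ketamine_perception"`.
#' @param injection_time Injection time (ms from session start).
#' @param trials Tibble with columns `trial_id`, `target_location` (1-9),
#'   `x`, `y`, `target_column`, `target_side`, `outcome`
#'   (`correct`/`incorrect`), `cue_on`, `delay_on`, `response_on`,
#'   `trial_end`, `period`, `response_time` (s, `NA` on incorrect trials).
#' @param units Tibble with `unit_id`, `is_single`, `array_id`,
#'   `sample_interval_us` and a `mean_waveform` list-column of voltage
#'   vectors.
#' @param spikes Tibble with `unit_id`, `time` (ms).
#' @param fixations Tibble with `trial_id`, `epoch`, `x`, `y` (screen px),
#'   `start`, `end` (ms).
#' @param saccades Tibble with `trial_id`, `start_x`, `start_y`, `end_x`,
#'   `end_y`, `start`, `end`.
#' @param trajectories Tibble with `trial_id`, `time`, `x`, `y` (arena
#'   units).
#' @param validate Run [validate_session()] on the result?
#' @return An object of class `session_recording`.
#' @export
session_recording <- function(session_id, condition, injection_time,
                              trials, units, spikes,
                              fixations = empty_fixations(),
                              saccades = empty_saccades(),
                              trajectories = empty_trajectories(),
                              validate = TRUE) {
  x <- structure(
    list(
      session_id = as.character(session_id),
      condition = match.arg(condition, CONDITIONS),
      injection_time = as.numeric(injection_time),
      trials = as_tibble(trials),
      units = as_tibble(units),
      spikes = as_tibble(spikes),
      fixations = as_tibble(fixations),
      saccades = as_tibble(saccades),
      trajectories = as_tibble(trajectories)
    ),
    class = "session_recording"
  )
  if (validate) validate_session(x)
  x
}

empty_fixations <- function() {
  tibble(trial_id = integer(), epoch = character(), x = numeric(),
         y = numeric(), start = numeric(), end = numeric())
}
empty_saccades <- function() {
  tibble(trial_id = integer(), start_x = numeric(), start_y = numeric(),
         end_x = numeric(), end_y = numeric(), start = numeric(),
         end = numeric())
}
empty_trajectories <- function() {
  tibble(trial_id = integer(), time = numeric(), x = numeric(), y = numeric())
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf("<session_recording> %s (%s)\n", x$session_id, x$condition))
  cat(sprintf("  trials: %d  units: %d  spikes: %d\n",
              nrow(x$trials), nrow(x$units), nrow(x$spikes)))
  cat(sprintf("  injection at %.0f ms; periods: %s\n", x$injection_time,
              paste(sprintf("%s=%d", names(table(x$trials$period)),
                            as.integer(table(x$trials$period))),
                    collapse = " ")))
  invisible(x)
}

fail_rows <- function(tbl, bad, what) {
  if (!any(bad)) return(invisible(NULL))
  shown <- utils::head(which(bad), 5)
  abort(c(
    sprintf("Session validation failed: %s (%d row(s)).", what, sum(bad)),
    sprintf("First offending rows: %s", paste(shown, collapse = ", "))
  ), class = "wmdecode_validation_error")
}

#' Validate a session recording
#'
#' Checks the structural invariants of the session contract: every spike
#' references a known unit and spike times are non-negative and sorted
#' within unit; epochs are ordered cue -> delay -> response with a 3000 ms
#' cue and a 2000 ms delay; each trial's injection-period label is
#' consistent with its start (cue onset) relative to the injection time
#' (early-post spans injection to 30 min, late-post 30 to 60 min); the
#' target column/side labels match the grid geometry.
#'
#' @param x A `session_recording`.
#' @return `x`, invisibly. Aborts with a
#'   `wmdecode_validation_error` describing the offending table and rows
#'   otherwise.
#' @export
validate_session <- function(x) {
  stopifnot(inherits(x, "session_recording"))
  tr <- x$trials
  need <- c("trial_id", "target_location", "x", "y", "target_column",
            "target_side", "outcome", "cue_on", "delay_on", "response_on",
            "trial_end", "period", "response_time")
  miss <- setdiff(need, names(tr))
  if (length(miss) > 0) {
    abort(sprintf("Trials table is missing column(s): %s",
                  paste(miss, collapse = ", ")),
          class = "wmdecode_validation_error")
  }

  fail_rows(tr, !(tr$target_location %in% 1:9), "target_location outside 1-9")
  g <- target_grid()
  fail_rows(tr, tr$target_column != g$target_column[tr$target_location],
            "target_column inconsistent with target_location")
  fail_rows(tr, tr$target_side != g$target_side[tr$target_location],
            "target_side inconsistent with target_location")
  fail_rows(tr, !(tr$outcome %in% c("correct", "incorrect")),
            "outcome not in {correct, incorrect}")
  fail_rows(tr, !(tr$period %in% PERIOD_LEVELS), "unknown period label")
  fail_rows(tr, abs(tr$delay_on - tr$cue_on - 3000) > 1e-6,
            "cue epoch is not 3000 ms")
  fail_rows(tr, abs(tr$response_on - tr$delay_on - 2000) > 1e-6,
            "delay epoch is not 2000 ms")
  fail_rows(tr, tr$trial_end <= tr$response_on,
            "trial_end not after response onset")

  inj <- x$injection_time
  half_hour <- 30 * 60 * 1000
  expected <- dplyr::case_when(
    tr$cue_on < inj ~ "pre",
    tr$cue_on < inj + half_hour ~ "early_post",
    tr$cue_on < inj + 2 * half_hour ~ "late_post",
    TRUE ~ NA_character_
  )
  fail_rows(tr, is.na(expected) | tr$period != expected,
            "period label inconsistent with injection_time")

  sp <- x$spikes
  if (nrow(sp) > 0) {
    fail_rows(sp, !(sp$unit_id %in% x$units$unit_id),
              "spike references unknown unit_id")
    fail_rows(sp, sp$time < 0, "negative spike time")
    ord <- sp |>
      group_by(unit_id) |>
      summarise(ok = !is.unsorted(time), .groups = "drop")
    if (!all(ord$ok)) {
      abort(sprintf("Spike times not non-decreasing for unit(s): %s",
                    paste(ord$unit_id[!ord$ok], collapse = ", ")),
            class = "wmdecode_validation_error")
    }
  }

  fx <- x$fixations
  if (nrow(fx) > 0) {
    fail_rows(fx, !(fx$epoch %in% EPOCH_LEVELS), "unknown fixation epoch")
    fail_rows(fx, fx$end <= fx$start, "fixation with non-positive duration")
  }
  invisible(x)
}

#' Write a session to a CSV directory
#'
#' The on-disk layout is a directory of tidy CSV tables (`trials.csv`,
#' `units.csv`, `waveforms.csv`, `spikes.csv`, `fixations.csv`,
#' `saccades.csv`, `trajectories.csv`) plus a `session.json` sidecar with
#' session-level metadata. Mean waveforms are stored long
#' (`unit_id`, `sample_idx`, `voltage`).
#'
#' @param x A `session_recording`.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(x, path) {
  stopifnot(inherits(x, "session_recording"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(session_id = x$session_id, condition = x$condition,
               injection_time = x$injection_time, format_version = 1L)
  jsonlite::write_json(meta, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_csv(x$trials, file.path(path, "trials.csv"))
  readr::write_csv(x$units |> select(-"mean_waveform"),
                   file.path(path, "units.csv"))
  wf <- x$units |>
    select(unit_id, "mean_waveform") |>
    mutate(sample_idx = purrr::map(.data$mean_waveform, seq_along)) |>
    tidyr::unnest(c("mean_waveform", "sample_idx")) |>
    rename(voltage = "mean_waveform") |>
    select(unit_id, sample_idx, voltage)
  readr::write_csv(wf, file.path(path, "waveforms.csv"))
  readr::write_csv(x$spikes, file.path(path, "spikes.csv"))
  readr::write_csv(x$fixations, file.path(path, "fixations.csv"))
  readr::write_csv(x$saccades, file.path(path, "saccades.csv"))
  readr::write_csv(x$trajectories, file.path(path, "trajectories.csv"))
  invisible(path)
}

read_table_or_fail <- function(path, name, col_types) {
  f <- file.path(path, name)
  if (!file.exists(f)) {
    abort(sprintf("Session at '%s' is missing required table '%s'.",
                  path, name),
          class = "wmdecode_io_error")
  }
  readr::read_csv(f, col_types = col_types, progress = FALSE)
}

#' Read a session from a CSV directory
#'
#' Inverse of [write_session()]; the returned object is validated.
#'
#' @param path Session directory.
#' @return A `session_recording`.
#' @export
read_session <- function(path) {
  meta_file <- file.path(path, "session.json")
  if (!file.exists(meta_file)) {
    abort(sprintf("Session at '%s' is missing 'session.json'.", path),
          class = "wmdecode_io_error")
  }
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)

  trials <- read_table_or_fail(path, "trials.csv", readr::cols(
    trial_id = readr::col_integer(),
    target_location = readr::col_integer(),
    target_column = readr::col_character(),
    target_side = readr::col_character(),
    outcome = readr::col_character(),
    period = readr::col_character(),
    .default = readr::col_double()
  ))
  units_flat <- read_table_or_fail(path, "units.csv", readr::cols(
    unit_id = readr::col_integer(),
    is_single = readr::col_logical(),
    array_id = readr::col_character(),
    .default = readr::col_double()
  ))
  wf <- read_table_or_fail(path, "waveforms.csv", readr::cols(
    unit_id = readr::col_integer(),
    sample_idx = readr::col_integer(),
    voltage = readr::col_double()
  ))
  wf_list <- wf |>
    arrange(unit_id, sample_idx) |>
    group_by(unit_id) |>
    summarise(mean_waveform = list(voltage), .groups = "drop")
  units <- units_flat |> left_join(wf_list, by = "unit_id")

  spikes <- read_table_or_fail(path, "spikes.csv", readr::cols(
    unit_id = readr::col_integer(), time = readr::col_double()
  ))
  fixations <- read_table_or_fail(path, "fixations.csv", readr::cols(
    trial_id = readr::col_integer(), epoch = readr::col_character(),
    .default = readr::col_double()
  ))
  saccades <- read_table_or_fail(path, "saccades.csv", readr::cols(
    trial_id = readr::col_integer(), .default = readr::col_double()
  ))
  trajectories <- read_table_or_fail(path, "trajectories.csv", readr::cols(
    trial_id = readr::col_integer(), .default = readr::col_double()
  ))

  session_recording(
    session_id = meta$session_id, condition = meta$condition,
    injection_time = meta$injection_time,
    trials = trials, units = units, spikes = spikes,
    fixations = fixations, saccades = saccades, trajectories = trajectories
  )
}
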