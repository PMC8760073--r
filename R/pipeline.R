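# Pipeline orchestration: configuration, stage dispatch, tidy CSV
# outputs and a reproducibility manifest.

PIPELINE_STAGES <- c("simulate", "behavior", "tuning", "decode",
                     "popcode", "waveforms", "gaze")

#' Pipeline configuration
#'
#' Builds (or reads from YAML/JSON) the configuration consumed by
#' [run_pipeline()]: which stages to run, where sessions come from (a
#' directory of session folders or the synthetic generator), the output
#' directory and the master seed from which every stage derives its own
#' child seed via [derive_seed()].
#'
#' @param stages Stages to run (subset of
#'   `simulate, behavior, tuning, decode, popcode, waveforms, gaze`, or
#'   `"all"`).
#' @param session_path Directory containing session subdirectories
#'   (ignored when `simulate` is among the stages, which generates one).
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param generator Named list of [generator_config()] overrides.
#' @param params Named list of per-stage parameter overrides.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(stages = "all", session_path = NULL,
                            out_dir = "wmdecode-out", seed = 1,
                            generator = list(), params = list()) {
  if (identical(stages, "all")) stages <- PIPELINE_STAGES
  unknown <- setdiff(stages, PIPELINE_STAGES)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown stage(s): %s. Known stages: %s.",
                  paste(unknown, collapse = ", "),
                  paste(PIPELINE_STAGES, collapse = ", ")),
          class = "wmdecode_config_error")
  }
  structure(list(stages = stages, session_path = session_path,
                 out_dir = out_dir, seed = as.integer(seed),
                 generator = generator, params = params),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Configuration file (`.yaml`/`.yml` or `.json`).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  pipeline_config(
    stages = raw$stages %||% "all",
    session_path = raw$session_path,
    out_dir = raw$out_dir %||% "wmdecode-out",
    seed = raw$seed %||% 1,
    generator = raw$generator %||% list(),
    params = raw$params %||% list()
  )
}

write_stage_csv <- function(df, out_dir, name) {
  readr::write_csv(df, file.path(out_dir, name))
}

#' Run the analysis pipeline
#'
#' Executes the configured stages on each session and writes tidy CSV
#' results plus a `manifest.json` recording package version, stages,
#' parameters and the per-stage child seeds. Identical configurations
#' (including the master seed) produce byte-identical result tables.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of the per-stage result tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  stage_seeds <- list()

  sessions <- list()
  if ("simulate" %in% config$stages) {
    seed_sim <- derive_seed(config$seed, "simulate")
    stage_seeds$simulate <- seed_sim
    cfg <- do.call(generator_config, config$generator)
    gen <- generate_session(cfg, seed = seed_sim)
    sdir <- file.path(config$out_dir, "session")
    write_session(gen$session, sdir)
    # ground truth written apart; analysis stages below never read it
    tdir <- file.path(config$out_dir, "ground_truth")
    dir.create(tdir, showWarnings = FALSE)
    readr::write_csv(gen$truth$units, file.path(tdir, "units.csv"))
    readr::write_csv(gen$truth$tuning, file.path(tdir, "tuning.csv"))
    readr::write_csv(gen$truth$trial_gain, file.path(tdir, "trial_gain.csv"))
    readr::write_csv(gen$truth$separation, file.path(tdir, "separation.csv"))
    sessions <- list(gen$session)
  } else if (!is.null(config$session_path)) {
    dirs <- list.dirs(config$session_path, recursive = FALSE)
    if (file.exists(file.path(config$session_path, "session.json"))) {
      dirs <- config$session_path
    }
    sessions <- lapply(dirs, read_session)
  }
  if (length(setdiff(config$stages, "simulate")) > 0 &&
      length(sessions) == 0) {
    abort("No sessions to analyze: provide session_path or the simulate stage.",
          class = "wmdecode_config_error")
  }

  for (session in sessions) {
    p <- config$params
    if ("behavior" %in% config$stages) {
      stage_seeds$behavior <- derive_seed(config$seed, "behavior")
      perf <- percent_correct(session$trials)
      rt <- response_times(session$trials)
      occ <- grid_occupancy(session$trajectories, session$trials,
                            start_line_y = p$start_line_y %||% -500)
      results$performance_by_period <- perf
      results$response_times <- rt
      results$grid_occupancy <- occ$percent
      write_stage_csv(perf, config$out_dir, "performance_by_period.csv")
      write_stage_csv(rt, config$out_dir, "response_times.csv")
      write_stage_csv(occ$percent, config$out_dir, "grid_occupancy.csv")
    }
    if ("tuning" %in% config$stages) {
      s <- derive_seed(config$seed, "tuning")
      stage_seeds$tuning <- s
      tun <- tuning_census(session, epoch = p$tuning_epoch %||% "delay",
                           alpha = p$tuning_alpha %||% 0.05, seed = s)
      rates <- session_epoch_rates(session, p$tuning_epoch %||% "delay")
      slopes <- ranked_slope(rates |>
                               select(unit_id, period, location, rate))
      results$tuning_results <- tun |> select(-"location_means")
      results$ranked_slopes <- as_tibble(slopes)
      write_stage_csv(results$tuning_results, config$out_dir,
                      "tuning_results.csv")
      write_stage_csv(results$ranked_slopes, config$out_dir,
                      "ranked_slopes.csv")
    }
    if ("decode" %in% config$stages) {
      s <- derive_seed(config$seed, "decode")
      stage_seeds$decode <- s
      rates <- session_epoch_rates(session, p$decode_epoch %||% "delay")
      per_period <- purrr::map_dfr(unique(rates$period), function(pd) {
        sub <- rates |> filter(period == pd)
        labs <- sub |> distinct(trial_id, target_column) |>
          arrange(trial_id)
        r <- decode_cv(sub |> select(trial_id, unit_id, rate),
                       labs$target_column,
                       n_balance = p$n_balance %||% 20,
                       cost = p$cost %||% NULL,
                       seed = derive_seed(s, pd))
        tibble(period = pd, accuracy = r$accuracy,
               n_per_class = r$n_per_class)
      })
      results$decoding_results <- per_period
      write_stage_csv(per_period, config$out_dir, "decoding_results.csv")
    }
    if ("popcode" %in% config$stages) {
      s <- derive_seed(config$seed, "popcode")
      stage_seeds$popcode <- s
      rates <- session_epoch_rates(session, p$popcode_epoch %||% "delay")
      sweep <- random_ensemble_sweep(
        rates, sizes = p$sizes %||% c(2, 3, 5),
        n_ensembles = p$n_ensembles %||% 1000, seed = s)
      out <- sweep |>
        mutate(unit_ids = purrr::map_chr(unit_ids, paste, collapse = ";"))
      results$popcode_stats <- out
      write_stage_csv(out, config$out_dir, "popcode_stats.csv")
    }
    if ("waveforms" %in% config$stages) {
      stage_seeds$waveforms <- derive_seed(config$seed, "waveforms")
      cls <- tryCatch(
        classify_waveforms(session$units,
                           single_only = p$waveform_single_only %||% TRUE),
        wmdecode_input_error = function(e) {
          warn(paste("Waveform mixture not fit (too few widths in this",
                     "session); classes left NA. Pool widths across",
                     "sessions and pass `mixture` to classify_waveforms()."))
          NULL
        })
      if (is.null(cls)) {
        widths <- purrr::map2_dbl(
          session$units$mean_waveform, session$units$sample_interval_us,
          function(wf, si) waveform_width(wf, si))
        cls <- tibble(unit_id = session$units$unit_id, width = widths,
                      class = NA_character_)
        fit <- NULL
      } else {
        fit <- attr(cls, "fit")
      }
      results$waveform_class <- cls
      write_stage_csv(cls, config$out_dir, "waveform_class.csv")
      if (!is.null(fit)) {
        jsonlite::write_json(
          list(model = fit$model, means = fit$means, sds = fit$sds,
               weights = fit$weights, aic_1g = fit$aic_1g,
               aic_2g = fit$aic_2g, threshold = fit$threshold),
          file.path(config$out_dir, "waveform_mixture.json"),
          auto_unbox = TRUE, digits = NA)
      }
    }
    if ("gaze" %in% config$stages) {
      s <- derive_seed(config$seed, "gaze")
      stage_seeds$gaze <- s
      prop <- fixation_on_target_proportion(session$fixations,
                                            session$trials)
      fix_dec <- tryCatch(
        glance(decode_target_from_fixations(
          session$fixations, session$trials,
          n_balance = p$n_balance %||% 20, cost = p$cost %||% NULL,
          seed = derive_seed(s, "fixdec"))),
        error = function(e) tibble(accuracy = NA_real_))
      sac <- saccade_frame_tuning(session$spikes, session$saccades,
                                  unit_ids = sort(session$units$unit_id),
                                  seed = derive_seed(s, "saccade"))
      results$gaze_results <- prop
      results$fixation_decoding <- fix_dec
      results$saccade_tuning <- sac
      write_stage_csv(prop, config$out_dir, "gaze_results.csv")
      write_stage_csv(fix_dec, config$out_dir, "fixation_decoding.csv")
      write_stage_csv(sac, config$out_dir, "saccade_tuning.csv")
    }
  }

  manifest <- list(
    package = "wmdecode",
    version = as.character(utils::packageVersion("wmdecode")),
    stages = config$stages,
    master_seed = config$seed,
    stage_seeds = stage_seeds,
    params = config$params,
    generator = config$generator
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}
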