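make_fixations <- function(trials, where = c("target", "off")) {
  where <- match.arg(where)
  tpos <- target_screen_xy()
  purrr::map_dfr(seq_len(nrow(trials)), function(i) {
    tr <- trials[i, ]
    pos <- if (where == "target") {
      c(tpos$sx[tr$target_location], tpos$sy[tr$target_location])
    } else {
      # far corner of the screen, outside any target window
      c(5, 5)
    }
    tibble::tibble(trial_id = tr$trial_id, epoch = "delay",
                   x = pos[1], y = pos[2],
                   start = tr$delay_on + 100, end = tr$delay_on + 400)
  })
}

test_that("on-target fixation proportion hits the 0 and 1 extremes", {
  tr <- manual_trials(rep("correct", 9))
  on <- fixation_on_target_proportion(make_fixations(tr, "target"), tr)
  expect_equal(on$proportion, 1)
  off <- fixation_on_target_proportion(make_fixations(tr, "off"), tr)
  expect_equal(off$proportion, 0)
})

test_that("a zero-fixation group is flagged undefined", {
  tr <- manual_trials(rep("correct", 3))
  fx <- make_fixations(tr)[0, ]
  expect_warning(
    out <- fixation_on_target_proportion(fx, tr, by_period = FALSE),
    regexp = "undefined")
  expect_true(out$undefined)
})

test_that("the generator's on-target bias is recovered from fixations", {
  gen <- fixture_session()
  s <- gen$session
  out <- fixation_on_target_proportion(s$fixations, s$trials,
                                       by_period = FALSE)
  # bias 0.3 plus uniform fixations that land on target by chance (~1/16),
  # minus biased fixations jittered outside the window
  expect_gt(out$proportion, 0.15)
  expect_lt(out$proportion, 0.45)
})

test_that("class-specific fixation cells decode perfectly; identical maps sit at chance", {
  tr <- manual_trials(rep("correct", 45))
  grid16 <- screen_grid()
  # fixations deterministically in a column-specific cell
  cell_x <- c(left = 100, center = 400, right = 700)
  fx <- purrr::map_dfr(seq_len(nrow(tr)), function(i) {
    tibble::tibble(trial_id = tr$trial_id[i], epoch = "delay",
                   x = cell_x[[tr$target_column[i]]], y = 100,
                   start = tr$delay_on[i] + 50, end = tr$delay_on[i] + 250)
  })
  r <- decode_target_from_fixations(fx, tr, n_balance = 3, cost = 1,
                                    seed = 1)
  expect_equal(r$accuracy, 1)

  fx_same <- fx |> dplyr::mutate(x = 500, y = 380)
  r2 <- decode_target_from_fixations(fx_same, tr, n_balance = 3, cost = 1,
                                     seed = 1)
  expect_lt(abs(r2$accuracy - 1 / 3), 0.2)
})

test_that("eye-region decoding rejects sessions missing a region", {
  s <- fixture_session()$session
  far <- tibble::tibble(region = "nowhere", x_min = 5000, x_max = 5100,
                        y_min = 5000, y_max = 5100)
  regions <- dplyr::bind_rows(default_eye_regions(), far)
  expect_error(
    decode_eye_region_from_neurons(s, regions = regions, cost = 1,
                                   n_balance = 2),
    regexp = "nowhere", class = "wmdecode_input_error")
})

test_that("neural eye-region decoding runs above chance on target-biased gaze", {
  s <- fixture_session()$session
  r <- decode_eye_region_from_neurons(s, n_balance = 3, cost = 1, seed = 2)
  expect_equal(length(r$classes), 4)
  expect_equal(r$k_folds, 4)
  # fixations are target-biased and units target-tuned, so the region
  # carries decodable structure
  expect_gt(r$accuracy, 0.25)
})

test_that("power matching equalizes paired bin counts and never adds saccades", {
  s <- fixture_session()$session
  raw_counts <- local({
    sc <- s$saccades
    geom <- screen_geometry()
    dx <- (sc$end_x - sc$start_x) * geom$deg_per_px_x
    dy <- (sc$end_y - sc$start_y) * geom$deg_per_px_y
    inside <- abs(dx) <= 20 & abs(dy) <= 15
    table(1L + (dx > 0) + 2L * (dy > 0), useNA = "no")
  })
  bins <- saccade_frame_bins(s$saccades, seed = 3)
  counts <- bins |> dplyr::count(frame, bin)
  ranked <- counts |>
    dplyr::group_by(frame) |>
    dplyr::arrange(dplyr::desc(n), .by_group = TRUE) |>
    dplyr::mutate(rank_ = dplyr::row_number()) |>
    dplyr::ungroup() |>
    tidyr::pivot_wider(id_cols = rank_, names_from = frame,
                       values_from = n)
  expect_equal(ranked$retinocentric, ranked$spatiocentric)
  expect_true(all(counts$n >= 10))
  # matching can only shrink bins
  retino <- counts |> dplyr::filter(frame == "retinocentric")
  expect_true(all(retino$n <= max(raw_counts)))
})

test_that("frame-specific drive is detected in the matching frame only", {
  set.seed(33)
  n <- 500
  # displacement quadrant independent of landing quadrant by construction
  end_x <- runif(n, 100, 924)
  end_y <- runif(n, 100, 668)
  dx <- sample(c(-1, 1), n, TRUE) * runif(n, 30, 200)
  dy <- sample(c(-1, 1), n, TRUE) * runif(n, 30, 150)
  sac <- tibble::tibble(
    trial_id = 1L, start_x = end_x - dx, start_y = end_y - dy,
    end_x = end_x, end_y = end_y,
    start = seq(1000, by = 1000, length.out = n),
    end = seq(1000, by = 1000, length.out = n) + 40)
  retino_q <- 1L + (dx > 0) + 2L * (dy > 0)
  # unit keyed to retinocentric quadrant 1
  rate_hz <- ifelse(retino_q == 1L, 40, 5)
  spikes <- purrr::map_dfr(seq_len(n), function(i) {
    k <- rpois(1, rate_hz[i] * 0.2)
    if (k == 0) return(NULL)
    tibble::tibble(unit_id = 1L, time = sort(runif(k, sac$start[i],
                                                   sac$start[i] + 200)))
  })
  out <- saccade_frame_tuning(spikes, sac, unit_ids = 1L, seed = 4)
  expect_true(out$tuned[out$frame == "retinocentric"])
  expect_gt(out$p_value[out$frame == "spatiocentric"], 1e-3)
})

test_that("saccade/target tuning overlap proportions sum to one per frame", {
  sac <- tibble::tibble(unit_id = rep(1:6, 2),
                        frame = rep(c("retinocentric", "spatiocentric"),
                                    each = 6),
                        n_bins = 4,
                        p_value = rep(c(0.01, 0.5), 6),
                        tuned = rep(c(TRUE, FALSE), 6))
  tun <- tibble::tibble(unit_id = 1:6, period = "pre",
                        anova_p = c(0.01, 0.2, 0.03, 0.6, 0.01, 0.9),
                        selective = anova_p < 0.05)
  ov <- saccade_target_overlap(sac, tun)
  sums <- ov |> dplyr::group_by(frame) |>
    dplyr::summarise(s = sum(proportion), n = sum(n), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-12))
  expect_true(all(sums$n == 6))
  both <- ov |>
    dplyr::filter(frame == "retinocentric", saccade_tuned, target_tuned)
  expect_equal(both$n, 3)  # units 1, 3, 5 tuned to both by construction
})

test_that("untuned units flag at roughly the nominal rate", {
  set.seed(34)
  s <- fixture_session()$session
  # Poisson spikes independent of gaze for 30 pseudo-units
  t_max <- max(s$saccades$end)
  spikes <- purrr::map_dfr(1:30, function(u) {
    k <- rpois(1, 5 * t_max / 1000)
    tibble::tibble(unit_id = u, time = sort(runif(k, 0, t_max)))
  })
  out <- saccade_frame_tuning(spikes, s$saccades, unit_ids = 1:30,
                              seed = 5)
  frac <- mean(out$tuned, na.rm = TRUE)
  # 60 tests at alpha 0.05: allow up to ~4 binomial SDs above nominal
  expect_lt(frac, 0.05 + 4 * sqrt(0.05 * 0.95 / 60))
})
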