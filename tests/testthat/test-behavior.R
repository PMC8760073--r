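test_that("percent correct uses the exact one-sided binomial tail against 1/9", {
  # all correct: tail is (1/9)^n
  tr <- manual_trials(rep("correct", 100))
  out <- suppressWarnings(percent_correct(tr))
  expect_equal(out$percent_correct, 100)
  expect_equal(log(out$p_binomial), 100 * log(1 / 9), tolerance = 1e-10)

  # 30/90 vs the manual tail-sum oracle
  tr2 <- manual_trials(rep(c("correct", "incorrect"), c(30, 60)))
  out2 <- suppressWarnings(percent_correct(tr2))
  oracle <- sum(dbinom(30:90, 90, 1 / 9))
  expect_equal(out2$p_binomial, oracle, tolerance = 1e-12)
  expect_equal(out2$percent_correct, 100 * 30 / 90)
})

test_that("a uniform guesser over nine targets sits at ~11% correct", {
  gen <- generate_session(
    generator_config(condition = "ketamine_perception", n_ns = 1, n_bs = 2,
                     trials_per_location = 12,
                     p_correct = c(pre = 1 / 9, early_post = 1 / 9,
                                   late_post = 1 / 9)),
    seed = 55)
  out <- percent_correct(gen$session$trials)
  pooled <- sum(out$n_correct) / sum(out$n_trials)
  n <- sum(out$n_trials)
  expect_lt(abs(pooled - 1 / 9), 3 * sqrt((1 / 9) * (8 / 9) / n))
})

test_that("response times summarise correct trials with SEM conventions", {
  one <- response_times(manual_trials("correct", rt = 4.2))
  expect_equal(one$mean_rt, 4.2)
  expect_equal(one$sem_rt, 0)
  expect_true(one$sem_degenerate)

  two <- response_times(manual_trials(c("correct", "correct"), rt = c(3, 5)))
  expect_equal(two$mean_rt, 4)
  expect_false(two$sem_degenerate)

  none <- response_times(manual_trials(rep("incorrect", 4)))
  expect_equal(nrow(none), 0)
})

test_that("drug sessions navigate slower early post-injection", {
  rt <- response_times(fixture_session()$session$trials)
  expect_gt(rt$mean_rt[rt$period == "early_post"],
            rt$mean_rt[rt$period == "pre"])
})

test_that("a straight path marks exactly the cells it crosses", {
  g <- trajectory_grid()
  # vertical path up the middle column: crosses the 5 cells of column 3
  tr <- manual_trials(rep("correct", 1))
  traj <- tibble::tibble(trial_id = 1L, time = seq(0, 1000, by = 50),
                         x = 0, y = seq(-600, 420, length.out = 21))
  occ <- grid_occupancy(traj, tr, grid = g, start_line_y = -500)
  per <- occ$per_trial
  entered <- per$cell[per$entered == 1]
  expected <- vapply(1:5, function(r) (r - 1L) * 5L + 3L, integer(1))
  expect_setequal(entered, expected)
  expect_equal(sum(per$entered), 5)
})

test_that("occupancy is invariant to trajectory sampling density", {
  tr <- manual_trials(rep("correct", 1))
  path_fine <- tibble::tibble(trial_id = 1L, time = seq(0, 1000, by = 10),
                              x = seq(-400, 400, length.out = 101),
                              y = seq(-430, 430, length.out = 101))
  path_coarse <- path_fine[c(1, 51, 101), ]
  occ_f <- grid_occupancy(path_fine, tr, start_line_y = -500)
  occ_c <- grid_occupancy(path_coarse, tr, start_line_y = -500)
  expect_equal(occ_c$per_trial$entered, occ_f$per_trial$entered)
})

test_that("identical trials give occupancy percentages of exactly 0 or 100", {
  tr <- manual_trials(rep("correct", 4))
  tr$target_location <- 5L
  traj <- purrr::map_dfr(1:4, function(i) {
    tibble::tibble(trial_id = i, time = seq(0, 500, by = 50),
                   x = 0, y = seq(-520, 0, length.out = 11))
  })
  occ <- grid_occupancy(traj, tr)
  expect_true(all(occ$percent$percent %in% c(0, 100)))
})

test_that("difference maps between identical periods are all zero", {
  s <- fixture_session()$session
  occ <- grid_occupancy(s$trajectories, s$trials)
  d <- occupancy_increase(occ, occ)
  expect_true(all(d$increase == 0))
})

test_that("the period-by-condition ANOVA recovers a planted interaction", {
  set.seed(44)
  d <- tidyr::expand_grid(period = period_levels(),
                          condition = c("drug", "saline"),
                          session = 1:8) |>
    dplyr::mutate(value = rnorm(dplyr::n(), sd = 2) +
                    ifelse(period == "early_post" & condition == "drug",
                           -8, 0))
  out <- period_condition_anova(d, "value")
  expect_setequal(out$term,
                  c("period", "condition", "period:condition", "Residuals"))
  expect_lt(out$p.value[out$term == "period:condition"], 0.01)

  flat <- d |> dplyr::mutate(value = rnorm(dplyr::n()))
  out2 <- period_condition_anova(flat, "value")
  expect_gt(min(out2$p.value, na.rm = TRUE), 1e-4)
})

test_that("higher dispersion spreads trajectories over more cells", {
  s <- fixture_session()$session
  occ <- grid_occupancy(s$trajectories, s$trials)
  per <- occ$per_trial |>
    dplyr::group_by(trial_id) |>
    dplyr::summarise(n_cells = sum(entered), .groups = "drop") |>
    dplyr::left_join(s$trials |> dplyr::select(trial_id, period),
                     by = "trial_id")
  m <- tapply(per$n_cells, per$period, mean)
  expect_gt(m[["early_post"]], m[["pre"]])  # dispersion 80 vs 30
})
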