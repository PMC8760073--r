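test_that("epoch rates are spike counts over half-open windows", {
  tr <- manual_trials(rep("correct", 2))
  # trial 1 delay window is [3000, 5000); trial 2 [13000, 15000)
  spikes <- tibble::tibble(
    unit_id = c(rep(1L, 6), 1L, 2L),
    time = c(seq(3100, 4600, length.out = 6), 5000, 13500)
  ) |> dplyr::arrange(unit_id, time)
  r <- epoch_rates(spikes, tr, "delay", unit_ids = c(1L, 2L))
  expect_equal(nrow(r), 4)
  expect_equal(r$rate[r$unit_id == 1 & r$trial_id == 1], 3)  # 6 / 2 s
  # spike exactly at window end is excluded (half-open)
  expect_equal(r$rate[r$unit_id == 1 & r$trial_id == 2], 0)
  expect_equal(r$rate[r$unit_id == 2 & r$trial_id == 2], 0.5)
  expect_equal(r$rate[r$unit_id == 2 & r$trial_id == 1], 0)
})

test_that("ANOVA selectivity matches a manual F-test when counts are equal", {
  set.seed(7)
  rates <- tidyr::expand_grid(unit_id = 1L, period = "pre",
                              location = 1:9, rep = 1:12) |>
    dplyr::mutate(rate = rnorm(dplyr::n(), mean = 5 + (location == 4) * 3))
  res <- anova_selectivity(rates |> dplyr::select(-rep), seed = 3)
  # equal counts: subsampling is a no-op, median p equals the full-data p
  oracle <- manual_oneway_p(rates$rate, rates$location)
  expect_equal(res$anova_p, oracle, tolerance = 1e-12)
  expect_true(res$selective)
  expect_equal(res$preferred_location, 4L)
})

test_that("strongly tuned units are detected and degenerate units skipped", {
  set.seed(8)
  strong <- tidyr::expand_grid(unit_id = 1L, period = "pre",
                               location = 1:9, rep = 1:20) |>
    dplyr::mutate(rate = rpois(dplyr::n(),
                               ifelse(location == 2, 20, 2)) / 2)
  res <- anova_selectivity(strong |> dplyr::select(-rep), seed = 4)
  expect_lt(res$anova_p, 1e-3)
  expect_equal(res$preferred_location, 2L)

  zero <- tidyr::expand_grid(unit_id = 2L, period = "pre",
                             location = 1:9, rep = 1:5) |>
    dplyr::mutate(rate = 0)
  rz <- anova_selectivity(zero |> dplyr::select(-rep), seed = 4)
  expect_true(rz$skipped)
  expect_true(is.na(rz$anova_p))
})

test_that("units with too few trials per location are skipped", {
  rates <- tibble::tibble(unit_id = 1L, period = "pre",
                          location = rep(1:9, c(1, rep(3, 8))),
                          rate = rnorm(25, 5))
  res <- anova_selectivity(rates, seed = 1)
  expect_true(res$skipped)
  expect_equal(res$n_per_location, 1)
})

test_that("ranked slopes recover flat and linear profiles exactly", {
  flat <- tidyr::expand_grid(unit_id = 1L, period = "pre", location = 1:9) |>
    dplyr::mutate(rate = 5)
  expect_equal(ranked_slope(flat, normalize = FALSE)$slope, 0)

  lin <- tidyr::expand_grid(unit_id = 1L, period = "pre", location = 1:9) |>
    dplyr::mutate(rate = 10 - location)  # ranked curve 9, 8, ..., 1
  sl <- ranked_slope(lin, normalize = FALSE)
  expect_equal(sl$slope, -1, tolerance = 1e-12)
  expect_equal(sl$intercept, 10, tolerance = 1e-12)
})

test_that("flattened tuning shrinks the ranked-slope magnitude", {
  rates <- fixture_delay_rates()
  sl <- ranked_slope(rates |>
                       dplyr::select(unit_id, period, location, rate))
  expect_lt(abs(sl$slope[sl$period == "early_post"]),
            abs(sl$slope[sl$period == "pre"]))
  expect_true(all(sl$slope <= 0))  # ranking makes slopes non-positive
})

test_that("spike density functions integrate to the spike count", {
  # single spike: peak 1000 * dnorm(0, 0, 150) ~ 2.66 Hz at the spike
  one <- sdf(5000, from = 3000, to = 7000, step_ms = 5)
  expect_equal(max(one$rate), 1000 / (150 * sqrt(2 * pi)), tolerance = 1e-6)
  expect_equal(one$time[which.max(one$rate)], 5000)

  expect_true(all(sdf(numeric(0), 0, 1000)$rate == 0))

  # linearity: two spikes = sum of two kernels
  a <- sdf(4000, 0, 10000, step_ms = 5)
  b <- sdf(6000, 0, 10000, step_ms = 5)
  ab <- sdf(c(4000, 6000), 0, 10000, step_ms = 5)
  expect_equal(ab$rate, a$rate + b$rate, tolerance = 1e-12)

  # mass conservation within 0.1% over a wide window
  spk <- c(4000, 4500, 5200, 6100)
  wide <- sdf(spk, 4000 - 1000, 6100 + 1000, step_ms = 1)
  integral <- sum(wide$rate) * 1 / 1000  # Hz * s
  expect_lt(abs(integral - length(spk)) / length(spk), 0.001)
})

test_that("plane fits recover exact polynomial surfaces and match the normal equations", {
  g <- target_grid() |> dplyr::mutate(xs = x / 290, ys = y / 290)
  lin <- plane_fit(tibble::tibble(x = g$xs, y = g$ys, rate = 2 * g$xs))
  expect_equal(unname(lin$coefficients["p10"]), 2, tolerance = 1e-10)
  expect_equal(unname(lin$coefficients[c("p00", "p01", "p20", "p02", "p11")]),
               rep(0, 5), tolerance = 1e-10)

  quad <- plane_fit(tibble::tibble(x = g$xs, y = g$ys, rate = g$xs^2))
  expect_equal(unname(quad$coefficients["p20"]), 1, tolerance = 1e-10)

  set.seed(12)
  z <- rnorm(9)
  fit <- plane_fit(tibble::tibble(x = g$xs, y = g$ys, rate = z))
  X <- cbind(1, g$xs, g$ys, g$xs^2, g$ys^2, g$xs * g$ys)
  oracle <- qr.solve(crossprod(X), crossprod(X, z))  # normal equations
  expect_equal(unname(fit$coefficients), as.numeric(oracle),
               tolerance = 1e-10)
  expect_equal(tidy(fit)$term, c("p00", "p10", "p01", "p20", "p02", "p11"))

  degen <- tibble::tibble(x = rep(1, 9), y = rep(2, 9), rate = rnorm(9))
  expect_error(plane_fit(degen), class = "wmdecode_input_error")
})

test_that("cell-type contrasts detect the drug direction on pooled sessions", {
  # preferred-rate decrease in NS and least-preferred increase in BS,
  # tested on per-trial delay rates pooled over two seeded sessions
  pool <- purrr::map_dfr(1:2, function(i) {
    gen <- generate_session(
      generator_config(n_ns = 6, n_bs = 10, trials_per_location = 8),
      seed = 200 + i)
    s <- gen$session
    epoch_rates(s$spikes, s$trials, "delay") |>
      dplyr::left_join(s$trials |>
                         dplyr::select(trial_id,
                                       location = target_location, period),
                       by = "trial_id") |>
      dplyr::mutate(unit_id = unit_id + 1000 * i) |>
      dplyr::left_join(gen$truth$units |>
                         dplyr::mutate(unit_id = unit_id + 1000 * i) |>
                         dplyr::select(unit_id, class),
                       by = "unit_id")
  })
  contrast <- preferred_rate_contrast(
    pool |> dplyr::select(unit_id, period, location, rate),
    pool |> dplyr::distinct(unit_id, class))
  ns_pref <- contrast |>
    dplyr::filter(class == "NS", location_type == "preferred")
  bs_least <- contrast |>
    dplyr::filter(class == "BS", location_type == "least_preferred")
  expect_lt(ns_pref$mean_early, ns_pref$mean_pre)
  expect_lt(ns_pref$p_value, 0.05)
  expect_gt(bs_least$mean_early, bs_least$mean_pre)
  expect_lt(bs_least$p_value, 0.05)
})
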