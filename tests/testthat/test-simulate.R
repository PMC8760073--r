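test_that("null perturbation leaves early-post tuning identical to pre", {
  gen <- generate_session(
    generator_config(g_ns = 1, delta_bs = 0, n_ns = 3, n_bs = 5,
                     trials_per_location = 2),
    seed = 21)
  tun <- gen$truth$tuning |>
    tidyr::pivot_wider(names_from = period, values_from = rate)
  expect_equal(tun$early_post, tun$pre)
  expect_equal(tun$late_post, tun$pre)
})

test_that("shared-gain strength rho controls pairwise count correlations", {
  mean_offdiag_cor <- function(rho, seed) {
    gen <- generate_session(
      generator_config(condition = "saline_wm", n_ns = 4, n_bs = 8,
                       trials_per_location = 12, rho = rho, fano = 1),
      seed = seed)
    s <- gen$session
    rates <- epoch_rates(s$spikes, s$trials, "delay") |>
      dplyr::left_join(s$trials |>
                         dplyr::select(trial_id, target_location),
                       by = "trial_id") |>
      dplyr::group_by(unit_id, target_location) |>
      dplyr::mutate(resid = rate - mean(rate)) |>
      dplyr::ungroup()
    m <- rates |>
      dplyr::select(trial_id, unit_id, resid) |>
      tidyr::pivot_wider(names_from = unit_id, values_from = resid)
    cm <- cor(as.matrix(m[, -1]))
    mean(cm[upper.tri(cm)])
  }
  c0 <- mean_offdiag_cor(0, 31)
  c2 <- mean_offdiag_cor(0.2, 31)
  c4 <- mean_offdiag_cor(0.4, 31)
  expect_lt(abs(c0), 0.05)  # independent by construction
  expect_gt(c2, c0)
  expect_gt(c4, c2)
})

test_that("empirical location means converge to the stored tuning curve", {
  gen <- generate_session(
    generator_config(condition = "saline_wm", n_ns = 2, n_bs = 4,
                     trials_per_location = 15, rho = 0, fano = 1),
    seed = 41)
  s <- gen$session
  rates <- epoch_rates(s$spikes, s$trials, "delay") |>
    dplyr::left_join(s$trials |>
                       dplyr::select(trial_id, location = target_location,
                                     period),
                     by = "trial_id") |>
    dplyr::group_by(unit_id, location) |>
    dplyr::summarise(emp = mean(rate), se = sd(rate) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
  tru <- gen$truth$tuning |> dplyr::filter(period == "pre")
  j <- dplyr::left_join(rates, tru, by = c("unit_id", "location"))
  # saline: same curve in all periods, so 45 trials per location mean;
  # each unit-location within 4 SE of its true rate (Poisson counts)
  frac_in <- mean(abs(j$emp - j$rate) <= 4 * pmax(j$se, 1e-9))
  expect_gt(frac_in, 0.95)
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(g_ns = 1.5), class = "wmdecode_config_error")
  expect_error(generator_config(delta_bs = -1),
               class = "wmdecode_config_error")
  expect_error(generator_config(p_correct = c(pre = 0, early_post = .5,
                                              late_post = .5)),
               class = "wmdecode_config_error")
  expect_error(generator_config(width_ns_mean = 500, width_bs_mean = 400),
               class = "wmdecode_config_error")
  expect_error(
    generate_session(generator_config(n_ns = 1, n_bs = 2,
                                      trials_per_location = 60),
                     seed = 1),
    regexp = "30 min", class = "wmdecode_config_error")
  expect_error(generator_config(peak_rate = 1, baseline_rate = 2),
               class = "wmdecode_config_error")
})

test_that("generate_null_units handles edge cases and emits flat tuning", {
  expect_equal(nrow(generate_null_units(0)), 0)
  z <- generate_null_units(3, rate = 0, trials_per_location = 5, seed = 5)
  expect_true(all(z$rate == 0))
  nu <- generate_null_units(5, rate = 5, trials_per_location = 50, seed = 6)
  means <- nu |>
    dplyr::group_by(unit_id, location) |>
    dplyr::summarise(m = mean(rate), .groups = "drop")
  # flat in expectation: per-location means near 5 Hz
  expect_true(all(abs(means$m - 5) < 1.2))
})

test_that("ground truth is emitted alongside every generated session", {
  gen <- fixture_session()
  expect_named(gen, c("session", "truth"))
  expect_setequal(names(gen$truth),
                  c("units", "tuning", "trial_gain", "separation"))
  expect_equal(nrow(gen$truth$tuning),
               nrow(gen$session$units) * 3 * 9)
  expect_equal(gen$truth$trial_gain$trial_id, gen$session$trials$trial_id)
  # drug-on: true decodable separation drops early-post
  sep <- gen$truth$separation
  expect_lt(sep$ps_true[sep$period == "early_post"],
            sep$ps_true[sep$period == "pre"])
})
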