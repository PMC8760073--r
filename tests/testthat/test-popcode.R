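test_that("population signal is the norm of the class mean difference", {
  a <- rbind(c(3, 0), c(3, 0), c(3, 0))
  b <- rbind(c(0, 4), c(0, 4), c(0, 4))
  ps <- population_signal(a, b)
  expect_equal(ps$delta_f, c(3, -4), ignore_attr = TRUE)
  expect_equal(ps$ps, 5)
  expect_equal(ps$u, c(3, -4) / 5, ignore_attr = TRUE)

  same <- population_signal(a, a)
  expect_equal(same$ps, 0)
  expect_true(all(is.na(same$u)))
  expect_equal(theoretical_accuracy(same$ps, NA), 0.5)
})

test_that("projected precision follows the eigenstructure closed forms", {
  expect_equal(projected_precision(diag(2) * 4, c(1, 0))$pp, 0.5)
  expect_equal(projected_precision(diag(c(1, 4)), c(1, 0))$pp, 1)
  expect_equal(projected_precision(diag(c(1, 4)), c(0, 1))$pp, 0.5)
  # isotropic: PP = 1/sigma for any direction
  u <- c(1, 2, 2) / 3
  expect_equal(projected_precision(diag(3) * 9, u)$pp, 1 / 3)

  set.seed(20)
  A <- matrix(rnorm(25), 5)
  S <- crossprod(A) + diag(5)
  d <- rnorm(5)
  pr <- projected_precision(S, d / sqrt(sum(d^2)))
  expect_equal(sum(pr$cos2), 1, tolerance = 1e-10)
  expect_gte(pr$pp^2, 1 / max(pr$eigenvalues) - 1e-12)
  expect_lte(pr$pp^2, 1 / min(pr$eigenvalues) + 1e-12)
  # equivalent quadratic form u' S^-1 u
  uu <- d / sqrt(sum(d^2))
  expect_equal(pr$pp, sqrt(drop(t(uu) %*% solve(S) %*% uu)),
               tolerance = 1e-10)
  expect_error(projected_precision(matrix(c(1, NA, NA, 1), 2), c(1, 0)),
               class = "wmdecode_input_error")
})

test_that("theoretical accuracy is the normal CDF of half the discriminability", {
  expect_equal(theoretical_accuracy(0, 1), 0.5)
  expect_equal(theoretical_accuracy(2, 1), pnorm(1), tolerance = 1e-12)
  expect_equal(theoretical_accuracy(2, 3), pnorm(3), tolerance = 1e-12)
  zs <- seq(0.1, 3, length.out = 10)
  vals <- vapply(zs, function(z) theoretical_accuracy(2 * z, 1), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals >= 0.5 & vals <= 1))
})

test_that("DPt is invariant to unit permutation and global rate rescaling", {
  set.seed(21)
  n <- 120
  x <- cbind(rnorm(n, rep(c(0, 2), each = n / 2)),
             rnorm(n, rep(c(1, 2.5), each = n / 2)),
             rnorm(n))
  colnames(x) <- as.character(1:3)
  y <- rep(c("l", "r"), each = n / 2)
  st <- ensemble_popcode(x, y, seed = 9)
  perm <- ensemble_popcode(x[, c(3, 1, 2)], y, seed = 9)
  expect_equal(perm$dpt, st$dpt, tolerance = 1e-10)
  scaled <- ensemble_popcode(x * 7, y, seed = 9)
  expect_equal(scaled$ps, st$ps * 7, tolerance = 1e-10)
  expect_equal(scaled$pp, st$pp / 7, tolerance = 1e-10)
  expect_equal(scaled$dpt, st$dpt, tolerance = 1e-10)
})

test_that("empirical LDA accuracy matches intuition at the extremes", {
  set.seed(22)
  n <- 60
  y <- rep(c("l", "r"), each = n)
  sep <- cbind(ifelse(y == "l", 0, 50) + rnorm(2 * n),
               rnorm(2 * n))
  expect_equal(empirical_accuracy(sep, y, seed = 2)$accuracy, 1)
  expect_error(empirical_accuracy(sep, rep(c("a", "b", "c"), 40)),
               class = "wmdecode_input_error")
})

test_that("the shrinkage-LDA rule agrees with MASS::lda when shrinkage vanishes", {
  set.seed(23)
  n <- 400
  mu <- c(0.8, -0.5, 0.3)
  # genuinely correlated covariance: off-diagonal signal dominates its
  # estimation noise, so the analytic shrinkage weight goes to zero
  S <- matrix(0.5, 3, 3); diag(S) <- 1
  L <- chol(S)
  xa <- matrix(rnorm(n * 3), ncol = 3) %*% L
  xb <- sweep(matrix(rnorm(n * 3), ncol = 3) %*% L, 2, mu, "+")
  rule <- wmdecode:::lda_rule(xa, xb)
  expect_lt(rule$lambda, 0.1)
  xt <- matrix(rnorm(200 * 3), ncol = 3)
  mine <- ifelse(xt %*% rule$w - rule$c0 > 0, "a", "b")
  ref <- MASS::lda(rbind(xa, xb),
                   grouping = rep(c("a", "b"), each = n),
                   prior = c(0.5, 0.5))
  theirs <- as.character(predict(ref, xt)$class)
  expect_gte(mean(mine == theirs), 0.98)
})

test_that("DPe does not systematically beat DPt on Gaussian data", {
  set.seed(24)
  res <- purrr::map_dfr(1:6, function(i) {
    p <- 3
    d <- rnorm(p, 0, 0.6)
    xa <- matrix(rnorm(1000 * p), ncol = p)
    xb <- sweep(matrix(rnorm(1000 * p), ncol = p), 2, d, "+")
    st <- ensemble_popcode(rbind(xa, xb),
                           rep(c("a", "b"), each = 1000), seed = i)
    tibble::tibble(dpe = st$dpe, dpt = st$dpt)
  })
  expect_true(all(res$dpe <= res$dpt + 0.03))
})

test_that("DPe converges to DPt on large equal-covariance samples", {
  set.seed(25)
  p <- 3
  d <- c(0.35, -0.2, 0.25)
  xa <- matrix(rnorm(2000 * p), ncol = p)
  xb <- sweep(matrix(rnorm(2000 * p), ncol = p), 2, d, "+")
  st <- ensemble_popcode(rbind(xa, xb), rep(c("a", "b"), each = 2000),
                         seed = 3)
  expect_lt(abs(st$dpe - st$dpt), 0.02)
})

test_that("random ensemble sweeps exhaust small combinatorial spaces", {
  rates <- fixture_delay_rates() |>
    dplyr::filter(unit_id <= 4)
  sw <- random_ensemble_sweep(rates, sizes = 3, n_ensembles = 1000,
                              min_rate = 0, k_folds = 4, seed = 6)
  per_period <- sw |> dplyr::count(period)
  expect_true(all(per_period$n == choose(4, 3)))
  keys <- sw |>
    dplyr::filter(period == "pre") |>
    dplyr::pull(unit_ids) |>
    purrr::map_chr(paste, collapse = "-")
  expect_equal(length(unique(keys)), choose(4, 3))  # de-duplicated

  sw2 <- random_ensemble_sweep(rates, sizes = 3, n_ensembles = 1000,
                               min_rate = 0, k_folds = 4, seed = 6)
  expect_identical(sw$unit_ids, sw2$unit_ids)  # same seed, same draws
  expect_warning(
    random_ensemble_sweep(rates, sizes = 5, n_ensembles = 10,
                          min_rate = 0, k_folds = 4, seed = 6),
    regexp = "eligible")
})

test_that("top-quartile flags mark the intended fraction per size and period", {
  rates <- fixture_delay_rates()
  sw <- random_ensemble_sweep(rates, sizes = 2, n_ensembles = 40,
                              k_folds = 4, seed = 8)
  frac <- sw |>
    dplyr::group_by(period) |>
    dplyr::summarise(f = mean(top75), .groups = "drop")
  expect_true(all(frac$f >= 0.25 & frac$f <= 0.5))  # ties can exceed 1/4
})
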