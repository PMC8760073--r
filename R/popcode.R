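# Decomposition of binary decodability into population signal (PS) and
# projected precision (PP), the theoretical accuracy DPt, and its
# empirical counterpart DPe from shrinkage-regularized LDA on random
# small ensembles.

#' Population signal
#'
#' The population signal is the Euclidean norm of the vector of per-unit
#' mean-rate differences between the two classes,
#' `PS = |Delta f|`, with unit direction `u = Delta f / |Delta f|`. It
#' quantifies stimulus-specific modulation of the population response.
#'
#' @param rates_a,rates_b Trial-by-unit rate matrices for the two classes
#'   (same columns).
#' @return List with `delta_f`, `ps`, `u` (`u` is `NA` when `PS = 0`).
#' @export
population_signal <- function(rates_a, rates_b) {
  stopifnot(ncol(rates_a) == ncol(rates_b),
            nrow(rates_a) >= 2, nrow(rates_b) >= 2)
  delta_f <- colMeans(rates_a) - colMeans(rates_b)
  ps <- sqrt(sum(delta_f^2))
  u <- if (ps > 0) delta_f / ps else rep(NA_real_, length(delta_f))
  list(delta_f = delta_f, ps = ps, u = u)
}

#' Projected precision
#'
#' Eigendecomposes the within-class covariance `Sigma` and accumulates the
#' squared cosines of the angles between each eigenvector and the signal
#' direction, inversely weighted by the eigenvalues:
#' `PP = sqrt(sum_i cos^2(theta_i) / sigma_i^2)`. It quantifies
#' trial-to-trial reliability of the population response along the signal
#' direction (equivalently `sqrt(u' Sigma^-1 u)`).
#'
#' @param sigma Symmetric positive-definite covariance matrix.
#' @param u Unit vector along the population signal.
#' @return List with `pp`, `eigenvalues`, `cos2` (squared cosines, which
#'   sum to 1 over the orthonormal eigenbasis).
#' @export
projected_precision <- function(sigma, u) {
  if (any(!is.finite(sigma))) {
    abort("Covariance contains non-finite entries.",
          class = "wmdecode_input_error")
  }
  stopifnot(nrow(sigma) == length(u))
  eig <- eigen(sigma, symmetric = TRUE)
  cosv <- drop(crossprod(eig$vectors, u))
  cos2 <- cosv^2
  list(pp = sqrt(sum(cos2 / eig$values)),
       eigenvalues = eig$values, cos2 = cos2)
}

#' Theoretical decoding accuracy
#'
#' `DPt = Phi(PS * PP / 2)` where `Phi` is the standard normal cumulative
#' distribution function: the accuracy of the optimal linear readout of
#' two equal-covariance Gaussian response classes separated by `PS` along
#' the signal direction with projected precision `PP`.
#'
#' @param ps Population signal (`>= 0`).
#' @param pp Projected precision (`> 0`); ignored when `ps = 0`.
#' @return Accuracy in `[0.5, 1]`; `0.5` iff `ps = 0`.
#' @export
theoretical_accuracy <- function(ps, pp) {
  stopifnot(ps >= 0)
  if (ps == 0) return(0.5)
  pnorm(ps * pp / 2)
}

# Pooled within-class covariance with analytic shrinkage toward its
# diagonal (Schafer-Strimmer style weight on off-diagonal entries).
shrinkage_covariance <- function(rates_a, rates_b) {
  xa <- sweep(rates_a, 2, colMeans(rates_a))
  xb <- sweep(rates_b, 2, colMeans(rates_b))
  xc <- rbind(xa, xb)
  n <- nrow(xc)
  s <- crossprod(xc) / (n - 2)  # two class means estimated
  p <- ncol(xc)
  if (p == 1) return(list(sigma = s, lambda = 0))

  # variance of off-diagonal covariance estimates
  var_s <- matrix(0, p, p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      w <- xc[, i] * xc[, j]
      var_s[i, j] <- n / (n - 1)^3 * sum((w - mean(w))^2)
    }
  }
  off2 <- sum(s[upper.tri(s)]^2)
  lambda <- if (off2 > 0) min(1, max(0, sum(var_s[upper.tri(var_s)]) / off2))
            else 1
  sigma <- s
  sigma[upper.tri(sigma)] <- (1 - lambda) * s[upper.tri(s)]
  sigma[lower.tri(sigma)] <- t(sigma)[lower.tri(sigma)]
  list(sigma = sigma, lambda = lambda)
}

# Shrinkage-LDA binary rule: w = Sigma^-1 delta_f, midpoint threshold.
lda_rule <- function(rates_a, rates_b) {
  sig <- shrinkage_covariance(rates_a, rates_b)
  mu_a <- colMeans(rates_a)
  mu_b <- colMeans(rates_b)
  w <- solve(sig$sigma, mu_a - mu_b)
  c0 <- sum(w * (mu_a + mu_b)) / 2
  list(w = w, c0 = c0, sigma = sig$sigma, lambda = sig$lambda)
}

#' Empirical decoding accuracy (shrinkage-regularized LDA)
#'
#' Cross-validated accuracy of a linear discriminant with a pooled
#' within-class covariance shrunk toward its diagonal by an analytic
#' weight; classes are balanced by subsampling beforehand. This is the
#' empirical counterpart `DPe` of [theoretical_accuracy()].
#'
#' @param features Trial-by-unit matrix or long rates tibble.
#' @param labels Binary class labels in row order.
#' @param k_folds Cross-validation folds.
#' @param seed Seed for balancing and fold assignment.
#' @return List of class `lda_decoding`: `accuracy`, `k_folds`, `classes`,
#'   `n_per_class`.
#' @export
empirical_accuracy <- function(features, labels, k_folds = 5, seed = 1) {
  if (is.data.frame(features)) features <- rates_to_matrix(features)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2) {
    abort("Empirical decoding is binary; got a different class count.",
          class = "wmdecode_input_error")
  }
  n_min <- min(table(labels))
  if (n_min < k_folds) {
    abort(sprintf("Class below the fold count: %s",
                  names(which.min(table(labels)))),
          class = "wmdecode_input_error")
  }
  with_seed_(seed, {
    keep <- unlist(lapply(classes, function(cl) {
      sample(which(labels == cl), n_min)
    }))
    x <- features[keep, , drop = FALSE]
    y <- labels[keep]
    fold <- stratified_folds(y, k_folds)
    hits <- 0L
    for (f in seq_len(k_folds)) {
      tr <- fold != f
      xa <- x[tr & y == classes[1], , drop = FALSE]
      xb <- x[tr & y == classes[2], , drop = FALSE]
      rule <- lda_rule(xa, xb)
      score <- x[!tr, , drop = FALSE] %*% rule$w - rule$c0
      pred <- ifelse(score > 0, classes[1], classes[2])
      hits <- hits + sum(pred == y[!tr])
    }
    structure(list(accuracy = hits / length(y), k_folds = k_folds,
                   classes = classes, n_per_class = n_min),
              class = "lda_decoding")
  })
}

#' Population-code statistics for one ensemble
#'
#' Computes the full decomposition for a binary contrast on one set of
#' units: `delta_f`, `PS`, the shrunk within-class covariance and its
#' eigenstructure, `PP`, `DPt = Phi(PS * PP / 2)` and the cross-validated
#' LDA accuracy `DPe`. The same regularized covariance feeds both the
#' discriminant and `PP`, and class means are taken on the same balanced
#' subsample, so the theoretical and empirical accuracies are directly
#' comparable.
#'
#' @param features Trial-by-unit matrix or long rates tibble.
#' @param labels Binary labels in row order.
#' @param k_folds Folds for `DPe`.
#' @param seed Seed (balancing + folds).
#' @return Object of class `popcode_stats`: list with `unit_ids`,
#'   `delta_f`, `ps`, `u`, `sigma`, `lambda`, `eigenvalues`, `cos2`, `pp`,
#'   `dpt`, `dpe`, `n_per_class`.
#' @export
ensemble_popcode <- function(features, labels, k_folds = 5, seed = 1) {
  if (is.data.frame(features)) features <- rates_to_matrix(features)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  stopifnot(length(classes) == 2)
  n_min <- min(table(labels))
  bal <- with_seed_(derive_seed(seed, "popcode-balance"), {
    unlist(lapply(classes, function(cl) sample(which(labels == cl), n_min)))
  })
  x <- features[bal, , drop = FALSE]
  y <- labels[bal]
  xa <- x[y == classes[1], , drop = FALSE]
  xb <- x[y == classes[2], , drop = FALSE]

  sig <- shrinkage_covariance(xa, xb)
  psig <- population_signal(xa, xb)
  if (psig$ps == 0) {
    pp <- NA_real_
    eigenvalues <- eigen(sig$sigma, symmetric = TRUE,
                         only.values = TRUE)$values
    cos2 <- rep(NA_real_, length(eigenvalues))
    dpt <- 0.5
  } else {
    prec <- projected_precision(sig$sigma, psig$u)
    pp <- prec$pp
    eigenvalues <- prec$eigenvalues
    cos2 <- prec$cos2
    dpt <- theoretical_accuracy(psig$ps, pp)
  }
  dpe <- empirical_accuracy(x, y, k_folds = k_folds,
                            seed = derive_seed(seed, "popcode-dpe"))$accuracy

  structure(
    list(unit_ids = colnames(features) %||% as.character(seq_len(ncol(features))),
         delta_f = psig$delta_f, ps = psig$ps, u = psig$u,
         sigma = sig$sigma, lambda = sig$lambda,
         eigenvalues = eigenvalues, cos2 = cos2,
         pp = pp, dpt = dpt, dpe = dpe, n_per_class = n_min),
    class = "popcode_stats"
  )
}

#' @export
print.popcode_stats <- function(x, ...) {
  cat(sprintf("<popcode_stats> %d units: PS=%.3f PP=%s DPt=%.3f DPe=%.3f\n",
              length(x$unit_ids), x$ps,
              ifelse(is.na(x$pp), "NA", sprintf("%.3f", x$pp)),
              x$dpt, x$dpe))
  invisible(x)
}

#' @rdname ensemble_popcode
#' @param x A `popcode_stats` object.
#' @param ... Unused.
#' @export
glance.popcode_stats <- function(x, ...) {
  tibble(n_units = length(x$unit_ids), ps = x$ps, pp = x$pp,
         dpt = x$dpt, dpe = x$dpe, lambda = x$lambda,
         n_per_class = x$n_per_class)
}

#' Random-ensemble sweep of population-code statistics
#'
#' Draws random ensembles of the requested sizes from the eligible units
#' (mean rate above `min_rate`), computes [ensemble_popcode()] per
#' ensemble and period for the binary left-vs-right contrast (center
#' column excluded), and flags the top quartile by empirical accuracy
#' within each size and period.
#'
#' @param rates Long tibble `trial_id`, `unit_id`, `rate`, `target_side`,
#'   `period` (e.g. from [session_epoch_rates()]).
#' @param sizes Ensemble sizes to draw.
#' @param n_ensembles Ensembles per size (duplicates are avoided; when the
#'   combinatorial space is smaller, all distinct ensembles are used).
#' @param min_rate Unit inclusion threshold on grand mean rate (Hz).
#' @param k_folds Folds for `DPe`.
#' @param top_quantile Quantile defining top ensembles (0.75).
#' @param seed Master seed.
#' @return Tibble `ensemble_id`, `size`, `period`, `ps`, `pp`, `dpt`,
#'   `dpe`, `lambda`, `top75` plus a `unit_ids` list-column.
#' @export
random_ensemble_sweep <- function(rates, sizes = c(2, 3, 5),
                                  n_ensembles = 1000, min_rate = 0.5,
                                  k_folds = 5, top_quantile = 0.75,
                                  seed = 1) {
  eligible <- rates |>
    group_by(unit_id) |>
    summarise(mean_rate = mean(rate), .groups = "drop") |>
    filter(mean_rate > min_rate) |>
    pull(unit_id)
  lateral <- rates |> filter(target_side %in% c("left", "right"))
  periods <- unique(lateral$period)

  mats <- lapply(setNames(periods, periods), function(p) {
    sub <- lateral |> filter(period == p)
    m <- rates_to_matrix(sub |> select(trial_id, unit_id, rate))
    labs <- sub |> distinct(trial_id, target_side) |> arrange(trial_id)
    list(m = m, labels = labs$target_side)
  })

  rows <- purrr::map_dfr(sizes, function(sz) {
    if (length(eligible) < sz) {
      warn(sprintf("Size %d skipped: only %d eligible units.",
                   sz, length(eligible)))
      return(tibble())
    }
    n_comb <- choose(length(eligible), sz)
    draws <- with_seed_(derive_seed(seed, "ensemble-draw", sz), {
      if (n_comb <= n_ensembles) {
        asplit(utils::combn(eligible, sz), 2)
      } else {
        seen <- character(0)
        out <- list()
        while (length(out) < n_ensembles) {
          e <- sort(sample(eligible, sz))
          key <- paste(e, collapse = "-")
          if (!key %in% seen) {
            seen <- c(seen, key)
            out[[length(out) + 1]] <- e
          }
        }
        out
      }
    })
    purrr::imap_dfr(draws, function(ens, i) {
      purrr::map_dfr(periods, function(p) {
        cols <- as.character(ens)
        st <- ensemble_popcode(
          mats[[p]]$m[, cols, drop = FALSE], mats[[p]]$labels,
          k_folds = k_folds,
          seed = derive_seed(seed, sprintf("popcode-%d-%s", sz, p), i))
        tibble(ensemble_id = sprintf("s%d_e%d", sz, i), size = sz,
               period = p, ps = st$ps, pp = st$pp, dpt = st$dpt,
               dpe = st$dpe, lambda = st$lambda,
               unit_ids = list(unname(ens)))
      })
    })
  })
  if (nrow(rows) == 0) {
    return(tibble(ensemble_id = character(), size = integer(),
                  period = character(), ps = numeric(), pp = numeric(),
                  dpt = numeric(), dpe = numeric(), lambda = numeric(),
                  unit_ids = list(), top75 = logical()))
  }
  rows |>
    group_by(size, period) |>
    mutate(top75 = dpe >= quantile(dpe, top_quantile)) |>
    ungroup()
}
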