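# Cross-validated multiclass decoding of target location from spike
# counts: class balancing, z-scored features, linear SVM, greedy ensemble
# construction and label-shuffle nulls.

# trial x unit rate matrix from long rates
rates_to_matrix <- function(rates) {
  wide <- rates |>
    select(trial_id, unit_id, rate) |>
    tidyr::pivot_wider(names_from = unit_id, values_from = rate) |>
    arrange(trial_id)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$trial_id
  m
}

zscore_train_apply <- function(train, test) {
  mu <- colMeans(train)
  s <- apply(train, 2, sd)
  s[s == 0 | is.na(s)] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, s, "/"),
       test = sweep(sweep(test, 2, mu), 2, s, "/"))
}

stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

svm_fit_predict <- function(xtr, ytr, xte, cost) {
  fit <- e1071::svm(x = xtr, y = factor(ytr), kernel = "linear",
                    cost = cost, scale = FALSE)
  as.character(predict(fit, xte))
}

tune_cost <- function(x, y, cost_grid, k_inner = 3) {
  acc <- vapply(cost_grid, function(cst) {
    fold <- stratified_folds(y, k_inner)
    hits <- 0L
    for (f in seq_len(k_inner)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2) return(0)
      pred <- svm_fit_predict(x[tr, , drop = FALSE], y[tr],
                              x[!tr, , drop = FALSE], cst)
      hits <- hits + sum(pred == y[!tr])
    }
    hits / length(y)
  }, numeric(1))
  cost_grid[which.max(acc)]  # ties -> smallest cost
}

#' Cross-validated linear-SVM decoding with class balancing
#'
#' Decodes class labels from trial spike-count features using a linear
#' support vector machine with k-fold cross-validation. Classes are first
#' balanced by subsampling without replacement to the minority-class
#' count; the balancing is repeated `n_balance` times and accuracy
#' averaged. Features are z-score normalized with means and SDs estimated
#' on the training folds only. The SVM penalty parameter is selected per
#' training fold by an inner 3-fold search over `cost_grid` unless a
#' single fixed `cost` is supplied.
#'
#' @param features Trial-by-unit numeric matrix (rownames = trial ids) or
#'   a long rates tibble (`trial_id`, `unit_id`, `rate`).
#' @param labels Class label per trial (in matrix row order).
#' @param k_folds Cross-validation folds (5 for the 3-class direction
#'   decoder; 4 for the 9-location variant).
#' @param n_balance Balancing subsample repetitions.
#' @param cost Fixed SVM cost; `NULL` selects it by inner cross-validation.
#' @param cost_grid Log-spaced candidate costs for the inner search.
#' @param seed Seed for balancing and fold assignment.
#' @return Object of class `decoding_result`: list with `accuracy` (mean
#'   over repeats), `repeat_accuracies`, `confusion` (long tibble of
#'   summed test counts), `n_per_class`, `k_folds`, `classes`.
#' @export
decode_cv <- function(features, labels, k_folds = 5, n_balance = 20,
                      cost = NULL, cost_grid = 10^seq(-2, 2), seed = 1) {
  if (is.data.frame(features)) features <- rates_to_matrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(features) == length(labels))
  classes <- sort(unique(labels))
  if (length(classes) < 2) {
    abort("Decoding requires at least two classes.",
          class = "wmdecode_input_error")
  }
  n_min <- min(table(labels))
  if (n_min < k_folds) {
    small <- names(which(table(labels) < k_folds))
    abort(sprintf("Class(es) below the fold count (%d): %s",
                  k_folds, paste(small, collapse = ", ")),
          class = "wmdecode_input_error")
  }

  with_seed_(seed, {
    rep_acc <- numeric(n_balance)
    conf <- matrix(0L, length(classes), length(classes),
                   dimnames = list(true = classes, predicted = classes))
    for (b in seq_len(n_balance)) {
      keep <- unlist(lapply(classes, function(cl) {
        sample(which(labels == cl), n_min)
      }))
      xb <- features[keep, , drop = FALSE]
      yb <- labels[keep]
      fold <- stratified_folds(yb, k_folds)
      hits <- 0L
      for (f in seq_len(k_folds)) {
        tr <- fold != f
        z <- zscore_train_apply(xb[tr, , drop = FALSE],
                                xb[!tr, , drop = FALSE])
        cst <- cost %||% tune_cost(z$train, yb[tr], cost_grid)
        pred <- svm_fit_predict(z$train, yb[tr], z$test, cst)
        hits <- hits + sum(pred == yb[!tr])
        for (i in seq_along(pred)) {
          conf[yb[!tr][i], pred[i]] <- conf[yb[!tr][i], pred[i]] + 1L
        }
      }
      rep_acc[b] <- hits / length(yb)
    }
    structure(
      list(accuracy = mean(rep_acc), repeat_accuracies = rep_acc,
           confusion = as_tibble(as.data.frame.table(
             conf, responseName = "count")),
           n_per_class = n_min, k_folds = k_folds, classes = classes),
      class = "decoding_result"
    )
  })
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf(
    "<decoding_result> %d classes, %d-fold CV, %d balancing repeat(s)\n",
    length(x$classes), x$k_folds, length(x$repeat_accuracies)))
  cat(sprintf("  accuracy: %.3f (chance %.3f)\n", x$accuracy,
              1 / length(x$classes)))
  invisible(x)
}

#' @rdname decode_cv
#' @param x A `decoding_result`.
#' @param ... Unused.
#' @export
tidy.decoding_result <- function(x, ...) {
  tibble(repeat_id = seq_along(x$repeat_accuracies),
         accuracy = x$repeat_accuracies)
}

#' @rdname decode_cv
#' @export
glance.decoding_result <- function(x, ...) {
  tibble(accuracy = x$accuracy, n_classes = length(x$classes),
         chance = 1 / length(x$classes), k_folds = x$k_folds,
         n_per_class = x$n_per_class,
         n_repeats = length(x$repeat_accuracies))
}

#' Greedy ensemble construction
#'
#' Builds a decoding ensemble by forward selection: the unit with the
#' highest individual cross-validated accuracy is selected first, then at
#' each step every remaining unit is tried in combination with the
#' current ensemble and the best-performing augmentation kept, up to
#' `max_size` units (accuracy plateaus around 16). Ties are broken toward
#' the lowest unit id. The size-k ensemble is by construction a prefix of
#' the size-(k+1) ensemble.
#'
#' @inheritParams decode_cv
#' @param max_size Maximum ensemble size.
#' @return Tibble of class `greedy_ensemble` with one row per size:
#'   `size`, `unit_added`, `accuracy` and the ordered `unit_ids`
#'   list-column.
#' @export
greedy_ensemble <- function(features, labels, max_size = 16, k_folds = 5,
                            n_balance = 20, cost = NULL,
                            cost_grid = 10^seq(-2, 2), seed = 1) {
  if (is.data.frame(features)) features <- rates_to_matrix(features)
  unit_ids <- colnames(features) %||% as.character(seq_len(ncol(features)))
  colnames(features) <- unit_ids
  if (ncol(features) < max_size) {
    warn(sprintf(
      "Only %d candidate units available; growing ensemble to %d.",
      ncol(features), ncol(features)))
    max_size <- ncol(features)
  }
  chosen <- character(0)
  rows <- vector("list", max_size)
  for (s in seq_len(max_size)) {
    remaining <- setdiff(unit_ids, chosen)
    accs <- vapply(remaining, function(u) {
      decode_cv(features[, c(chosen, u), drop = FALSE], labels,
                k_folds = k_folds, n_balance = n_balance, cost = cost,
                cost_grid = cost_grid,
                seed = derive_seed(seed, paste0("greedy-", s)))$accuracy
    }, numeric(1))
    # ties: lowest unit id (numeric order when ids are numeric)
    best_acc <- max(accs)
    cand <- remaining[accs == best_acc]
    pick <- cand[order(suppressWarnings(as.numeric(cand)), cand)][1]
    chosen <- c(chosen, pick)
    rows[[s]] <- tibble(size = s, unit_added = pick, accuracy = best_acc,
                        unit_ids = list(chosen))
  }
  out <- bind_rows(rows)
  class(out) <- c("greedy_ensemble", class(out))
  out
}

#' Label-shuffle null distribution for a decoder
#'
#' Repeats the cross-validated decoding with class labels randomly
#' permuted (all other data features unaltered), `n_shuffle` times with
#' `n_balance` balancing subsamples each. A session whose pooled null
#' accuracy is significantly above the binomial chance level is flagged
#' for exclusion.
#'
#' @inheritParams decode_cv
#' @param n_shuffle Number of label permutations.
#' @param flag_alpha One-sided binomial level for the above-chance flag.
#' @return Tibble `shuffle`, `accuracy` with attributes `chance`,
#'   `flagged` (logical), `flag_p`.
#' @export
shuffle_null <- function(features, labels, n_shuffle = 10, k_folds = 5,
                         n_balance = 20, cost = NULL,
                         cost_grid = 10^seq(-2, 2), seed = 1,
                         flag_alpha = 0.05) {
  if (is.data.frame(features)) features <- rates_to_matrix(features)
  labels <- as.character(labels)
  res <- purrr::map_dfr(seq_len(n_shuffle), function(i) {
    perm <- with_seed_(derive_seed(seed, "shuffle-perm", i),
                       sample(labels))
    r <- decode_cv(features, perm, k_folds = k_folds,
                   n_balance = n_balance, cost = cost,
                   cost_grid = cost_grid,
                   seed = derive_seed(seed, "shuffle-cv", i))
    tibble(shuffle = i, accuracy = r$accuracy,
           n_per_class = r$n_per_class, n_classes = length(r$classes))
  })
  chance <- 1 / res$n_classes[1]
  # pooled correct count over all shuffles vs binomial chance
  n_obs <- res$n_per_class[1] * res$n_classes[1] * n_shuffle
  bt <- binom.test(round(mean(res$accuracy) * n_obs), n_obs, p = chance,
                   alternative = "greater")
  out <- res |> select(shuffle, accuracy)
  attr(out, "chance") <- chance
  attr(out, "flagged") <- bt$p.value < flag_alpha
  attr(out, "flag_p") <- bt$p.value
  out
}

#' Target-direction labels for decoding
#'
#' Pools the nine target locations by grid column into left/center/right
#' (3-class decoding) or keeps the nine locations (9-class variant).
#'
#' @param trials Trials table.
#' @param scheme `"column"` (3 classes) or `"location"` (9 classes).
#' @return Character vector of labels in trial order.
#' @export
decoding_labels <- function(trials, scheme = c("column", "location")) {
  scheme <- match.arg(scheme)
  if (scheme == "column") trials$target_column
  else as.character(trials$target_location)
}
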