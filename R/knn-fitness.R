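# Wrapper fitness: KNN classification restricted to a feature mask, combined
# with subset size as
#     fitness = w * error + (1 - w) * |s| / d,
# minimized. The KNN is written here (rather than wrapped from a library)
# because the contract pins fully deterministic tie rules: distance ties are
# broken by lower train-row index, and vote ties by the class of the single
# nearest neighbour.

#' k-nearest-neighbour prediction on masked features
#'
#' Labels each test row by majority vote of its `k` nearest training rows
#' under Euclidean distance restricted to the columns selected by `mask`.
#' Fully deterministic: distance ties are broken by lower train-row index and
#' (forced) vote ties by the nearest neighbour's class.
#'
#' @param train A data frame with a label column (the training part).
#' @param test A data frame with the same feature columns (labels optional).
#' @param k Number of neighbours; a positive odd integer `<= nrow(train)`.
#' @param mask Binary 0/1 vector over the feature columns; `NULL` selects
#'   all features. Must select at least one feature.
#' @param label_col Name of the label column in `train`.
#' @return Integer vector of 0/1 predictions, one per test row.
#' @examples
#' tr <- tibble::tibble(
#'   f1 = c(0, 0, 0, 10, 10, 10), f2 = c(0, 0, 0, 10, 10, 10),
#'   label = c(0, 0, 0, 1, 1, 1)
#' )
#' te <- tibble::tibble(f1 = 9, f2 = 9)
#' knn_predict(tr, te, k = 1)
#' @export
knn_predict <- function(train, test, k = 5L, mask = NULL, label_col = "label") {
  parts <- ft_parts(train, label_col)
  feat <- parts$feature_names
  missing_cols <- setdiff(feat, names(test))
  if (length(missing_cols) > 0L) {
    abort(sprintf(
      "Test data lacks feature column(s): %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  xt <- as.matrix(as.data.frame(test)[feat])
  if (is.null(mask)) mask <- rep(1L, length(feat))
  check_mask(mask, length(feat))
  if (sum(mask) < 1L) abort("`mask` must select at least one feature.")
  k <- as.integer(k)
  if (k < 1L || k %% 2L == 0L) abort("`k` must be a positive odd integer.")
  if (k > nrow(parts$x)) abort("`k` exceeds the number of training rows.")
  sel <- which(mask == 1L)
  knn_predict_matrix(
    parts$x[, sel, drop = FALSE], parts$y,
    xt[, sel, drop = FALSE], k
  )
}

# Matrix core shared by the public API and the optimizer's evaluator.
knn_predict_matrix <- function(x_train, y_train, x_test, k) {
  n_tr <- nrow(x_train)
  # squared Euclidean distances, test rows x train rows
  d2 <- outer(rowSums(x_test^2), rowSums(x_train^2), "+") -
    2 * tcrossprod(x_test, x_train)
  preds <- integer(nrow(x_test))
  for (i in seq_len(nrow(x_test))) {
    ord <- order(d2[i, ]) # stable: equal distances keep train-row order
    nb <- y_train[ord[seq_len(k)]]
    pos <- sum(nb == 1L)
    preds[i] <- if (pos * 2L > k) {
      1L
    } else if (pos * 2L < k) {
      0L
    } else {
      y_train[ord[1L]] # vote tie (even k, if forced): nearest neighbour
    }
  }
  preds
}

check_mask <- function(mask, d) {
  if (length(mask) != d) {
    abort(sprintf("Mask length %d does not match %d features.", length(mask), d))
  }
  if (!all(mask %in% c(0L, 1L))) abort("Mask entries must be 0 or 1.")
  invisible(TRUE)
}

#' Classification error and confusion counts
#'
#' The error alpha is `1 - accuracy = (FP + FN) / (TP + TN + FP + FN)`, with
#' label 1 the positive class.
#'
#' @param predictions Integer 0/1 predictions.
#' @param labels Integer 0/1 reference labels of the same length.
#' @return A list with `alpha` and `counts` (named vector TP, TN, FP, FN).
#' @export
classification_error <- function(predictions, labels) {
  if (length(predictions) == 0L) abort("Empty predictions.")
  if (length(predictions) != length(labels)) {
    abort("`predictions` and `labels` must have equal length.")
  }
  tp <- sum(predictions == 1L & labels == 1L)
  tn <- sum(predictions == 0L & labels == 0L)
  fp <- sum(predictions == 1L & labels == 0L)
  fn <- sum(predictions == 0L & labels == 1L)
  list(
    alpha = (fp + fn) / (tp + tn + fp + fn),
    counts = c(TP = tp, TN = tn, FP = fp, FN = fn)
  )
}

#' Precision and recall from confusion counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`. A zero
#' denominator yields `NA` (undefined), never 0.
#'
#' @param counts Named vector or list with TP, TN, FP, FN.
#' @return A list with `precision` and `recall`.
#' @export
precision_recall <- function(counts) {
  tp <- counts[["TP"]]
  fp <- counts[["FP"]]
  fn <- counts[["FN"]]
  list(
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_
  )
}

#' Wrapper fitness from its components
#'
#' The scalar being minimized: `w * alpha + (1 - w) * selected_count / d`,
#' combining the classification error `alpha` with the relative subset size.
#'
#' @param alpha Classification error in `[0, 1]`.
#' @param selected_count Number of selected features `|s|`.
#' @param d Total number of features.
#' @param w Weight on the error term, in `[0, 1]`. Default 0.2.
#' @return The fitness value in `[0, 1]`.
#' @examples
#' wrapper_fitness(alpha = 0.5, selected_count = 64, d = 128, w = 0.2)
#' @export
wrapper_fitness <- function(alpha, selected_count, d, w = 0.2) {
  stopifnot(w >= 0, w <= 1, alpha >= 0, alpha <= 1,
            selected_count >= 0, selected_count <= d)
  w * alpha + (1 - w) * selected_count / d
}

new_fitness_value <- function(fitness, alpha, selected_count, w, d,
                              counts = NULL) {
  structure(
    list(
      fitness = fitness, error_alpha = alpha,
      selected_count = as.integer(selected_count), w = w, d = as.integer(d),
      counts = counts
    ),
    class = "fitness_value"
  )
}

#' @export
print.fitness_value <- function(x, ...) {
  cat(sprintf(
    "<fitness_value> fitness = %.6f (w = %g, error = %s, selected %d/%d)\n",
    x$fitness, x$w,
    if (is.na(x$error_alpha)) "undefined" else sprintf("%.6f", x$error_alpha),
    x$selected_count, x$d
  ))
  invisible(x)
}

# Evaluator factory: binds a split (standardized once), KNN settings and w,
# and memoizes by mask so repeated visits to the same subset are free. Every
# call (cached or not) counts toward `n_evaluations`, and every evaluated
# mask is archived for the optimizer's all-time top-3.
make_mask_evaluator <- function(split, k = 5L, w = 0.2, standardize = TRUE) {
  stopifnot(inherits(split, "split_pair"))
  if (w < 0 || w > 1) abort("`w` must be in [0, 1].")
  if (standardize) split <- standardize_features(split)
  tr <- ft_parts(split$train, split$label_col, require_both_classes = TRUE)
  te <- ft_parts(split$test, split$label_col)
  d <- length(tr$feature_names)
  k <- as.integer(k)
  if (k < 1L || k %% 2L == 0L) abort("`k` must be a positive odd integer.")
  if (k > nrow(tr$x)) abort("`k` exceeds the number of training rows.")
  cache <- new.env(parent = emptyenv())
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  archive <- new.env(parent = emptyenv())
  archive$keys <- character(0)
  archive$fitness <- numeric(0)
  archive$sizes <- integer(0)
  archive$masks <- list()
  evaluate <- function(mask) {
    check_mask(mask, d)
    counter$n <- counter$n + 1L
    key <- paste(mask, collapse = "")
    hit <- get0(key, envir = cache, inherits = FALSE)
    if (!is.null(hit)) {
      return(hit)
    }
    s <- sum(mask)
    if (s == 0L) {
      fv <- new_fitness_value(1.0, NA_real_, 0L, w, d)
    } else {
      sel <- which(mask == 1L)
      preds <- knn_predict_matrix(
        tr$x[, sel, drop = FALSE], tr$y, te$x[, sel, drop = FALSE], k
      )
      err <- classification_error(preds, te$y)
      fv <- new_fitness_value(
        wrapper_fitness(err$alpha, s, d, w),
        err$alpha, s, w, d, err$counts
      )
      archive$keys <- c(archive$keys, key)
      archive$fitness <- c(archive$fitness, fv$fitness)
      archive$sizes <- c(archive$sizes, s)
      archive$masks[[length(archive$masks) + 1L]] <- as.integer(mask)
    }
    assign(key, fv, envir = cache)
    fv
  }
  list(
    evaluate = evaluate,
    # cache lookup that does not count as a fitness evaluation
    peek = function(mask) {
      get0(paste(mask, collapse = ""), envir = cache, inherits = FALSE)
    },
    d = d,
    k = k,
    w = w,
    n_evaluations = function() counter$n,
    archive = archive
  )
}

# Best entries of an evaluator archive, ordered by fitness, then fewer
# selected features, then lexicographically smallest mask.
archive_top <- function(archive, n = 3L) {
  m <- length(archive$keys)
  if (m == 0L) abort("No evaluated masks in archive.")
  ord <- order(archive$fitness, archive$sizes, archive$keys)
  take <- ord[seq_len(min(n, m))]
  # pad by recycling the best if fewer than n distinct masks exist yet
  while (length(take) < n) take <- c(take, take[1L])
  take
}

#' Evaluate one feature mask on a split
#'
#' Computes the wrapper fitness `w * alpha + (1 - w) * |s| / d`, with `alpha`
#' the KNN classification error on the held-out (test) part of `split` and
#' `|s|` the number of selected features. An empty mask is assigned the worst
#' fitness 1.0 with an undefined error.
#'
#' @param mask Binary 0/1 vector over the feature columns.
#' @param split A `split_pair` from [stratified_split()].
#' @param k KNN neighbourhood size (positive odd integer). Default 5.
#' @param w Weight on classification error, in `[0, 1]`. Default 0.2.
#' @param standardize Standardize with training statistics first. Default TRUE.
#' @return A `fitness_value`: list with `fitness`, `error_alpha`,
#'   `selected_count`, `w`, `d` and confusion `counts`.
#' @examples
#' tbl <- sim_feature_table(100, 2, 0, 2, class_separation = 3, seed = 1)$data
#' sp <- stratified_split(tbl, 0.2, seed = 1)
#' evaluate_mask(c(1, 1, 0, 0), sp)
#' @export
evaluate_mask <- function(mask, split, k = 5L, w = 0.2, standardize = TRUE) {
  ev <- make_mask_evaluator(split, k = k, w = w, standardize = standardize)
  ev$evaluate(as.integer(mask))
}

#' Exhaustive feature-subset oracle
#'
#' Enumerates all `2^d - 1` non-empty masks and returns the global minimum of
#' the wrapper fitness — the ground truth any stochastic optimizer can be
#' checked against. Ties are broken by fewer selected features, then by the
#' lexicographically smallest mask. Limited to `d <= 16`.
#'
#' @inheritParams evaluate_mask
#' @return A list with `best_mask`, `best_fitness` (a `fitness_value`) and
#'   `n_masks` evaluated.
#' @export
exhaustive_oracle <- function(split, k = 5L, w = 0.2, standardize = TRUE) {
  ev <- make_mask_evaluator(split, k = k, w = w, standardize = standardize)
  d <- ev$d
  if (d > 16L) abort("Exhaustive oracle limited to d <= 16 features.")
  for (code in seq_len(2^d - 1L)) {
    mask <- as.integer(bitwAnd(bitwShiftR(code, seq_len(d) - 1L), 1L))
    ev$evaluate(mask)
  }
  best <- archive_top(ev$archive, 1L)[1L]
  list(
    best_mask = ev$archive$masks[[best]],
    best_fitness = ev$peek(ev$archive$masks[[best]]),
    n_masks = 2^d - 1L
  )
}
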