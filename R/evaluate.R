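# Multi-run experiment protocol: repeat the selection with consecutive
# seeds, refit the KNN on each run's best mask, and report per-run accuracy,
# precision, recall and subset size with their mean +/- sample SD — the
# usual "mean over five simulations" reporting convention.

#' Mean and sample standard deviation
#'
#' The reporting convention used throughout: arithmetic mean and sample
#' (n - 1) standard deviation.
#'
#' @param x Numeric vector, length >= 2.
#' @return Named numeric vector with `mean` and `sd`.
#' @export
mean_sd <- function(x) {
  stopifnot(length(x) >= 2L)
  c(mean = mean(x), sd = stats::sd(x))
}

#' Repeat a feature-selection experiment over several seeds
#'
#' Runs [ssd_select()] `n_runs` times with seeds `base_seed`,
#' `base_seed + 1`, ... For each run the KNN is refit with the run's best
#' mask on the run's training part and scored on its held-out part, giving
#' accuracy, precision and recall (in percent) plus the selected-feature
#' count. Fully reproducible from `base_seed`.
#'
#' @param data A data frame with a binary label column.
#' @param n_runs Number of simulations (>= 2). Default 5.
#' @param base_seed First seed. Default 1.
#' @param label_col Name of the label column.
#' @param ... Further arguments passed to [ssd_select()].
#' @return An object of class `fs_experiment`: list with `per_run` (tibble:
#'   run, seed, accuracy, precision, recall, n_selected), `summary` (tibble
#'   of mean and sample SD per metric), `seeds` and `fits` (the `ssd_fit`
#'   objects). Use [tidy()], [glance()] and [autoplot()] on it.
#' @export
repeat_experiment <- function(data, n_runs = 5L, base_seed = 1L,
                              label_col = "label", ...) {
  n_runs <- as.integer(n_runs)
  if (n_runs < 2L) abort("`n_runs` must be >= 2.")
  seeds <- base_seed + seq_len(n_runs) - 1L
  fits <- lapply(seeds, function(s) {
    ssd_select(data, label_col = label_col, seed = s, ...)
  })
  rows <- lapply(seq_along(fits), function(i) {
    m <- holdout_metrics(fits[[i]])
    tibble(
      run = i, seed = seeds[i],
      accuracy = 100 * m$accuracy,
      precision = 100 * m$precision,
      recall = 100 * m$recall,
      n_selected = length(fits[[i]]$selected_indices)
    )
  })
  per_run <- dplyr::bind_rows(rows)
  summ <- dplyr::bind_rows(lapply(
    c("accuracy", "precision", "recall", "n_selected"),
    function(col) {
      ms <- mean_sd(per_run[[col]])
      tibble(metric = col, mean = ms[["mean"]], sd = ms[["sd"]])
    }
  ))
  structure(
    list(per_run = per_run, summary = summ, seeds = seeds, fits = fits),
    class = "fs_experiment"
  )
}

# Refit KNN with the best mask on the run's own split and score the
# held-out part.
holdout_metrics <- function(fit) {
  stopifnot(inherits(fit, "ssd_fit"))
  split <- fit$split
  if (fit$config$standardize) split <- standardize_features(split)
  preds <- knn_predict(
    split$train, split$test,
    k = fit$config$k,
    mask = fit$best_mask, label_col = split$label_col
  )
  truth <- ft_parts(split$test, split$label_col)$y
  err <- classification_error(preds, truth)
  pr <- precision_recall(err$counts)
  list(
    accuracy = 1 - err$alpha,
    precision = pr$precision,
    recall = pr$recall,
    counts = err$counts
  )
}

#' @export
print.fs_experiment <- function(x, ...) {
  cat(sprintf("<fs_experiment> %d runs (seeds %s)\n",
              nrow(x$per_run), paste(x$seeds, collapse = ", ")))
  print(x$per_run)
  cat("\nMean +/- sample SD:\n")
  print(x$summary)
  invisible(x)
}

#' Render an experiment as a markdown table
#'
#' One row per simulation plus a final `Mean ± SD` row, mirroring the usual
#' multi-simulation reporting layout.
#'
#' @param x An `fs_experiment`.
#' @return A character vector of markdown lines.
#' @export
experiment_markdown <- function(x) {
  stopifnot(inherits(x, "fs_experiment"))
  hdr <- c(
    "| Simulation | Accuracy (%) | Precision (%) | Recall (%) | #FS |",
    "|---|---|---|---|---|"
  )
  rows <- sprintf(
    "| %d | %.2f | %.2f | %.2f | %d |",
    x$per_run$run, x$per_run$accuracy, x$per_run$precision,
    x$per_run$recall, x$per_run$n_selected
  )
  s <- x$summary
  g <- function(m) s[s$metric == m, ]
  tail_row <- sprintf(
    "| Mean ± SD | %.2f ± %.2f | %.2f ± %.2f | %.2f ± %.2f | %.0f ± %.0f |",
    g("accuracy")$mean, g("accuracy")$sd,
    g("precision")$mean, g("precision")$sd,
    g("recall")$mean, g("recall")$sd,
    g("n_selected")$mean, g("n_selected")$sd
  )
  c(hdr, rows, tail_row)
}

#' Mann-Whitney U test with midrank ties
#'
#' Computes U from rank sums using midranks for ties. For pooled sample
#' sizes `n1 + n2 <= 12` (or `method = "exact"`) the p-value is obtained by
#' complete enumeration of all rank assignments; otherwise a normal
#' approximation with tie correction is used. The reported `U` is the
#' statistic of the first sample.
#'
#' @param xs,ys Numeric vectors, each of length >= 2.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param method `"auto"` (default), `"exact"` or `"normal"`.
#' @return A list with `U`, `p_value` and `method` used.
#' @examples
#' mann_whitney_u(1:5, 6:10)
#' @export
mann_whitney_u <- function(xs, ys,
                           alternative = c("two.sided", "less", "greater"),
                           method = c("auto", "exact", "normal")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  if (length(xs) < 2L || length(ys) < 2L) {
    abort("Each sample must have length >= 2.")
  }
  n1 <- length(xs)
  n2 <- length(ys)
  n <- n1 + n2
  ranks <- rank(c(xs, ys)) # midranks for ties
  u_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (method == "auto") method <- if (n <= 12L) "exact" else "normal"
  mu <- n1 * n2 / 2
  if (method == "exact") {
    combos <- utils::combn(n, n1)
    u_all <- colSums(matrix(ranks[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- switch(alternative,
      two.sided = mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12),
      less = mean(u_all <= u_obs + 1e-12),
      greater = mean(u_all >= u_obs - 1e-12)
    )
  } else {
    # tie-corrected variance; Edgeworth kurtosis term (exact fourth
    # cumulant of U for untied ranks) and a 0.5 continuity correction keep
    # the approximation within a few 1e-4 of the exact tail at n1 = n2 = 8
    ties <- table(ranks)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      k4 <- -n1 * n2 * (n + 1) *
        (n1^2 + n2^2 + n1 * n2 + n1 + n2) / 120
      gamma2 <- k4 / sigma2^2
      lower_tail <- function(z) {
        stats::pnorm(z) - stats::dnorm(z) * (z^3 - 3 * z) * gamma2 / 24
      }
      sigma <- sqrt(sigma2)
      p <- switch(alternative,
        two.sided = 2 * lower_tail((0.5 - abs(u_obs - mu)) / sigma),
        less = lower_tail((u_obs - mu + 0.5) / sigma),
        greater = lower_tail((mu - u_obs + 0.5) / sigma)
      )
      p <- min(max(p, 0), 1)
    }
  }
  list(U = u_obs, p_value = p, method = method)
}

#' Score ground-truth recovery of a selection result
#'
#' `informative_recall` is the fraction of ground-truth informative features
#' recovered: an informative feature counts as recovered when it is selected
#' itself or when one of its redundant copies is selected in its place.
#' `noise_fraction` is the fraction of selected features that are pure noise.
#'
#' @param fit An `ssd_fit` (or anything with `selected_indices`).
#' @param truth A `ground_truth` from [sim_feature_table()].
#' @return A list with `informative_recall` and `noise_fraction`,
#'   both in `[0, 1]`.
#' @export
score_recovery <- function(fit, truth) {
  stopifnot(inherits(truth, "ground_truth"))
  sel <- if (inherits(fit, "ssd_fit")) fit$selected_indices else as.integer(fit)
  if (length(sel) > 0 && max(sel) > truth$d) {
    abort("Selected indices exceed the ground-truth dimension.")
  }
  informative <- truth$informative_indices
  covered <- informative %in% sel
  if (length(truth$redundant_map) > 0) {
    red_idx <- as.integer(names(truth$redundant_map))
    hit_sources <- unique(truth$redundant_map[red_idx %in% sel])
    covered <- covered | informative %in% hit_sources
  }
  list(
    informative_recall = mean(covered),
    noise_fraction =
      if (length(sel) == 0L) 0
      else sum(sel %in% truth$noise_indices) / length(sel)
  )
}
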