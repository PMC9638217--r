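# Binary Social Ski-Driver optimizer. Agents hold a binary mask and a real
# velocity; each iteration the velocity is pulled toward the personal best
# and the mean of the all-time top-3 masks (MGB) through sin/cos-weighted
# random steps scaled by h, h decays geometrically, the velocity is mapped
# to bit-flip probabilities by a V-shaped transfer function, and the new
# mask is refined by ABHC. Minimizes the KNN wrapper fitness.

#' V-shaped transfer function
#'
#' `V(x) = |x| / sqrt(1 + x^2)`: maps a velocity component to a bit-flip
#' probability in `[0, 1)`. Even in `x`, strictly increasing in `|x|`,
#' saturating toward 1.
#'
#' @param x Numeric vector (finite).
#' @return Values in `[0, 1)`.
#' @examples
#' v_transfer(c(0, 1, -1, 1e6))
#' @export
v_transfer <- function(x) {
  if (any(!is.finite(x))) abort("`x` must be finite.")
  abs(x) / sqrt(1 + x^2)
}

#' Mean of the top-3 solution locations (MGB)
#'
#' Elementwise arithmetic mean of the three best masks, treated as real
#' vectors; the swarm's shared attractor.
#'
#' @param top3 List of three equal-length binary masks.
#' @return Real vector with values in `[0, 1]`.
#' @export
mean_global_best <- function(top3) {
  if (length(top3) != 3L) abort("Exactly three locations are required.")
  len <- lengths(top3)
  if (length(unique(len)) != 1L) abort("Locations differ in length.")
  (as.numeric(top3[[1L]]) + as.numeric(top3[[2L]]) + as.numeric(top3[[3L]])) / 3
}

#' Geometric decay of the exploration weight
#'
#' `h <- r * h`, applied once per iteration.
#'
#' @param h Current exploration weight (> 0).
#' @param r Decay factor in (0, 1].
#' @return The decayed value.
#' @export
decay_h <- function(h, r) {
  stopifnot(h > 0, r > 0, r <= 1)
  r * h
}

#' Social Ski-Driver velocity update
#'
#' One fair coin chooses the sine or cosine branch for the whole agent; each
#' attraction term then gets a fresh `rand(0,1)` per dimension inside the
#' chosen function:
#' `V_j = h * f(r1_j) * (PB_j - L_j) + f(r2_j) * (MGB_j - L_j)`,
#' `f` being `sin` or `cos`. There is no previous-velocity (inertia) term.
#'
#' @param location Current binary mask (treated as reals).
#' @param personal_best The agent's personal-best mask.
#' @param mgb Mean-of-top-3 attractor from [mean_global_best()].
#' @param h Exploration weight (> 0).
#' @param stream RNG stream from [rng_streams()].
#' @return Real velocity vector.
#' @export
update_velocity <- function(location, personal_best, mgb, h, stream) {
  stopifnot(h > 0)
  d <- length(location)
  f <- if (stream_runif(stream, 1L) <= 0.5) sin else cos
  r1 <- stream_runif(stream, d)
  r2 <- stream_runif(stream, d)
  h * f(r1) * (as.numeric(personal_best) - as.numeric(location)) +
    f(r2) * (mgb - as.numeric(location))
}

#' Transfer-function binarization step
#'
#' Where `v_transfer(velocity_j)` exceeds a fresh `rand_j(0,1)` the bit is
#' complemented, else kept. An all-zero result is repaired by switching one
#' uniformly chosen bit on (flagged by attribute `"repaired"`).
#'
#' @param mask Binary 0/1 vector (current location).
#' @param velocity Real vector of the same length.
#' @param stream RNG stream from [rng_streams()].
#' @return Binary 0/1 integer vector.
#' @export
binarize_step <- function(mask, velocity, stream) {
  if (length(mask) != length(velocity)) {
    abort("`mask` and `velocity` must have equal length.")
  }
  p <- v_transfer(velocity)
  u <- stream_runif(stream, length(mask))
  flip <- p > u
  bits <- as.integer(ifelse(flip, 1L - mask, mask))
  repair_empty_mask(bits, stream)
}

#' Select features with the Social Ski-Driver optimizer
#'
#' Runs the binary SSD swarm with embedded ABHC local search on a labeled
#' feature table. Candidate masks are scored by a k-nearest-neighbour
#' classifier on the held-out part of a stratified split (made internally
#' from `seed` unless `split` is given), with fitness
#' `w * error + (1 - w) * selected/d`, minimized. The same configuration and
#' seed always reproduce the identical result, including the convergence
#' history.
#'
#' @param data A data frame with a binary label column and numeric features.
#' @param label_col Name of the label column. Default `"label"`.
#' @param population_size Number of agents PS (>= 3). Default 20.
#' @param max_iterations Iteration budget. Default 100.
#' @param h0 Initial exploration weight. Default 100.
#' @param r Geometric decay factor of `h`, in (0, 1). Default 0.9.
#' @param w Fitness weight on classification error, `[0, 1]`. Default 0.2.
#' @param k KNN neighbourhood size (positive odd integer). Default 5.
#' @param mt ABHC local iteration budget per refinement. Default 10.
#' @param c ABHC radius curvature. Default 2.
#' @param beta_min,beta_max ABHC mutation schedule endpoints.
#'   Defaults 0.01, 0.5.
#' @param test_fraction Held-out fraction for the internal fitness split.
#'   Default 0.2.
#' @param standardize Standardize features with training statistics.
#'   Default TRUE.
#' @param seed Master seed; spawns one independent RNG stream per agent.
#' @param split Optional `split_pair` to use instead of an internal split
#'   (e.g. to compare runs on a fixed split).
#' @return An object of class `ssd_fit`: a list with `best_mask`,
#'   `best_fitness` (a `fitness_value`), `selected_indices`,
#'   `selected_features`, `fitness_history` (length `max_iterations + 1`,
#'   non-increasing), `n_evaluations`, `seed`, `config`, `split` and
#'   `feature_names`. Use [tidy()], [glance()] and [autoplot()] on it.
#' @examples
#' tbl <- sim_feature_table(120, 2, 0, 6, class_separation = 3, seed = 1)$data
#' fit <- ssd_select(tbl,
#'   population_size = 6, max_iterations = 5,
#'   mt = 3, seed = 1
#' )
#' glance(fit)
#' @export
ssd_select <- function(data, label_col = "label",
                       population_size = 20L, max_iterations = 100L,
                       h0 = 100, r = 0.9, w = 0.2, k = 5L,
                       mt = 10L, c = 2, beta_min = 0.01, beta_max = 0.5,
                       test_fraction = 0.2, standardize = TRUE,
                       seed = 1L, split = NULL) {
  population_size <- as.integer(population_size)
  max_iterations <- as.integer(max_iterations)
  if (population_size < 3L) {
    abort("`population_size` must be >= 3 (the top-3 attractor requires it).")
  }
  if (max_iterations < 0L) abort("`max_iterations` must be >= 0.")
  stopifnot(h0 > 0, r > 0, r < 1, w >= 0, w <= 1)
  ft_parts(data, label_col, require_both_classes = TRUE)
  if (is.null(split)) {
    split <- stratified_split(data, test_fraction, seed = seed,
                              label_col = label_col)
  }
  evaluator <- make_mask_evaluator(split, k = k, w = w,
                                   standardize = standardize)
  d <- evaluator$d
  streams <- rng_streams(seed, population_size)

  agents <- vector("list", population_size)
  for (i in seq_len(population_size)) {
    bits <- repair_empty_mask(
      as.integer(stream_runif(streams[[i]], d) < 0.5), streams[[i]]
    )
    fit <- evaluator$evaluate(bits)
    agents[[i]] <- list(
      mask = as.integer(bits), velocity = numeric(d),
      pb_mask = as.integer(bits), pb_fitness = fit
    )
  }

  swarm_best <- function() {
    idx <- archive_top(evaluator$archive, 3L)
    list(
      top3 = lapply(idx, function(j) evaluator$archive$masks[[j]]),
      best_idx = idx[[1L]]
    )
  }
  tops <- swarm_best()
  mgb <- mean_global_best(tops$top3)
  best_fit <- function(idx) evaluator$archive$fitness[[idx]]
  fitness_history <- best_fit(tops$best_idx)

  h <- h0
  iter <- 0L
  while (iter < max_iterations) {
    iter <- iter + 1L
    for (i in seq_len(population_size)) {
      ag <- agents[[i]]
      st <- streams[[i]]
      ag$velocity <- update_velocity(ag$mask, ag$pb_mask, mgb, h, st)
      new_mask <- binarize_step(ag$mask, ag$velocity, st)
      fit <- evaluator$evaluate(new_mask)
      ref <- abhc_refine(
        new_mask, evaluator$evaluate,
        mt = mt, c = c, beta_min = beta_min, beta_max = beta_max,
        stream = st, current_fitness = fit
      )
      ag$mask <- ref$mask
      if (ref$fitness$fitness < ag$pb_fitness$fitness) {
        ag$pb_mask <- ref$mask
        ag$pb_fitness <- ref$fitness
      }
      agents[[i]] <- ag
    }
    tops <- swarm_best()
    mgb <- mean_global_best(tops$top3)
    h <- decay_h(h, r)
    fitness_history <- c(fitness_history, best_fit(tops$best_idx))
  }

  best_idx <- tops$best_idx
  best_mask <- evaluator$archive$masks[[best_idx]]
  best_fitness <- evaluator$peek(best_mask)
  feature_names <- setdiff(names(split$train), split$label_col)
  structure(
    list(
      best_mask = best_mask,
      best_fitness = best_fitness,
      selected_indices = which(best_mask == 1L),
      selected_features = feature_names[best_mask == 1L],
      fitness_history = fitness_history,
      n_evaluations = evaluator$n_evaluations(),
      seed = seed,
      feature_names = feature_names,
      split = split,
      config = list(
        population_size = population_size, max_iterations = max_iterations,
        h0 = h0, r = r, w = w, k = evaluator$k, mt = as.integer(mt), c = c,
        beta_min = beta_min, beta_max = beta_max,
        test_fraction = test_fraction, standardize = standardize
      )
    ),
    class = "ssd_fit"
  )
}

#' @export
print.ssd_fit <- function(x, ...) {
  cat("<ssd_fit> Social Ski-Driver feature selection\n")
  cat(sprintf(
    "  selected %d of %d features; fitness %.6f (error %s, w = %g)\n",
    length(x$selected_indices), length(x$feature_names),
    x$best_fitness$fitness,
    if (is.na(x$best_fitness$error_alpha)) "undefined"
    else sprintf("%.4f", x$best_fitness$error_alpha),
    x$config$w
  ))
  cat(sprintf(
    "  %d iterations, %d fitness evaluations, seed %d\n",
    x$config$max_iterations, x$n_evaluations, x$seed
  ))
  invisible(x)
}

#' Serialize a selection result to JSON
#'
#' @param fit An `ssd_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection_json <- function(fit, path) {
  stopifnot(inherits(fit, "ssd_fit"))
  jsonlite::write_json(
    list(
      best_mask = fit$best_mask,
      selected_indices = fit$selected_indices,
      selected_features = fit$selected_features,
      fitness = fit$best_fitness$fitness,
      error_alpha = fit$best_fitness$error_alpha,
      selected_count = fit$best_fitness$selected_count,
      w = fit$config$w,
      k = fit$config$k,
      fitness_history = fit$fitness_history,
      n_evaluations = fit$n_evaluations,
      seed = fit$seed,
      config = fit$config
    ),
    path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
  )
  invisible(path)
}
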