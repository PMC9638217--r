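# Adaptive Beta Hill Climbing: single-solution refinement with a shrinking
# neighbourhood radius N(z) and a growing keep-probability schedule Beta(z),
# accepting only strict improvements. Operates on a relaxed [0,1]
# representation of the binary mask (the neighbourhood step is real-valued),
# clipped and thresholded at 0.5 back to bits.

#' ABHC neighbourhood radius schedule
#'
#' `N(z) = 1 - z^(1/c) / MT^(1/c)`: the maximal per-dimension step size,
#' shrinking from 1 at `z = 0` to 0 at `z = MT`.
#'
#' @param z Current local-search iteration, `0 <= z <= MT`.
#' @param mt Local iteration budget MT.
#' @param c Curvature constant (> 0); `c = 1` gives a linear schedule.
#' @return The radius, in `[0, 1]`.
#' @export
neighborhood_radius <- function(z, mt, c = 2) {
  stopifnot(c > 0, mt >= 1)
  if (any(z < 0) || any(z > mt)) abort("`z` must satisfy 0 <= z <= MT.")
  1 - z^(1 / c) / mt^(1 / c)
}

#' ABHC mutation-probability schedule
#'
#' `Beta(z) = (Ma - Mi) * z / MT + Mi`: linear from `Mi` at `z = 0` to `Ma`
#' at `z = MT`.
#'
#' @inheritParams neighborhood_radius
#' @param beta_min Minimum value Mi.
#' @param beta_max Maximum value Ma (`Mi <= Ma`).
#' @return The schedule value.
#' @export
beta_schedule <- function(z, mt, beta_min = 0.01, beta_max = 0.5) {
  stopifnot(mt >= 1, beta_min <= beta_max)
  if (any(z < 0) || any(z > mt)) abort("`z` must satisfy 0 <= z <= MT.")
  (beta_max - beta_min) * z / mt + beta_min
}

#' Random neighbour of a mask in the relaxed representation
#'
#' Per dimension, `L'_j = L_j +/- rand(0,1) * radius` with a fair sign coin
#' per dimension. The result is real-valued; binarization happens in
#' [beta_mutation()].
#'
#' @param mask Binary 0/1 vector.
#' @param radius Maximal per-dimension step, in `[0, 1]`.
#' @param stream RNG stream from [rng_streams()].
#' @return Real vector of the same length.
#' @export
neighbor_move <- function(mask, radius, stream) {
  d <- length(mask)
  signs <- ifelse(stream_runif(stream, d) < 0.5, -1, 1)
  mask + signs * stream_runif(stream, d) * radius
}

#' Beta mutation of a relaxed neighbour back to a binary mask
#'
#' Per dimension the original bit is kept where `beta > rand_j`, else the
#' neighbour value is taken; values are clipped to `[0, 1]` and thresholded
#' at 0.5 (ties become 1). An all-zero result is repaired by switching one
#' uniformly chosen bit on.
#'
#' @param mask Binary 0/1 vector (the incumbent).
#' @param l_prime Real vector from [neighbor_move()].
#' @param beta Keep probability, in `[0, 1]`.
#' @param stream RNG stream from [rng_streams()].
#' @return Binary 0/1 integer vector; repaired masks carry attribute
#'   `"repaired"`.
#' @export
beta_mutation <- function(mask, l_prime, beta, stream) {
  d <- length(mask)
  keep <- beta > stream_runif(stream, d)
  x <- ifelse(keep, mask, l_prime)
  bits <- as.integer(pmin(pmax(x, 0), 1) >= 0.5)
  repair_empty_mask(bits, stream)
}

repair_empty_mask <- function(bits, stream) {
  if (sum(bits) == 0L) {
    bits[stream_sample_int(stream, length(bits))] <- 1L
    attr(bits, "repaired") <- TRUE
  }
  bits
}

#' Refine a feature mask by Adaptive Beta Hill Climbing
#'
#' Runs `mt` local iterations: at step `z` a neighbour is proposed with
#' radius [neighborhood_radius()] and mutated with probability schedule
#' [beta_schedule()], then evaluated; the incumbent is replaced only on a
#' strict fitness improvement, so the result is never worse than the input.
#'
#' @param mask Binary 0/1 starting mask (non-empty).
#' @param evaluate Function mapping a mask to a `fitness_value`.
#' @param mt Local iteration budget MT (>= 1). Default 10.
#' @param c Radius curvature constant. Default 2.
#' @param beta_min,beta_max Mutation schedule endpoints. Defaults 0.01, 0.5.
#' @param stream RNG stream (from `rng_streams()`); pass one stream per
#'   calling agent for order-independent reproducibility.
#' @param current_fitness Optional `fitness_value` of `mask`; when `NULL` it
#'   is computed with one extra evaluation.
#' @return A list with `mask`, `fitness` and `trace` (start/end fitness,
#'   accepted move count, number of proposal evaluations = `mt`).
#' @export
abhc_refine <- function(mask, evaluate, mt = 10L, c = 2,
                        beta_min = 0.01, beta_max = 0.5,
                        stream = rng_streams(1L, 1L)[[1L]],
                        current_fitness = NULL) {
  mask <- as.integer(mask)
  if (sum(mask) == 0L) abort("Starting mask must be non-empty.")
  mt <- as.integer(mt)
  stopifnot(mt >= 1L)
  cur_fit <- if (is.null(current_fitness)) evaluate(mask) else current_fitness
  start_fitness <- cur_fit$fitness
  accepted <- 0L
  for (z in seq_len(mt)) {
    radius <- neighborhood_radius(z, mt, c)
    beta <- beta_schedule(z, mt, beta_min, beta_max)
    l_prime <- neighbor_move(mask, radius, stream)
    candidate <- beta_mutation(mask, l_prime, beta, stream)
    cand_fit <- evaluate(candidate)
    if (cand_fit$fitness < cur_fit$fitness) {
      mask <- as.integer(candidate)
      cur_fit <- cand_fit
      accepted <- accepted + 1L
    }
  }
  list(
    mask = mask,
    fitness = cur_fit,
    trace = list(
      start_fitness = start_fitness,
      end_fitness = cur_fit$fitness,
      accepted_moves = accepted,
      evaluations = mt
    )
  )
}
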