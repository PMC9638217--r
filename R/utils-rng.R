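# Reproducibility helpers. All stochastic code in the package draws either
# through a temporarily-seeded RNG scope (generators, splits) or through
# explicit L'Ecuyer-CMRG streams (the optimizer), so user session RNG state
# is never disturbed and identical seeds replay bit-identically.

.get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Evaluate `code` with the session RNG untouched afterwards; optionally seed.
local_seed <- function(seed, code) {
  old <- .get_rng_state()
  on.exit(.set_rng_state(old), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Spawn independent reproducible RNG streams
#'
#' One master seed spawns `n` independent L'Ecuyer-CMRG substreams, one per
#' consumer (e.g. per optimizer agent), so draws are reproducible regardless
#' of how much any single consumer draws. The session RNG is untouched.
#'
#' @param seed Integer master seed.
#' @param n Number of streams.
#' @return A list of `n` stream objects for the `stream =` arguments of the
#'   stochastic operators.
#' @export
rng_streams <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1L)
  old <- .get_rng_state()
  on.exit(.set_rng_state(old), add = TRUE)
  set.seed(as.integer(seed), kind = "L'Ecuyer-CMRG")
  state <- get(".Random.seed", envir = globalenv())
  streams <- vector("list", n)
  for (i in seq_len(n)) {
    e <- new.env(parent = emptyenv())
    e$state <- state
    streams[[i]] <- e
    state <- parallel::nextRNGStream(state)
  }
  streams
}

# Draw from a stream: swap its state in, call the sampler, swap back out.
stream_eval <- function(stream, fn, ...) {
  old <- .get_rng_state()
  on.exit(.set_rng_state(old), add = TRUE)
  .set_rng_state(stream$state)
  out <- fn(...)
  stream$state <- get(".Random.seed", envir = globalenv())
  out
}

stream_runif <- function(stream, n) stream_eval(stream, stats::runif, n)

stream_sample_int <- function(stream, n, size = 1L) {
  stream_eval(stream, sample.int, n, size)
}
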