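test_that("the V-shaped transfer function has its closed-form values", {
  expect_equal(v_transfer(0), 0)
  expect_equal(v_transfer(1), 1 / sqrt(2))
  xs <- c(0.1, 0.5, 2, 17, 1e3)
  expect_equal(v_transfer(-xs), v_transfer(xs))
  expect_true(all(diff(v_transfer(xs)) > 0))
  expect_true(all(v_transfer(xs) < 1))
  expect_error(v_transfer(Inf), "finite")
})

test_that("the mean-global-best attractor averages the top three masks", {
  m <- c(1L, 0L, 1L)
  expect_equal(mean_global_best(list(m, m, m)), as.numeric(m))
  expect_equal(
    mean_global_best(list(c(1L, 0L), c(1L, 1L), c(0L, 0L))),
    c(2 / 3, 1 / 3)
  )
  perms <- list(
    list(c(1L, 0L), c(1L, 1L), c(0L, 0L)),
    list(c(0L, 0L), c(1L, 0L), c(1L, 1L)),
    list(c(1L, 1L), c(0L, 0L), c(1L, 0L))
  )
  outs <- lapply(perms, mean_global_best)
  expect_equal(outs[[1]], outs[[2]])
  expect_equal(outs[[1]], outs[[3]])
  expect_error(mean_global_best(list(c(1L, 0L), c(1L, 1L))), "three")
})

test_that("the exploration weight decays geometrically", {
  expect_equal(decay_h(100, 0.9), 90)
  expect_equal(decay_h(decay_h(100, 0.9), 0.9), 81)
  expect_equal(decay_h(57, 1), 57)
})

test_that("velocity updates vanish at a fixed point and respect the bound", {
  loc <- c(1L, 0L, 1L, 0L)
  mgb <- as.numeric(loc)
  expect_equal(
    update_velocity(loc, loc, mgb, h = 100, new_stream(1)),
    rep(0, 4)
  )
  pb <- c(0L, 1L, 1L, 0L)
  mgb2 <- c(0.5, 0.25, 1, 0)
  for (s in 1:10) {
    v <- update_velocity(loc, pb, mgb2, h = 100, new_stream(s))
    bound <- 100 * abs(pb - loc) + abs(mgb2 - loc)
    expect_true(all(abs(v) <= bound + 1e-12))
  }
  expect_identical(
    update_velocity(loc, pb, mgb2, h = 7, new_stream(3)),
    update_velocity(loc, pb, mgb2, h = 7, new_stream(3))
  )
})

test_that("binarization flips by transfer probability and repairs zeros", {
  mask <- c(1L, 0L, 1L)
  expect_equal(binarize_step(mask, c(0, 0, 0), new_stream(1)), mask)

  # saturated velocity: flip frequency matches v_transfer(1e6) ~ 1
  st <- new_stream(7)
  n_trials <- 1e4
  flips <- 0L
  for (i in seq_len(n_trials)) {
    out <- binarize_step(c(1L, 1L), c(1e6, 0), st)
    flips <- flips + (out[1L] == 0L)
  }
  expect_gte(flips / n_trials, 0.99)

  expect_identical(
    binarize_step(mask, c(2, -1, 0.3), new_stream(2)),
    binarize_step(mask, c(2, -1, 0.3), new_stream(2))
  )

  # all bits flipping off triggers the single-bit repair
  out <- binarize_step(c(1L, 1L), c(1e9, 1e9), new_stream(3))
  expect_equal(sum(out), 1L)
})

test_that("zero iterations return the best of the initial population", {
  prob <- small_search_problem()
  fit <- ssd_select(prob$sim$data,
    population_size = 5, max_iterations = 0,
    seed = 2, split = prob$split
  )
  expect_length(fit$fitness_history, 1L)
  expect_equal(fit$fitness_history[1L], fit$best_fitness$fitness)
})

test_that("runs are elitist, budgeted and bit-reproducible", {
  prob <- small_search_problem()
  ps <- 6L
  iters <- 8L
  mt <- 5L
  fits <- lapply(1:3, function(s) {
    ssd_select(prob$sim$data,
      population_size = ps, max_iterations = iters,
      mt = mt, seed = s, split = prob$split
    )
  })
  for (fit in fits) {
    expect_true(all(diff(fit$fitness_history) <= 0))
    expect_length(fit$fitness_history, iters + 1L)
    expect_lte(fit$n_evaluations, ps * (1 + iters * (1 + mt)))
    expect_equal(
      fit$fitness_history[length(fit$fitness_history)],
      fit$best_fitness$fitness
    )
    expect_equal(fit$selected_indices, which(fit$best_mask == 1L))
    expect_gte(sum(fit$best_mask), 1L)
  }

  again <- ssd_select(prob$sim$data,
    population_size = ps, max_iterations = iters,
    mt = mt, seed = 1, split = prob$split
  )
  keep <- c("best_mask", "best_fitness", "selected_indices",
            "fitness_history", "n_evaluations")
  expect_identical(fits[[1]][keep], again[keep])
})

test_that("degenerate inputs are rejected before any iteration", {
  one_class <- tibble::tibble(f1 = rnorm(10), label = rep(1L, 10))
  expect_error(ssd_select(one_class, seed = 1), "[Bb]oth classes")
  prob <- small_search_problem()
  expect_error(
    ssd_select(prob$sim$data, population_size = 2, seed = 1),
    "population_size"
  )
})

test_that("selection results serialize to JSON and tidy into tibbles", {
  prob <- small_search_problem()
  fit <- ssd_select(prob$sim$data,
    population_size = 4, max_iterations = 3,
    mt = 2, seed = 1, split = prob$split
  )
  tf <- withr::local_tempfile(fileext = ".json")
  write_selection_json(fit, tf)
  back <- jsonlite::read_json(tf, simplifyVector = TRUE)
  expect_equal(back$fitness, fit$best_fitness$fitness)
  expect_equal(back$selected_indices, fit$selected_indices)
  expect_equal(back$fitness_history, fit$fitness_history)

  td <- tidy(fit)
  expect_equal(nrow(td), 8L)
  expect_equal(sum(td$selected), length(fit$selected_indices))
  g <- glance(fit)
  expect_equal(g$n_selected, length(fit$selected_indices))
  expect_equal(g$fitness, fit$best_fitness$fitness)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
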