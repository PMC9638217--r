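test_that("the radius and mutation schedules hit their endpoints", {
  expect_equal(neighborhood_radius(0, 10), 1)
  expect_equal(neighborhood_radius(10, 10), 0)
  expect_equal(neighborhood_radius(5, 10, c = 1), 0.5)
  expect_equal(beta_schedule(0, 10), 0.01)
  expect_equal(beta_schedule(10, 10), 0.5)
  expect_equal(beta_schedule(5, 10, 0.01, 0.5), 0.255)
  expect_error(neighborhood_radius(11, 10), "<= MT")
})

test_that("schedules are monotone for random configurations", {
  set.seed(42)
  for (rep in 1:20) {
    mt <- sample(2:30, 1)
    cc <- runif(1, 0.2, 5)
    mi <- runif(1, 0, 0.5)
    ma <- runif(1, mi, 1)
    z <- 0:mt
    n_vals <- neighborhood_radius(z, mt, cc)
    b_vals <- beta_schedule(z, mt, mi, ma)
    expect_true(all(diff(n_vals) <= 1e-12))
    expect_true(all(diff(b_vals) >= -1e-12))
    expect_true(all(n_vals >= 0 & n_vals <= 1))
  }
})

test_that("neighbour moves stay inside the radius and replay exactly", {
  mask <- c(1L, 0L, 1L, 1L, 0L)
  expect_equal(neighbor_move(mask, 0, new_stream(1)), as.numeric(mask))
  for (radius in c(0.1, 0.5, 1)) {
    lp <- neighbor_move(mask, radius, new_stream(2))
    expect_true(all(abs(lp - mask) <= radius + 1e-12))
  }
  expect_identical(
    neighbor_move(mask, 0.7, new_stream(5)),
    neighbor_move(mask, 0.7, new_stream(5))
  )
})

test_that("beta mutation keeps, takes, clips and thresholds as specified", {
  mask <- c(1L, 0L)
  lp <- c(1.0, 0.9)
  # beta = 1: always keep the incumbent
  expect_equal(beta_mutation(mask, c(-5, 5), 1, new_stream(1)), mask)
  # beta = 0: always take the neighbour, clipped and thresholded at 0.5
  expect_equal(beta_mutation(mask, lp, 0, new_stream(1)), c(1L, 1L))
  expect_equal(beta_mutation(mask, c(2, -3), 0, new_stream(1)), c(1L, 0L))
  # threshold ties go to 1
  expect_equal(beta_mutation(mask, c(0.5, 0.5), 0, new_stream(1)), c(1L, 1L))
  # all-zero results are repaired to a single set bit
  out <- beta_mutation(c(0L, 0L, 0L), c(-1, -1, -1), 0, new_stream(3))
  expect_equal(sum(out), 1L)
  expect_true(isTRUE(attr(out, "repaired")))
})

test_that("refinement never worsens and spends exactly MT evaluations", {
  # constant evaluator: nothing strictly improves, nothing changes
  const_eval <- function(mask) {
    ssdfs:::new_fitness_value(0.5, 0.5, sum(mask), 0.2, length(mask))
  }
  out <- abhc_refine(c(1L, 0L, 1L), const_eval, mt = 8,
                     stream = new_stream(1))
  expect_equal(out$mask, c(1L, 0L, 1L))
  expect_equal(out$trace$accepted_moves, 0L)
  expect_equal(out$trace$evaluations, 8L)

  # counting wrapper: exactly MT proposals evaluated when the current
  # fitness is supplied
  calls <- new.env()
  calls$n <- 0L
  counting_eval <- function(mask) {
    calls$n <- calls$n + 1L
    const_eval(mask)
  }
  abhc_refine(c(1L, 1L), counting_eval, mt = 6, stream = new_stream(2),
              current_fitness = const_eval(c(1L, 1L)))
  expect_equal(calls$n, 6L)

  # never-worsening across random problems
  prob <- small_search_problem()
  ev <- ssdfs:::make_mask_evaluator(prob$split)
  for (s in 1:5) {
    st <- new_stream(s)
    mask <- as.integer(ssdfs:::stream_runif(st, 8) < 0.5)
    if (sum(mask) == 0L) mask[1L] <- 1L
    start <- ev$evaluate(mask)
    out <- abhc_refine(mask, ev$evaluate, mt = 10, stream = st,
                       current_fitness = start)
    expect_lte(out$fitness$fitness, start$fitness)
    expect_equal(out$trace$start_fitness, start$fitness)
    expect_equal(out$trace$end_fitness, out$fitness$fitness)
  }
})

test_that("refinement cannot leave the global optimum and fixes slack masks", {
  sim <- sim_feature_table(150, 2, 0, 4, class_separation = 3, seed = 9)
  sp <- stratified_split(sim$data, 0.2, seed = 9)
  ev <- ssdfs:::make_mask_evaluator(sp)
  or <- exhaustive_oracle(sp)

  out <- abhc_refine(or$best_mask, ev$evaluate, mt = 15,
                     stream = new_stream(4),
                     current_fitness = ev$evaluate(or$best_mask))
  expect_equal(out$fitness$fitness, or$best_fitness$fitness)

  # a mask carrying extra noise features improves on most seeds
  slack <- or$best_mask
  slack[sim$truth$noise_indices] <- 1L
  start <- ev$evaluate(slack)
  improved <- sum(vapply(1:5, function(s) {
    out <- abhc_refine(slack, ev$evaluate, mt = 20, stream = new_stream(s),
                       current_fitness = start)
    out$fitness$fitness < start$fitness
  }, logical(1)))
  expect_gte(improved, 4L)
})
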