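test_that("KNN predicts by nearest cluster with deterministic tie rules", {
  tr <- cluster_table(n_per_class = 3L)
  expect_equal(
    knn_predict(tr, tibble::tibble(f1 = 9, f2 = 9), k = 1),
    1L
  )
  expect_equal(
    knn_predict(tr, tibble::tibble(f1 = 1, f2 = 1), k = 3),
    0L
  )

  # constant selected column: all train rows equidistant; the stable
  # tie rule picks the lowest-index rows, here the majority class
  tr2 <- tibble::tibble(
    f1 = c(0, 1, 2, 3, 4), f2 = rep(7, 5),
    label = c(0L, 0L, 0L, 1L, 1L)
  )
  expect_equal(
    knn_predict(tr2, tibble::tibble(f1 = 100, f2 = 0), k = 5,
                mask = c(0, 1)),
    0L
  )

  # train-on-train 1-NN is error-free (each point is its own neighbour)
  preds <- knn_predict(tr, tr, k = 1)
  expect_equal(preds, tr$label)

  expect_error(knn_predict(tr, tr, k = 2), "odd")
  expect_error(knn_predict(tr, tr, k = 7), "training rows")
  expect_error(knn_predict(tr, tr, k = 1, mask = c(0, 0)), "at least one")
})

test_that("classification error and precision/recall follow the formulas", {
  counts <- c(TP = 3, TN = 4, FP = 2, FN = 1)
  pr <- precision_recall(counts)
  expect_equal(pr$precision, 0.6)
  expect_equal(pr$recall, 0.75)

  # rebuild the same counts from label vectors
  preds <- c(rep(1L, 3), rep(0L, 4), rep(1L, 2), rep(0L, 1))
  labs <- c(rep(1L, 3), rep(0L, 4), rep(0L, 2), rep(1L, 1))
  err <- classification_error(preds, labs)
  expect_equal(err$alpha, 0.3)
  expect_equal(err$counts, counts)

  expect_equal(classification_error(labs, labs)$alpha, 0)
  expect_equal(classification_error(1L - labs, labs)$alpha, 1)

  expect_identical(
    precision_recall(c(TP = 0, TN = 5, FP = 0, FN = 2))$precision,
    NA_real_
  )
  expect_equal(precision_recall(c(TP = 4, TN = 1, FP = 0, FN = 0)),
               list(precision = 1, recall = 1))
  expect_error(classification_error(integer(0), integer(0)), "Empty")
})

test_that("the wrapper fitness combines error and subset size", {
  expect_equal(wrapper_fitness(0.5, 64, 128, w = 0.2), 0.5)
  expect_equal(wrapper_fitness(0, 128, 128, w = 0.2), 0.8)
  expect_equal(wrapper_fitness(0.37, 10, 128, w = 1), 0.37)
  # monotone in |s| for w < 1 and in alpha for w > 0
  f_s <- sapply(1:10, function(s) wrapper_fitness(0.3, s, 10, w = 0.2))
  expect_true(all(diff(f_s) > 0))
  f_a <- sapply(seq(0, 1, 0.1), function(a) wrapper_fitness(a, 5, 10, w = 0.2))
  expect_true(all(diff(f_a) > 0))
})

test_that("mask evaluation reports consistent components and memoizes", {
  prob <- small_search_problem()
  mask <- c(1L, 1L, 0L, 0L, 0L, 1L, 0L, 0L)
  fv <- evaluate_mask(mask, prob$split)
  expect_equal(
    fv$fitness,
    wrapper_fitness(fv$error_alpha, fv$selected_count, 8, 0.2),
    tolerance = 1e-12
  )
  expect_equal(fv$selected_count, 3L)
  expect_gte(fv$fitness, 0)
  expect_lte(fv$fitness, 1)

  # empty mask: defined worst fitness, undefined error
  fv0 <- evaluate_mask(rep(0L, 8), prob$split)
  expect_equal(fv0$fitness, 1.0)
  expect_true(is.na(fv0$error_alpha))

  # memoized re-evaluation is bit-identical and does not recompute
  ev <- ssdfs:::make_mask_evaluator(prob$split)
  a <- ev$evaluate(mask)
  b <- ev$evaluate(mask)
  expect_identical(a, b)
  expect_equal(ev$n_evaluations(), 2L)
})

test_that("w = 1 collapses the fitness to the classification error", {
  prob <- small_search_problem()
  mask <- c(1L, 0L, 0L, 0L, 1L, 0L, 0L, 1L)
  fv <- evaluate_mask(mask, prob$split, w = 1)
  expect_equal(fv$fitness, fv$error_alpha, tolerance = 1e-12)
})

test_that("the exhaustive oracle finds the constructed optimum", {
  # feature 1 separates perfectly, feature 2 is noise: best mask [1,0]
  tbl <- perfect_plus_noise_table()
  sp <- stratified_split(tbl, 0.2, seed = 1)
  or <- exhaustive_oracle(sp, k = 1, w = 0.2)
  expect_equal(or$best_mask, c(1L, 0L))
  expect_equal(or$best_fitness$fitness, 0.2 * 0 + 0.8 * 0.5)
  expect_equal(or$n_masks, 3L)

  # all-noise table: ties on error resolve to the smallest subset
  noise <- sim_feature_table(120, 1, 0, 3, class_separation = 0, seed = 2)
  sp2 <- stratified_split(noise$data, 0.2, seed = 2)
  or2 <- exhaustive_oracle(sp2)
  expect_equal(sum(or2$best_mask), 1L)

  # d = 1: the single non-empty mask
  one <- tibble::tibble(f1 = c(0, 0, 1, 1), label = c(0L, 0L, 1L, 1L))
  sp3 <- stratified_split(one, 0.25, seed = 1)
  or3 <- exhaustive_oracle(sp3, k = 1)
  expect_equal(or3$best_mask, 1L)

  big <- sim_feature_table(40, 17, 0, 0, seed = 1)
  sp4 <- stratified_split(big$data, 0.2, seed = 1)
  expect_error(exhaustive_oracle(sp4), "d <= 16")
})

test_that("no optimizer result beats the oracle on the same split", {
  prob <- small_search_problem()
  or <- exhaustive_oracle(prob$split)
  fit <- ssd_select(prob$sim$data,
    population_size = 6, max_iterations = 10,
    mt = 5, seed = 3, split = prob$split
  )
  expect_gte(fit$best_fitness$fitness, or$best_fitness$fitness - 1e-12)
})
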