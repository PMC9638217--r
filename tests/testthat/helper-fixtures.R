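# Fixtures built in code; no files on disk.

# Two well-separated clusters: class 0 near the origin, class 1 near
# (10, 10, ...). `n_per_class` rows each.
cluster_table <- function(n_per_class = 3L, d = 2L, gap = 10) {
  x0 <- matrix(0, n_per_class, d)
  x1 <- matrix(gap, n_per_class, d)
  df <- as.data.frame(rbind(x0, x1))
  names(df) <- paste0("f", seq_len(d))
  df$label <- rep(c(0L, 1L), each = n_per_class)
  tibble::as_tibble(df)
}

# d = 2 table where feature 1 separates the classes perfectly and feature 2
# is label-independent noise; deterministic.
perfect_plus_noise_table <- function(n_per_class = 10L) {
  tibble::tibble(
    f1 = c(seq(-2, -1, length.out = n_per_class),
           seq(1, 2, length.out = n_per_class)),
    f2 = rep(c(-1, 1), n_per_class), # alternating, identical in both classes
    label = rep(c(0L, 1L), each = n_per_class)
  )
}

# A split pair over a deterministic table, for evaluator tests.
fixed_split <- function(data, test_fraction = 0.2, seed = 1L) {
  stratified_split(data, test_fraction, seed = seed)
}

# Small synthetic table used across optimizer tests (2 informative at
# separation 3, 6 noise, 200 rows) with a fixed split.
small_search_problem <- function(seed = 1L, split_seed = 42L) {
  sim <- sim_feature_table(
    n_samples = 200, n_informative = 2, n_redundant = 0, n_noise = 6,
    class_separation = 3, seed = seed
  )
  list(
    sim = sim,
    split = stratified_split(sim$data, 0.2, seed = split_seed)
  )
}

new_stream <- function(seed = 1L) rng_streams(seed, 1L)[[1L]]
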