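# broom-style accessors for fitted objects.

#' Tidy a selection result
#'
#' One row per feature: its name, index, and whether the optimizer kept it.
#'
#' @param x An `ssd_fit` from [ssd_select()].
#' @param ... Unused.
#' @return A tibble with columns `term`, `index`, `selected`.
#' @export
tidy.ssd_fit <- function(x, ...) {
  tibble(
    term = x$feature_names,
    index = seq_along(x$feature_names),
    selected = seq_along(x$feature_names) %in% x$selected_indices
  )
}

#' Glance at a selection result
#'
#' @param x An `ssd_fit` from [ssd_select()].
#' @param ... Unused.
#' @return A one-row tibble with the fitness, its error component, accuracy
#'   on the held-out part, subset size, problem size, evaluation count,
#'   iteration budget and seed.
#' @export
glance.ssd_fit <- function(x, ...) {
  tibble(
    fitness = x$best_fitness$fitness,
    error_alpha = x$best_fitness$error_alpha,
    accuracy = 1 - x$best_fitness$error_alpha,
    n_selected = length(x$selected_indices),
    n_features = length(x$feature_names),
    n_evaluations = x$n_evaluations,
    max_iterations = x$config$max_iterations,
    w = x$config$w,
    k = x$config$k,
    seed = x$seed
  )
}

#' Tidy a multi-run experiment
#'
#' @param x An `fs_experiment` from [repeat_experiment()].
#' @param ... Unused.
#' @return The per-run tibble (run, seed, accuracy, precision, recall,
#'   n_selected).
#' @export
tidy.fs_experiment <- function(x, ...) x$per_run

#' Glance at a multi-run experiment
#'
#' @param x An `fs_experiment` from [repeat_experiment()].
#' @param ... Unused.
#' @return A one-row tibble with mean and sample SD of each metric.
#' @export
glance.fs_experiment <- function(x, ...) {
  s <- x$summary
  out <- tibble(.rows = 1L)
  for (i in seq_len(nrow(s))) {
    out[[paste0("mean_", s$metric[i])]] <- s$mean[i]
    out[[paste0("sd_", s$metric[i])]] <- s$sd[i]
  }
  out$n_runs <- nrow(x$per_run)
  out
}

#' Plot the convergence history of a selection run
#'
#' Best-so-far fitness against iteration; non-increasing by construction.
#'
#' @param object An `ssd_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ssd_fit <- function(object, ...) {
  df <- tibble(
    iteration = seq_along(object$fitness_history) - 1L,
    fitness = object$fitness_history
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$fitness)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = "Iteration", y = "Best fitness",
      title = "SSD + ABHC convergence",
      subtitle = sprintf(
        "%d of %d features selected (w = %g, k = %d)",
        length(object$selected_indices), length(object$feature_names),
        object$config$w, object$config$k
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-run metrics of an experiment
#'
#' Accuracy, precision and recall per simulation with the mean as a
#' horizontal reference.
#'
#' @param object An `fs_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fs_experiment <- function(object, ...) {
  pr <- object$per_run
  long <- dplyr::bind_rows(lapply(
    c("accuracy", "precision", "recall"),
    function(m) tibble(run = pr$run, metric = m, value = pr[[m]])
  ))
  means <- dplyr::summarise(
    dplyr::group_by(long, .data$metric),
    value = mean(.data$value), .groups = "drop"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$run, y = .data$value)) +
    ggplot2::geom_hline(
      data = means, ggplot2::aes(yintercept = .data$value),
      linetype = "dashed", colour = "grey50"
    ) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Simulation", y = "Percent") +
    ggplot2::theme_minimal()
}
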