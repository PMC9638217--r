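# tabular I/O: labeled feature tables as tibbles with one label column.

#' Validate a labeled feature table and extract its parts
#'
#' Internal canonical form used by the classifier and the optimizer: a
#' numeric feature matrix, an integer 0/1 label vector (0 = negative/benign,
#' 1 = positive/malignant) and the feature names.
#'
#' @param data A data frame; every column except `label_col` must be numeric.
#' @param label_col Name of the label column.
#' @param require_both_classes Error unless both classes are present.
#' @return A list with `x` (matrix), `y` (integer vector), `feature_names`,
#'   and `label_levels` (the original values mapped to 0 and 1).
#' @noRd
ft_parts <- function(data, label_col = "label", require_both_classes = FALSE) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  if (!label_col %in% names(data)) {
    abort(sprintf("Label column '%s' not found.", label_col))
  }
  feat_names <- setdiff(names(data), label_col)
  if (length(feat_names) < 1L) abort("At least one feature column is required.")
  if (anyDuplicated(feat_names)) {
    abort(sprintf(
      "Duplicate feature names: %s",
      paste(unique(feat_names[duplicated(feat_names)]), collapse = ", ")
    ))
  }
  for (nm in feat_names) {
    if (!is.numeric(data[[nm]])) {
      abort(sprintf("Feature column '%s' is not numeric.", nm))
    }
  }
  x <- as.matrix(data[feat_names])
  if (nrow(x) < 2L) abort("At least 2 samples are required.")
  enc <- encode_labels(data[[label_col]])
  if (require_both_classes && length(unique(enc$y)) < 2L) {
    abort("Both classes must be present.")
  }
  list(
    x = x, y = enc$y, feature_names = feat_names,
    label_levels = enc$levels
  )
}

# Map any two distinct label values to {0,1} by sorted order.
encode_labels <- function(labels) {
  if (anyNA(labels)) abort("Labels contain missing values.")
  lev <- sort(unique(labels))
  if (length(lev) > 2L) {
    abort(sprintf(
      "Labels must have at most two distinct values, found %d.", length(lev)
    ))
  }
  if (is.numeric(labels) && all(lev %in% c(0, 1))) {
    return(list(y = as.integer(labels), levels = c(0, 1)))
  }
  y <- as.integer(match(labels, lev) - 1L)
  list(y = y, levels = lev)
}

#' Read a labeled feature table from delimited text
#'
#' Reads a CSV/TSV file with a header row into a tibble, checking that every
#' non-label cell is numeric (the offending row and column are named
#' otherwise). Label values are coerced to 0/1: any two distinct values are
#' accepted and mapped by sorted order, with the mapping reported.
#'
#' @param path Path to a delimited text file with a header row.
#' @param label_col Name of the label column. Default `"label"`.
#' @param delim Field delimiter. Default `","`.
#' @return A tibble whose label column is integer 0/1. The original label
#'   values, in mapped order, are kept in the `"label_levels"` attribute.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("f1,f2,label", "0.1,1.0,benign", "0.3,2.0,malignant"), tf)
#' read_feature_table(tf)
#' @export
read_feature_table <- function(path, label_col = "label", delim = ",") {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  header <- strsplit(readLines(path, n = 1L), delim, fixed = TRUE)[[1L]]
  if (anyDuplicated(header)) {
    abort(sprintf(
      "Duplicate column names in %s: %s",
      path, paste(unique(header[duplicated(header)]), collapse = ", ")
    ))
  }
  raw <- readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (!label_col %in% names(raw)) {
    abort(sprintf("Label column '%s' not found in %s.", label_col, path))
  }
  feat_names <- setdiff(names(raw), label_col)
  if (anyDuplicated(feat_names)) {
    abort(sprintf(
      "Duplicate feature names in %s: %s",
      path, paste(unique(feat_names[duplicated(feat_names)]), collapse = ", ")
    ))
  }
  out <- raw
  for (nm in feat_names) {
    v <- suppressWarnings(as.numeric(raw[[nm]]))
    bad <- which(is.na(v) & !is.na(raw[[nm]]))
    if (length(bad) > 0L) {
      abort(sprintf(
        "Non-numeric value '%s' at row %d, column '%s'.",
        raw[[nm]][bad[1L]], bad[1L], nm
      ))
    }
    if (anyNA(v)) {
      abort(sprintf(
        "Missing value at row %d, column '%s'.", which(is.na(v))[1L], nm
      ))
    }
    out[[nm]] <- v
  }
  enc <- encode_labels(out[[label_col]])
  if (!identical(enc$levels, c(0, 1))) {
    inform(sprintf(
      "Label mapping: '%s' -> 0, '%s' -> 1.",
      format(enc$levels[1L]), format(enc$levels[2L])
    ))
  }
  out[[label_col]] <- enc$y
  attr(out, "label_levels") <- enc$levels
  out
}

#' Write a labeled feature table to delimited text
#'
#' @param data A data frame with a label column.
#' @param path Output file path.
#' @param delim Field delimiter. Default `","`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(data, path, delim = ",") {
  stopifnot(is.data.frame(data))
  readr::write_delim(as_tibble(data), path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Stratified train/test split
#'
#' Partitions the rows of a labeled table into a train and a test part,
#' preserving per-class proportions within one sample. The same seed always
#' yields the same split.
#'
#' @param data A data frame with a label column; each class needs >= 2 rows.
#' @param test_fraction Fraction of each class assigned to the test part,
#'   in (0, 1). Default 0.2.
#' @param seed Integer seed controlling the assignment.
#' @param label_col Name of the label column.
#' @return A `split_pair`: a list with tibbles `train` and `test`, the row
#'   indices `train_idx`/`test_idx` into `data`, and `label_col`.
#' @examples
#' tbl <- sim_feature_table(n_samples = 40, n_informative = 2, seed = 1)$data
#' sp <- stratified_split(tbl, test_fraction = 0.25, seed = 7)
#' nrow(sp$test)
#' @export
stratified_split <- function(data, test_fraction = 0.2, seed = 1L,
                             label_col = "label") {
  stopifnot(is.numeric(test_fraction), length(test_fraction) == 1L)
  if (test_fraction <= 0 || test_fraction >= 1) {
    abort("`test_fraction` must be in (0, 1).")
  }
  parts <- ft_parts(data, label_col, require_both_classes = TRUE)
  y <- parts$y
  test_idx <- integer(0)
  local_seed(seed, {
    for (cl in sort(unique(y))) {
      rows <- which(y == cl)
      n_cl <- length(rows)
      if (n_cl < 2L) {
        abort(sprintf(
          "Class %s has %d sample(s); need >= 2 to appear in both parts.",
          cl, n_cl
        ))
      }
      n_test <- round(test_fraction * n_cl)
      n_test <- min(max(n_test, 1L), n_cl - 1L)
      test_idx <- c(test_idx, sample(rows, n_test))
    }
  })
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_along(y), test_idx)
  structure(
    list(
      train = as_tibble(data[train_idx, , drop = FALSE]),
      test = as_tibble(data[test_idx, , drop = FALSE]),
      train_idx = train_idx,
      test_idx = test_idx,
      label_col = label_col
    ),
    class = "split_pair"
  )
}

#' @export
print.split_pair <- function(x, ...) {
  cat(sprintf(
    "<split_pair> train: %d rows, test: %d rows, label column '%s'\n",
    nrow(x$train), nrow(x$test), x$label_col
  ))
  invisible(x)
}

#' Standardize features using training statistics
#'
#' Centers and scales every feature column so that the training part has
#' mean 0 and population (divide-by-n) standard deviation 1; the test part is
#' transformed with the training statistics. Constant training columns are
#' mapped to 0 in both parts, which keeps the transform total and
#' deterministic.
#'
#' @param split A `split_pair` from [stratified_split()].
#' @return A `split_pair` with standardized feature columns.
#' @export
standardize_features <- function(split) {
  stopifnot(inherits(split, "split_pair"))
  label_col <- split$label_col
  feat <- setdiff(names(split$train), label_col)
  train <- split$train
  test <- split$test
  for (nm in feat) {
    v <- train[[nm]]
    mu <- mean(v)
    sigma <- sqrt(mean((v - mu)^2)) # population SD
    if (sigma == 0) {
      train[[nm]] <- rep(0, length(v))
      test[[nm]] <- rep(0, nrow(test))
    } else {
      train[[nm]] <- (v - mu) / sigma
      test[[nm]] <- (test[[nm]] - mu) / sigma
    }
  }
  split$train <- train
  split$test <- test
  split
}
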