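# Synthetic data with known ground truth, so the selector can be scored
# against features that are informative, redundant, or pure noise.

#' Simulate a binary-labeled feature table with known ground truth
#'
#' Emulates the kind of deep-feature table the selector consumes: a binary
#' label and three kinds of columns. Informative columns are unit-variance
#' normals whose mean is 0 for class 0 and `class_separation` for class 1;
#' redundant columns are noisy copies of informative columns (source assigned
#' round-robin); noise columns are standard normal, independent of the label.
#' Labels are balanced exactly (class 0 gets the extra sample when
#' `n_samples` is odd). The same seed always reproduces the same table.
#'
#' @param n_samples Number of rows (>= 2).
#' @param n_informative Number of informative features (>= 1).
#' @param n_redundant Number of redundant features (noisy copies).
#' @param n_noise Number of pure-noise features.
#' @param class_separation Gap between class means of informative features,
#'   in within-class SD units. Must be > 0 for recoverable signal;
#'   0 is allowed (for null-model checks).
#' @param redundancy_noise_sd SD of the noise added to redundant copies.
#'   Default 0.1.
#' @param seed Integer seed.
#' @param label_col Name of the label column. Default `"label"`.
#' @return A list with `data` (tibble, columns `inf_*`, `red_*`, `noise_*`
#'   and the label) and `truth` (a `ground_truth` list with
#'   `informative_indices`, `redundant_map` — redundant index -> source
#'   informative index — and `noise_indices`, all 1-based feature indices).
#' @examples
#' out <- sim_feature_table(
#'   n_samples = 200, n_informative = 4, n_redundant = 2,
#'   n_noise = 10, class_separation = 3, seed = 1
#' )
#' dim(out$data)
#' out$truth$informative_indices
#' @export
sim_feature_table <- function(n_samples, n_informative, n_redundant = 0L,
                              n_noise = 0L, class_separation = 3,
                              redundancy_noise_sd = 0.1, seed = 1L,
                              label_col = "label") {
  stopifnot(
    n_samples >= 2, n_informative >= 1, n_redundant >= 0, n_noise >= 0,
    class_separation >= 0, redundancy_noise_sd >= 0
  )
  d <- n_informative + n_redundant + n_noise
  n0 <- ceiling(n_samples / 2)
  y <- as.integer(c(rep(0L, n0), rep(1L, n_samples - n0)))
  x <- matrix(NA_real_, n_samples, d)
  local_seed(seed, {
    for (j in seq_len(n_informative)) {
      x[, j] <- stats::rnorm(n_samples, mean = class_separation * y, sd = 1)
    }
    if (n_redundant > 0) {
      for (r in seq_len(n_redundant)) {
        src <- (r - 1L) %% n_informative + 1L
        x[, n_informative + r] <-
          x[, src] + stats::rnorm(n_samples, sd = redundancy_noise_sd)
      }
    }
    if (n_noise > 0) {
      for (j in seq_len(n_noise)) {
        x[, n_informative + n_redundant + j] <- stats::rnorm(n_samples)
      }
    }
  })
  nm <- c(
    sprintf("inf_%02d", seq_len(n_informative)),
    if (n_redundant > 0) sprintf("red_%02d", seq_len(n_redundant)),
    if (n_noise > 0) sprintf("noise_%02d", seq_len(n_noise))
  )
  data <- as_tibble(setNames(as.data.frame(x), nm))
  data[[label_col]] <- y
  redundant_map <- if (n_redundant > 0) {
    setNames(
      (seq_len(n_redundant) - 1L) %% n_informative + 1L,
      n_informative + seq_len(n_redundant)
    )
  } else {
    integer(0)
  }
  truth <- structure(
    list(
      informative_indices = seq_len(n_informative),
      redundant_map = redundant_map,
      noise_indices =
        if (n_noise > 0) n_informative + n_redundant + seq_len(n_noise)
        else integer(0),
      d = d
    ),
    class = "ground_truth"
  )
  list(data = data, truth = truth)
}

#' Simulate grayscale blob images
#'
#' Small toy images emulating mass/no-mass grayscale patches for extractor
#' smoke tests: positives contain a single bright Gaussian blob at a random
#' center and width over background texture; negatives contain background
#' texture only. Pixel values lie in [0, 1].
#'
#' @param n_images Number of images.
#' @param size Image side length in pixels (>= 32).
#' @param with_mass_fraction Fraction of positive (blob) images; positives
#'   are the first `round(n_images * with_mass_fraction)` images.
#' @param seed Integer seed; the same seed reproduces identical pixels.
#' @return A list with `images` (list of `size` x `size` matrices) and
#'   `labels` (integer 0/1 vector).
#' @examples
#' batch <- sim_blob_images(n_images = 4, size = 32, seed = 0)
#' sapply(batch$images, max)
#' @export
sim_blob_images <- function(n_images, size = 64L, with_mass_fraction = 0.5,
                            seed = 1L) {
  stopifnot(n_images >= 1, size >= 32, with_mass_fraction >= 0,
            with_mass_fraction <= 1)
  n_pos <- round(n_images * with_mass_fraction)
  labels <- as.integer(c(rep(1L, n_pos), rep(0L, n_images - n_pos)))
  coords <- expand.grid(row = seq_len(size), col = seq_len(size))
  images <- local_seed(seed, {
    lapply(seq_len(n_images), function(i) {
      # low-amplitude smooth background: coarse noise + gentle gradient
      bg <- 0.25 + 0.05 * matrix(stats::rnorm(size^2), size, size)
      grad <- outer(seq_len(size), seq_len(size), function(r, c2) {
        0.05 * (r + c2) / (2 * size)
      })
      img <- bg + grad
      if (labels[i] == 1L) {
        cx <- stats::runif(1, 0.25 * size, 0.75 * size)
        cy <- stats::runif(1, 0.25 * size, 0.75 * size)
        width <- stats::runif(1, 0.05 * size, 0.12 * size)
        blob <- 0.7 * exp(-((coords$row - cx)^2 + (coords$col - cy)^2) /
                            (2 * width^2))
        img <- img + matrix(blob, size, size)
      }
      pmin(pmax(img, 0), 1)
    })
  })
  list(images = images, labels = labels)
}

#' Write images as 8-bit grayscale PNG files
#'
#' @param images List of numeric matrices with values in [0, 1].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix. Files are `<prefix>_0001.png`, ...
#' @return Character vector of file paths, invisibly.
#' @export
write_blob_pngs <- function(images, dir, prefix = "img") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(images))
  for (i in seq_along(images)) {
    paths[i] <- file.path(dir, sprintf("%s_%04d.png", prefix, i))
    png::writePNG(images[[i]], paths[i])
  }
  invisible(paths)
}

#' Read grayscale PNG images from a directory
#'
#' Non-PNG files are skipped with a warning. RGB images are converted to
#' grayscale by channel averaging.
#'
#' @param dir Directory containing `.png` files.
#' @return A list of numeric matrices in [0, 1], named by file.
#' @export
read_image_dir <- function(dir) {
  if (!dir.exists(dir)) abort(sprintf("Directory not found: %s", dir))
  files <- sort(list.files(dir, full.names = TRUE))
  if (length(files) == 0L) abort(sprintf("No files in %s", dir))
  keep <- grepl("\\.png$", files, ignore.case = TRUE)
  if (any(!keep)) {
    warn(sprintf("Skipping %d non-PNG file(s) in %s.", sum(!keep), dir))
  }
  files <- files[keep]
  if (length(files) == 0L) abort(sprintf("No PNG files in %s", dir))
  imgs <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3L) img <- apply(img[, , 1:3, drop = FALSE], c(1, 2), mean)
    img
  })
  names(imgs) <- basename(files)
  imgs
}

#' Write ground truth to JSON
#'
#' @param truth A `ground_truth` object from [sim_feature_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(
    list(
      informative_indices = truth$informative_indices,
      redundant_map = as.list(truth$redundant_map),
      noise_indices = truth$noise_indices,
      d = truth$d
    ),
    path,
    auto_unbox = FALSE, pretty = TRUE
  )
  invisible(path)
}

#' Read ground truth from JSON
#'
#' @param path Path written by [write_ground_truth()].
#' @return A `ground_truth` object.
#' @export
read_ground_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rm_map <- unlist(obj$redundant_map)
  structure(
    list(
      informative_indices = as.integer(obj$informative_indices),
      redundant_map =
        if (length(rm_map)) setNames(as.integer(rm_map), names(rm_map))
        else integer(0),
      noise_indices = as.integer(obj$noise_indices),
      d = as.integer(obj$d)
    ),
    class = "ground_truth"
  )
}
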