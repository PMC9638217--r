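# Attention-aided VGG-style deep feature extractor, implemented natively:
# a frozen stack of 3x3 convolution blocks with max-pooling (VGG16 layout
# and channel widths by default), a 1x1 locally-connected attention layer
# (per-position weights, sigmoid activation so weights are nonnegative and
# never all zero), attention-weighted global average pooling renormalized by
# the attention mass, a dropout-regularized dense bottleneck whose
# activations are the exported deep features, and a 1-unit sigmoid head.
# Convolutions run as im2col + BLAS matrix products; head fine-tuning is
# plain SGD with analytic backpropagation through everything above the
# frozen backbone.

#' Build an attention-aided convolutional feature extractor
#'
#' The backbone is a VGG16-layout convolutional stack (3x3 kernels, ReLU,
#' 2x2 max-pooling; channel widths 64-128-256-512-512 with 2-2-3-3-3
#' convolutions per block) with randomly initialized, frozen weights. On top
#' sit a 1x1 locally-connected attention layer with sigmoid activation, a
#' weighted global-average-pooling step ([weighted_gap()]), dropout, a dense
#' bottleneck of `feature_dim` units (the exported features), dropout, and a
#' sigmoid output unit. Only the layers above the backbone are trainable.
#'
#' @param input_height,input_width Expected image size in pixels.
#'   Defaults 299 x 299; images of other sizes are resampled on input.
#' @param feature_dim Bottleneck width = exported feature count. Default 128.
#' @param block_channels Channel widths of the five convolution blocks.
#' @param convs_per_block Convolutions per block.
#' @param dropout_rates Dropout rates before and after the bottleneck.
#'   Default `c(0.5, 0.25)`.
#' @param batch_size Minibatch size for training. Default 64.
#' @param initial_learning_rate SGD learning rate. Default 1e-2.
#' @param lr_halving_epoch Epoch after which the learning rate is halved.
#'   Default 3.
#' @param backbone_frozen Must be `TRUE`: backbone weights are never updated.
#' @param seed Seed for weight initialization.
#' @return An object of class `cnn_extractor`.
#' @examples
#' model <- build_extractor(input_height = 32, input_width = 32, seed = 1)
#' model
#' @export
build_extractor <- function(input_height = 299L, input_width = 299L,
                            feature_dim = 128L,
                            block_channels = c(64L, 128L, 256L, 512L, 512L),
                            convs_per_block = c(2L, 2L, 3L, 3L, 3L),
                            dropout_rates = c(0.5, 0.25),
                            batch_size = 64L,
                            initial_learning_rate = 1e-2,
                            lr_halving_epoch = 3L,
                            backbone_frozen = TRUE,
                            seed = 1L) {
  stopifnot(
    feature_dim >= 1, length(block_channels) == length(convs_per_block),
    all(dropout_rates >= 0), all(dropout_rates < 1),
    length(dropout_rates) == 2L
  )
  if (!isTRUE(backbone_frozen)) {
    abort("Only a frozen backbone is supported; set `backbone_frozen = TRUE`.")
  }
  min_size <- 2^length(block_channels)
  if (input_height < min_size || input_width < min_size) {
    abort(sprintf("Input must be at least %d x %d pixels.", min_size, min_size))
  }
  hh <- as.integer(input_height)
  ww <- as.integer(input_width)
  local_seed(seed, {
    blocks <- list()
    cin <- 3L
    for (b in seq_along(block_channels)) {
      cout <- block_channels[b]
      convs <- list()
      for (i in seq_len(convs_per_block[b])) {
        convs[[i]] <- list(
          W = matrix(
            stats::rnorm(9L * cin * cout, sd = sqrt(2 / (9 * cin))),
            9L * cin, cout
          ),
          b = rep(0, cout)
        )
        cin <- cout
      }
      blocks[[b]] <- convs
      hh <- hh %/% 2L
      ww <- ww %/% 2L
    }
    n_pos <- hh * ww
    n_chan <- block_channels[length(block_channels)]
    head <- list(
      att_W = matrix(stats::rnorm(n_pos * n_chan, sd = 0.01), n_pos, n_chan),
      att_b = rep(0, n_pos),
      W1 = matrix(
        stats::rnorm(feature_dim * n_chan, sd = sqrt(2 / n_chan)),
        feature_dim, n_chan
      ),
      b1 = rep(0, feature_dim),
      w2 = stats::rnorm(feature_dim, sd = sqrt(1 / feature_dim)),
      b2 = 0
    )
    structure(
      list(
        cfg = list(
          input_height = as.integer(input_height),
          input_width = as.integer(input_width),
          feature_dim = as.integer(feature_dim),
          block_channels = as.integer(block_channels),
          convs_per_block = as.integer(convs_per_block),
          dropout_rates = dropout_rates,
          batch_size = as.integer(batch_size),
          initial_learning_rate = initial_learning_rate,
          lr_halving_epoch = as.integer(lr_halving_epoch),
          backbone_frozen = TRUE,
          map_height = hh, map_width = ww, n_channels = n_chan,
          seed = as.integer(seed)
        ),
        backbone = blocks,
        head = head
      ),
      class = "cnn_extractor"
    )
  })
}

#' @export
print.cnn_extractor <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf(
    paste0(
      "<cnn_extractor> attention-aided VGG-style extractor\n",
      "  input %dx%d -> %d blocks (%s channels) -> %dx%dx%d maps\n",
      "  attention-weighted GAP -> bottleneck %d (features) -> sigmoid\n"
    ),
    cfg$input_height, cfg$input_width, length(x$backbone),
    paste(cfg$block_channels, collapse = "/"),
    cfg$map_height, cfg$map_width, cfg$n_channels, cfg$feature_dim
  ))
  invisible(x)
}

# 3x3 same-padding convolution via im2col; returns H x W x Cout.
conv3x3 <- function(x, W, b) {
  h <- dim(x)[1]
  w <- dim(x)[2]
  cin <- dim(x)[3]
  cout <- ncol(W)
  padded <- array(0, c(h + 2L, w + 2L, cin))
  padded[2:(h + 1L), 2:(w + 1L), ] <- x
  cols <- matrix(0, h * w, 9L * cin)
  pos <- 1L
  for (dj in 0:2) {
    for (di in 0:2) {
      blk <- padded[(1L + di):(h + di), (1L + dj):(w + dj), , drop = FALSE]
      cols[, pos:(pos + cin - 1L)] <- matrix(blk, h * w, cin)
      pos <- pos + cin
    }
  }
  out <- cols %*% W
  out <- out + rep(b, each = h * w)
  array(out, c(h, w, cout))
}

maxpool2 <- function(x) {
  h2 <- dim(x)[1] %/% 2L
  w2 <- dim(x)[2] %/% 2L
  a <- x[seq_len(2L * h2), seq_len(2L * w2), , drop = FALSE]
  r1 <- seq(1L, 2L * h2, 2L)
  r2 <- seq(2L, 2L * h2, 2L)
  c1 <- seq(1L, 2L * w2, 2L)
  c2 <- seq(2L, 2L * w2, 2L)
  pmax(
    a[r1, c1, , drop = FALSE], a[r2, c1, , drop = FALSE],
    a[r1, c2, , drop = FALSE], a[r2, c2, , drop = FALSE]
  )
}

# Nearest-neighbour resize of a grayscale matrix.
resize_nn <- function(img, h, w) {
  ri <- pmin(pmax(round(seq(1, nrow(img), length.out = h)), 1), nrow(img))
  ci <- pmin(pmax(round(seq(1, ncol(img), length.out = w)), 1), ncol(img))
  img[ri, ci, drop = FALSE]
}

# Frozen backbone forward pass: grayscale matrix (or HxWx3 array) -> feature
# maps H' x W' x C. Grayscale input is replicated to 3 channels.
backbone_forward <- function(model, img) {
  cfg <- model$cfg
  if (is.matrix(img)) {
    if (nrow(img) != cfg$input_height || ncol(img) != cfg$input_width) {
      inform(sprintf(
        "Resampling image from %dx%d to %dx%d.",
        nrow(img), ncol(img), cfg$input_height, cfg$input_width
      ))
      img <- resize_nn(img, cfg$input_height, cfg$input_width)
    }
    x <- array(rep(img, 3L), c(dim(img), 3L))
  } else {
    stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
    x <- img
  }
  for (block in model$backbone) {
    for (conv in block) {
      x <- conv3x3(x, conv$W, conv$b)
      x <- pmax(x, 0)
    }
    x <- maxpool2(x)
  }
  x
}

#' Attention-weighted global average pooling
#'
#' Per channel `c`, returns
#' `sum_p a_p * f_pc / sum_p a_p` — the spatial average of the feature maps
#' weighted by a nonnegative attention map and renormalized by the attention
#' mass. Under a uniform attention map this reduces exactly to plain global
#' average pooling, and rescaling the attention map by any positive constant
#' leaves the output unchanged.
#'
#' @param feature_maps Numeric array H x W x C.
#' @param attention_map Nonnegative H x W matrix (or H x W x 1 array), not
#'   identically zero.
#' @return Numeric vector of length C.
#' @examples
#' f <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
#' all.equal(weighted_gap(f, matrix(1, 4, 4)), apply(f, 3, mean))
#' @export
weighted_gap <- function(feature_maps, attention_map) {
  stopifnot(length(dim(feature_maps)) == 3L)
  if (length(dim(attention_map)) == 3L) {
    stopifnot(dim(attention_map)[3] == 1L)
    attention_map <- attention_map[, , 1L]
  }
  stopifnot(all(dim(attention_map) == dim(feature_maps)[1:2]))
  if (any(attention_map < 0)) abort("Attention weights must be nonnegative.")
  s <- sum(attention_map)
  if (s == 0) abort("Attention map is identically zero: average undefined.")
  p <- prod(dim(feature_maps)[1:2])
  cc <- dim(feature_maps)[3]
  as.vector(
    crossprod(matrix(feature_maps, p, cc), as.vector(attention_map))
  ) / s
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Head forward pass from backbone feature maps. In training mode, inverted
# dropout masks are drawn from `stream`; in inference mode dropout is off
# and the pass is deterministic.
head_forward <- function(model, fmaps, training = FALSE, stream = NULL) {
  cfg <- model$cfg
  hd <- model$head
  p <- cfg$map_height * cfg$map_width
  fmat <- matrix(fmaps, p, cfg$n_channels)
  logits <- rowSums(fmat * hd$att_W) + hd$att_b
  a <- sigmoid(logits)
  s <- sum(a)
  g <- as.vector(crossprod(fmat, a)) / s
  p1 <- cfg$dropout_rates[1L]
  p2 <- cfg$dropout_rates[2L]
  if (training) {
    m1 <- as.numeric(stream_runif(stream, length(g)) >= p1) / (1 - p1)
    g_d <- g * m1
  } else {
    m1 <- NULL
    g_d <- g
  }
  pre1 <- as.vector(hd$W1 %*% g_d) + hd$b1
  z <- pmax(pre1, 0)
  if (training) {
    m2 <- as.numeric(stream_runif(stream, length(z)) >= p2) / (1 - p2)
    z_d <- z * m2
  } else {
    m2 <- NULL
    z_d <- z
  }
  y_hat <- sigmoid(sum(hd$w2 * z_d) + hd$b2)
  list(
    fmat = fmat, a = a, s = s, g = g, g_d = g_d, m1 = m1,
    pre1 = pre1, z = z, z_d = z_d, m2 = m2, y_hat = y_hat
  )
}

# Analytic gradients of the binary cross-entropy w.r.t. the trainable head
# parameters (backbone frozen; no gradient flows into it).
head_gradients <- function(model, fw, y) {
  hd <- model$head
  delta_y <- fw$y_hat - y
  grad_w2 <- delta_y * fw$z_d
  grad_b2 <- delta_y
  delta_zd <- delta_y * hd$w2
  delta_z <- if (is.null(fw$m2)) delta_zd else delta_zd * fw$m2
  delta_pre1 <- delta_z * (fw$pre1 > 0)
  grad_W1 <- outer(delta_pre1, fw$g_d)
  grad_b1 <- delta_pre1
  delta_gd <- as.vector(crossprod(hd$W1, delta_pre1))
  delta_g <- if (is.null(fw$m1)) delta_gd else delta_gd * fw$m1
  delta_a <- (as.vector(fw$fmat %*% delta_g) - sum(delta_g * fw$g)) / fw$s
  delta_l <- delta_a * fw$a * (1 - fw$a)
  list(
    att_W = fw$fmat * delta_l, # row p scaled by delta_l[p]
    att_b = delta_l,
    W1 = grad_W1, b1 = grad_b1, w2 = grad_w2, b2 = grad_b2
  )
}

#' Fine-tune the extractor head on labeled images
#'
#' Trains the attention layer, bottleneck and output unit by minibatch SGD
#' on binary cross-entropy; the convolutional backbone stays frozen, so its
#' activations are computed once per image and cached across epochs. The
#' learning rate is halved after `lr_halving_epoch` epochs.
#'
#' @param model A `cnn_extractor`.
#' @param images List of grayscale matrices in `[0, 1]`.
#' @param labels Integer 0/1 vector, one per image.
#' @param epochs Number of passes over the data. Default 2.
#' @param seed Seed for the dropout masks.
#' @return The model with updated head weights; the per-epoch mean loss is
#'   attached as attribute `"loss_history"`.
#' @export
train_extractor <- function(model, images, labels, epochs = 2L, seed = 1L) {
  stopifnot(inherits(model, "cnn_extractor"))
  if (length(images) == 0L) abort("Empty image batch.")
  if (length(images) != length(labels)) {
    abort("`images` and `labels` must have equal length.")
  }
  cfg <- model$cfg
  cached <- lapply(images, function(im) backbone_forward(model, im))
  stream <- rng_streams(seed, 1L)[[1L]]
  n <- length(images)
  batches <- split(seq_len(n), ceiling(seq_len(n) / cfg$batch_size))
  losses <- numeric(epochs)
  for (epoch in seq_len(epochs)) {
    lr <- cfg$initial_learning_rate *
      if (epoch > cfg$lr_halving_epoch) 0.5 else 1
    epoch_loss <- 0
    for (batch in batches) {
      acc <- NULL
      for (i in batch) {
        fw <- head_forward(model, cached[[i]], training = TRUE,
                           stream = stream)
        eps <- 1e-12
        epoch_loss <- epoch_loss -
          (labels[i] * log(fw$y_hat + eps) +
             (1 - labels[i]) * log(1 - fw$y_hat + eps))
        gr <- head_gradients(model, fw, labels[i])
        if (is.null(acc)) {
          acc <- gr
        } else {
          for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + gr[[nm]]
        }
      }
      scale <- lr / length(batch)
      for (nm in names(acc)) {
        model$head[[nm]] <- model$head[[nm]] - scale * acc[[nm]]
      }
    }
    losses[epoch] <- epoch_loss / n
  }
  attr(model, "loss_history") <- losses
  model
}

#' Extract deep features from images
#'
#' Runs the extractor in inference mode (dropout disabled, deterministic)
#' and returns the bottleneck activations — one `feature_dim`-vector per
#' image — as a tibble ready for [ssd_select()].
#'
#' @param model A `cnn_extractor`.
#' @param images List of grayscale matrices in `[0, 1]` (resampled to the
#'   configured input size if needed).
#' @param labels Optional integer 0/1 vector appended as a label column.
#' @param label_col Name for the label column. Default `"label"`.
#' @return A tibble with columns `feat_001` ... `feat_<feature_dim>` and,
#'   when labels are given, the label column.
#' @export
extract_features <- function(model, images, labels = NULL,
                             label_col = "label") {
  stopifnot(inherits(model, "cnn_extractor"))
  if (length(images) == 0L) abort("Empty image batch.")
  feats <- t(vapply(images, function(im) {
    fw <- head_forward(model, backbone_forward(model, im), training = FALSE)
    fw$z
  }, numeric(model$cfg$feature_dim)))
  colnames(feats) <- sprintf("feat_%03d", seq_len(model$cfg$feature_dim))
  out <- as_tibble(as.data.frame(feats))
  if (!is.null(labels)) {
    if (length(labels) != length(images)) {
      abort("`labels` must match the number of images.")
    }
    out[[label_col]] <- as.integer(labels)
  }
  out
}

#' Classify images with the extractor's sigmoid head
#'
#' @param model A `cnn_extractor`.
#' @param images List of grayscale matrices.
#' @return Numeric vector of sigmoid outputs in (0, 1).
#' @export
predict_extractor <- function(model, images) {
  vapply(images, function(im) {
    head_forward(model, backbone_forward(model, im), training = FALSE)$y_hat
  }, numeric(1))
}
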