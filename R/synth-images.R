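#' Generate a labeled toy image dataset
#'
#' Procedurally draws small RGB images, each showing one textured patch
#' of its category's color/pattern family on a black background. The
#' families are separable by a small classifier, which makes the dataset
#' sufficient to train the mock backbone without any downloads.
#'
#' @param n_categories Number of categories.
#' @param n_per_category Images per category.
#' @param image_size Side length in pixels (>= 32).
#' @param seed RNG seed.
#' @return List with `images` (list of H x W x 3 arrays in `[0, 255]`),
#'   `labels` (factor) and `meta` (data frame).
#' @export
gen_image_dataset <- function(n_categories = 10L, n_per_category = 20L,
                              image_size = 64L, seed = 1L) {
  n_categories <- check_count(n_categories, "n_categories")
  n_per_category <- check_count(n_per_category, "n_per_category")
  image_size <- check_count(image_size, "image_size", min = 32L)
  with_seed(seed, {
    n <- n_categories * n_per_category
    labels <- factor(rep(sprintf("cat%03d", seq_len(n_categories)),
                         each = n_per_category))
    images <- vector("list", n)
    for (i in seq_len(n)) {
      cat_i <- (i - 1L) %/% n_per_category + 1L
      images[[i]] <- draw_texture_object(cat_i, image_size)
    }
    list(images = images, labels = labels,
         meta = data.frame(image_id = sprintf("img%05d", seq_len(n)),
                           label = labels, stringsAsFactors = FALSE))
  })
}

# One textured object of category `k` on black background. Each category is
# a fixed (color, pattern, spatial period) family; position/size/phase vary
# per draw. Consumes the caller's RNG stream.
draw_texture_object <- function(k, size) {
  palette <- rbind(
    c(230, 60, 60), c(60, 200, 60), c(70, 90, 235), c(225, 210, 50),
    c(210, 60, 210), c(50, 200, 210), c(240, 140, 40), c(140, 220, 120),
    c(150, 90, 220), c(200, 200, 200))
  col <- palette[(k - 1L) %% nrow(palette) + 1L, ]
  pattern <- (k - 1L) %% 5L        # solid, h-stripes, v-stripes, checker, rings
  period <- 4L + 2L * ((k - 1L) %/% 5L)
  half <- floor(size / 2)
  side <- sample(seq(half, size - 4L), 1L)
  x0 <- sample.int(size - side, 1L)
  y0 <- sample.int(size - side, 1L)
  phase <- sample.int(period, 1L)
  ix <- outer(seq_len(side), rep(1, side))
  iy <- t(ix)
  m <- switch(pattern + 1L,
              matrix(1, side, side),
              ((ix + phase) %/% period) %% 2L,
              ((iy + phase) %/% period) %% 2L,
              (((ix + phase) %/% period) + ((iy + phase) %/% period)) %% 2L,
              (floor(sqrt((ix - side / 2)^2 + (iy - side / 2)^2) + phase) %/% period) %% 2L)
  img <- array(0, dim = c(size, size, 3L))
  tex <- 0.45 + 0.55 * m
  tex <- tex * matrix(stats::runif(side * side, 0.9, 1.1), side)
  for (ch in 1:3)
    img[y0 + seq_len(side) - 1L, x0 + seq_len(side) - 1L, ch] <- pmin(col[ch] * tex, 255)
  img
}

# Block-mean resize of an H x W x 3 array to size x size, via row/column
# averaging operators (exact mean pooling for integer ratios, length-
# weighted block means otherwise).
resize_image <- function(img, size) {
  avg_op <- function(n_in, n_out) {
    op <- matrix(0, n_out, n_in)
    breaks <- floor(seq(0, n_in, length.out = n_out + 1L))
    breaks[n_out + 1L] <- n_in
    for (i in seq_len(n_out)) {
      idx <- (breaks[i] + 1L):max(breaks[i + 1L], breaks[i] + 1L)
      op[i, idx] <- 1 / length(idx)
    }
    op
  }
  d <- dim(img)
  R <- avg_op(d[1L], size)
  C <- t(avg_op(d[2L], size))
  out <- array(0, dim = c(size, size, 3L))
  for (ch in 1:3) out[, , ch] <- R %*% img[, , ch] %*% C
  out
}

new_backbone <- function(conv_w, cls_w, categories, trained, input_size, grid, seed) {
  structure(list(conv_w = conv_w, cls_w = cls_w, categories = categories,
                 trained = trained, input_size = input_size, grid = grid,
                 seed = seed),
            class = "numsense_backbone")
}

#' @export
print.numsense_backbone <- function(x, ...) {
  cat(sprintf("<numsense_backbone> %s, %d categories, input %dx%d, conv %dx%dx%d\n",
              if (x$trained) "trained" else "untrained (random weights)",
              length(x$categories), x$input_size, x$input_size,
              nrow(x$conv_w), x$grid, x$grid))
  invisible(x)
}

# Deterministic forward pass. The "last_conv" layer is a C x g x g map:
# per grid cell, the mean RGB plus the mean absolute-gradient (edge
# energy) per channel are passed through a fixed random 1x1 mixing +
# ReLU. Color separates the toy categories; edge energy carries their
# texture frequency and is what pixel noise saturates. The classifier
# layer is a linear readout of the flattened conv map (pre-softmax
# category scores), one unit per category.
backbone_forward <- function(backbone, img) {
  small <- resize_image(img, backbone$input_size) / 255
  g <- backbone$grid
  n <- backbone$input_size
  edges <- small
  for (ch in 1:3) {
    m <- small[, , ch]
    dx <- cbind(abs(m[, -1] - m[, -n]), 0)
    dy <- rbind(abs(m[-1, ] - m[-n, ]), 0)
    edges[, , ch] <- (dx + dy) / 2
  }
  cells <- resize_image(small * 255, g) / 255      # 3-channel g x g cell means
  ecells <- resize_image(edges * 255, g) / 255     # per-cell edge energy
  # divisive (contrast) normalization of the edge channel: per-cell edge
  # energy relative to the picture's global edge energy
  ecells <- 0.1 * ecells / (mean(ecells) + 1e-3)
  x <- rbind(as.vector(cells[, , 1]), as.vector(cells[, , 2]),
             as.vector(cells[, , 3]),
             as.vector(ecells[, , 1]), as.vector(ecells[, , 2]),
             as.vector(ecells[, , 3]))             # 6 x g^2
  conv <- pmax(backbone$conv_w %*% x, 0)           # C x g^2, ReLU
  feat <- as.vector(conv)
  scores <- NULL
  if (!is.null(backbone$cls_w)) {
    scores <- as.vector(backbone$cls_w %*% c(1, feat))
    names(scores) <- backbone$categories
  }
  list(classifier = scores, last_conv = feat)
}

backbone_features <- function(backbone, images) {
  t(vapply(images, function(im) backbone_forward(backbone, im)$last_conv,
           numeric(nrow(backbone$conv_w) * backbone$grid^2)))
}

#' Untrained mock backbone (random weights)
#'
#' Mirrors the untrained-network control: same architecture as the
#' trained mock backbone, classifier weights drawn at random.
#'
#' @param n_categories Width of the classifier layer.
#' @param seed RNG seed (also fixes the conv mixing weights).
#' @param input_size,grid,n_conv Architecture parameters: input side
#'   length, pooling grid, conv channels.
#' @return A `numsense_backbone` with `trained = FALSE`.
#' @export
untrained_mock_backbone <- function(n_categories = 10L, seed = 1L,
                                    input_size = 64L, grid = 4L, n_conv = 8L) {
  with_seed(derive_seed(seed, "untrained"), {
    conv_w <- matrix(stats::rnorm(n_conv * 6), n_conv, 6)
    cls_w <- matrix(stats::rnorm(n_categories * (n_conv * grid^2 + 1), sd = 0.5),
                    n_categories)
    new_backbone(conv_w, cls_w, sprintf("cat%03d", seq_len(n_categories)),
                 trained = FALSE, input_size = input_size, grid = grid, seed = seed)
  })
}

#' Train the mock backbone on labeled images
#'
#' Fits the classifier layer (multinomial logistic regression over the
#' fixed random conv features) with full-batch Adam. Training is seeded
#' and reproducible; the result satisfies the backbone contract used by
#' [extract_activations()].
#'
#' @param images List of H x W x 3 arrays in `[0, 255]`.
#' @param labels Factor (or coercible) of category labels, one per image.
#' @param epochs Training epochs.
#' @param seed RNG seed.
#' @param lr Adam learning rate.
#' @param input_size,grid,n_conv Architecture parameters.
#' @return A `numsense_backbone` with `trained = TRUE`.
#' @export
train_mock_backbone <- function(images, labels, epochs = 200L, seed = 1L,
                                lr = 0.05, input_size = 64L, grid = 4L,
                                n_conv = 8L) {
  labels <- factor(labels)
  if (length(images) != length(labels))
    stopf("train_mock_backbone: %d images but %d labels",
          length(images), length(labels))
  if (nlevels(labels) < 2L)
    stopf("train_mock_backbone: need >= 2 categories, got %d", nlevels(labels))
  with_seed(derive_seed(seed, "convw"), {
    conv_w <- matrix(stats::rnorm(n_conv * 6), n_conv, 6)
  })
  bb <- new_backbone(conv_w, NULL, levels(labels), trained = FALSE,
                     input_size = input_size, grid = grid, seed = seed)
  X <- cbind(1, backbone_features(bb, images))
  Y <- diag(nlevels(labels))[as.integer(labels), , drop = FALSE]
  W <- softmax_fit(X, Y, epochs = epochs, lr = lr,
                   seed = derive_seed(seed, "clsw"))
  new_backbone(conv_w, t(W), levels(labels), trained = TRUE,
               input_size = input_size, grid = grid, seed = seed)
}

# Full-batch Adam on the multinomial cross-entropy; returns P x K weights.
softmax_fit <- function(X, Y, epochs, lr, seed) {
  with_seed(seed, {
    W <- matrix(stats::rnorm(ncol(X) * ncol(Y), sd = 0.01), ncol(X))
    m <- v <- W * 0
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    for (t in seq_len(epochs)) {
      Z <- X %*% W
      Z <- Z - apply(Z, 1, max)
      P <- exp(Z); P <- P / rowSums(P)
      G <- crossprod(X, P - Y) / nrow(X)
      m <- b1 * m + (1 - b1) * G
      v <- b2 * v + (1 - b2) * G^2
      W <- W - lr * (m / (1 - b1^t)) / (sqrt(v / (1 - b2^t)) + eps)
    }
    W
  })
}

#' Classify images with a mock backbone
#'
#' @param backbone A `numsense_backbone`.
#' @param images List of images.
#' @return Character vector of predicted category labels (argmax of the
#'   classifier layer).
#' @export
predict_backbone <- function(backbone, images) {
  vapply(images, function(im) {
    s <- backbone_forward(backbone, im)$classifier
    backbone$categories[which.max(s)]
  }, character(1))
}
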