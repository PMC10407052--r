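#' Set of monotonically tuned units
#'
#' @param increasing,decreasing Disjoint integer unit indices.
#' @param alpha Selection threshold used.
#' @param layer Layer tag.
#' @param n_units Width of the layer the indices refer to.
#' @return A `unit_set` object.
#' @export
unit_set <- function(increasing, decreasing = integer(0), alpha = 0.1,
                     layer = "classifier", n_units = NA_integer_) {
  increasing <- sort(unique(as.integer(increasing)))
  decreasing <- sort(unique(as.integer(decreasing)))
  if (length(intersect(increasing, decreasing)))
    stopf("unit_set: increasing and decreasing sets overlap")
  structure(list(increasing = increasing, decreasing = decreasing,
                 alpha = alpha, layer = layer, n_units = n_units),
            class = "unit_set")
}

#' @export
print.unit_set <- function(x, ...) {
  cat(sprintf("<unit_set> %d increasing, %d decreasing (alpha = %g, layer %s)\n",
              length(x$increasing), length(x$decreasing), x$alpha, x$layer))
  invisible(x)
}

#' Select monotonically tuned units
#'
#' A unit is *increasing* iff its group-mean activation is strictly
#' increasing over the numerosity levels AND every consecutive-pair
#' difference is significant at `alpha` (Welch two-sample t-test across
#' pictures; default alpha 0.1, no multiple-testing correction --
#' the threshold is a screening criterion). *Decreasing* is defined
#' symmetrically. On the classifier layer of the full-scale analysis
#' this yields the 48 increasing / 13 decreasing units; on the last
#' convolutional layer, 16 / 24.
#'
#' @param acts An `activation_matrix` (normalized rows recommended).
#' @param groups Group labels (default from metadata); all levels must
#'   have >= 2 pictures.
#' @param alpha Per-pair significance threshold.
#' @return A [unit_set()].
#' @export
select_monotone_units <- function(acts, groups = NULL, alpha = 0.1) {
  if (is.matrix(acts)) acts <- activation_matrix(acts)
  groups <- groups %||% acts$meta$group
  if (is.null(groups)) stopf("select_monotone_units: no group labels")
  g <- factor(groups)
  k <- nlevels(g)
  if (k < 2L) stopf("select_monotone_units: need >= 2 groups")
  n <- as.vector(table(g))
  if (any(n < 2L))
    stopf("select_monotone_units: missing or singleton group '%s'",
          levels(g)[which(n < 2L)[1L]])
  s <- group_summary(acts, groups)
  m <- s$mean; v <- s$sd^2
  p <- dir <- matrix(NA_real_, k - 1L, ncol(m))
  for (i in seq_len(k - 1L)) {
    se2 <- v[i, ] / n[i] + v[i + 1L, ] / n[i + 1L]
    tt <- (m[i + 1L, ] - m[i, ]) / sqrt(se2)
    df <- se2^2 / ((v[i, ] / n[i])^2 / (n[i] - 1) + (v[i + 1L, ] / n[i + 1L])^2 / (n[i + 1L] - 1))
    p[i, ] <- 2 * stats::pt(-abs(tt), df)
    dir[i, ] <- sign(m[i + 1L, ] - m[i, ])
  }
  sig <- apply(p, 2L, function(col) all(is.finite(col) & col < alpha))
  inc <- which(sig & apply(dir, 2L, function(d) all(d > 0)))
  dec <- which(sig & apply(dir, 2L, function(d) all(d < 0)))
  unit_set(inc, dec, alpha = alpha, layer = acts$layer, n_units = ncol(m))
}

#' Train the numerosity-decoding network
#'
#' Fits the small decoding network -- selected-unit activations as
#' input, one fully connected hidden layer (default 2000 units), one
#' output unit whose response is the estimated number of objects -- by
#' full-batch Adam on mean squared error against the integer counts,
#' with a seeded 90/10 train/validation split and early stopping on a
#' validation plateau.
#'
#' @param acts Normalized `activation_matrix` used for training.
#' @param units A [unit_set()] (non-empty).
#' @param targets Integer counts per picture (default: group metadata).
#' @param hidden Hidden-layer width (default 2000).
#' @param epochs,lr,patience,val_frac Training hyperparameters.
#' @param seed RNG seed.
#' @return A `num_decoder` holding the fitted network, the unit
#'   indices, and the training history.
#' @export
train_decoder <- function(acts, units, targets = NULL, hidden = 2000L,
                          epochs = 300L, lr = 0.01, seed = 1L,
                          patience = 25L, val_frac = 0.1) {
  targets <- targets %||% acts$meta$group
  if (is.null(targets)) stopf("train_decoder: no targets")
  idx <- c(units$increasing, units$decreasing)
  if (length(idx) == 0L) stopf("train_decoder: no informative units in the unit set")
  if (max(idx) > ncol(acts$values))
    stopf("train_decoder: unit index %d exceeds layer width %d",
          max(idx), ncol(acts$values))
  X <- acts$values[, idx, drop = FALSE]
  model <- mlp_train(X, as.numeric(targets), hidden = hidden, epochs = epochs,
                     lr = lr, seed = seed, patience = patience,
                     val_frac = val_frac)
  structure(list(model = model, units = units, unit_index = idx,
                 layer = acts$layer, seed = seed),
            class = "num_decoder")
}

#' @export
print.num_decoder <- function(x, ...) {
  cat(sprintf("<num_decoder> %d input units -> %d hidden -> 1 (trained %d epochs, val MSE %.4f)\n",
              length(x$unit_index), x$model$hidden,
              x$model$config$stopped_at, min(x$model$history$val_mse)))
  invisible(x)
}

#' Decode per-picture numerosity estimates
#'
#' @param decoder A [train_decoder()] model.
#' @param acts Normalized `activation_matrix` whose columns align with
#'   the decoder's layer.
#' @return Numeric vector of real-valued numerosity estimates, one per
#'   picture; deterministic.
#' @export
decode <- function(decoder, acts) {
  v <- if (inherits(acts, "activation_matrix")) acts$values else as.matrix(acts)
  if (max(decoder$unit_index) > ncol(v))
    stopf("decode: activation width %d does not cover unit index %d",
          ncol(v), max(decoder$unit_index))
  mlp_predict(decoder$model, v[, decoder$unit_index, drop = FALSE])
}
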