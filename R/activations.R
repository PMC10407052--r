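#' Activation matrix container
#'
#' A pictures x units response table together with per-picture metadata
#' (picture id, numerosity group, variant) and a layer tag. Rows are raw
#' responses until [normalize_unit_range()] maps each picture's responses
#' to the unit interval.
#'
#' @param values Numeric matrix, one row per picture, one column per unit.
#' @param meta Data frame with one row per picture. Must contain a
#'   `picture_id` column; a `group` column (integer numerosity label) is
#'   required by the group-level analyses.
#' @param layer Layer tag, e.g. `"classifier"` or `"last_conv"`.
#' @param normalized Logical; whether rows have already been unit-range
#'   normalized.
#' @param degenerate Logical vector flagging constant rows (set by
#'   [normalize_unit_range()]).
#' @return An object of class `activation_matrix`.
#' @export
activation_matrix <- function(values, meta = NULL, layer = "classifier",
                              normalized = FALSE, degenerate = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values) || nrow(values) < 1L || ncol(values) < 1L)
    stopf("activation_matrix: 'values' must be a non-empty numeric matrix")
  if (is.null(meta)) meta <- data.frame(picture_id = seq_len(nrow(values)))
  if (nrow(meta) != nrow(values))
    stopf("activation_matrix: metadata has %d rows but values has %d",
          nrow(meta), nrow(values))
  if (is.null(meta$picture_id)) meta$picture_id <- seq_len(nrow(values))
  structure(list(values = values, meta = meta, layer = layer,
                 normalized = isTRUE(normalized),
                 degenerate = degenerate %||% rep(FALSE, nrow(values))),
            class = "activation_matrix")
}

#' @export
print.activation_matrix <- function(x, ...) {
  cat(sprintf("<activation_matrix> %d pictures x %d units [layer: %s, %s]\n",
              nrow(x$values), ncol(x$values), x$layer,
              if (x$normalized) "normalized" else "raw"))
  if (!is.null(x$meta$group))
    cat("  groups:", paste(names(table(x$meta$group)), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.activation_matrix <- function(x) dim(x$values)

#' Subset pictures of an activation matrix
#' @param x An `activation_matrix`.
#' @param i Row (picture) index.
#' @param ... Ignored.
#' @return An `activation_matrix` with the selected pictures.
#' @export
`[.activation_matrix` <- function(x, i, ...) {
  copy_synth_attrs(x, activation_matrix(
    x$values[i, , drop = FALSE], x$meta[i, , drop = FALSE],
    layer = x$layer, normalized = x$normalized, degenerate = x$degenerate[i]))
}

# carry the synthetic-generator annotations through transformations
copy_synth_attrs <- function(from, to) {
  for (a in c("planted", "profiles", "config"))
    if (!is.null(attr(from, a, exact = TRUE))) attr(to, a) <- attr(from, a, exact = TRUE)
  to
}

#' Per-picture unit-range normalization
#'
#' Rescales each picture's responses to `[0, 1]` using the minimum and
#' maximum response across the units of that picture:
#' `(x - min) / (max - min)`. Pictures whose responses are constant carry
#' no pattern; they are set to all-zero and flagged degenerate rather than
#' dropped, so picture counts stay stable downstream.
#'
#' @param x An `activation_matrix` (raw) or a numeric matrix.
#' @return An `activation_matrix` with `normalized = TRUE` and a
#'   `degenerate` flag per picture.
#' @export
#' @examples
#' normalize_unit_range(matrix(c(2, 4, 6), 1))$values  # 0 0.5 1
normalize_unit_range <- function(x) {
  if (is.matrix(x)) x <- activation_matrix(x)
  if (!inherits(x, "activation_matrix"))
    stopf("normalize_unit_range: input must be a matrix or activation_matrix")
  v <- x$values
  lo <- apply(v, 1L, min)
  hi <- apply(v, 1L, max)
  rng <- hi - lo
  degen <- rng == 0
  rng[degen] <- 1
  out <- (v - lo) / rng
  out[degen, ] <- 0
  copy_synth_attrs(x, activation_matrix(out, x$meta, layer = x$layer,
                                        normalized = TRUE, degenerate = degen))
}

#' Category-profile matrix
#'
#' Averages normalized activation rows within categories, yielding the
#' category x units "embedding" reference: each row is a category's mean
#' response pattern over the classifier units, typically with its maximum
#' at the category's own unit and weaker co-activations elsewhere.
#'
#' @param acts An `activation_matrix` (normalized rows recommended).
#' @param labels Category label per picture (length = number of pictures).
#' @return A `category_profiles` object: numeric matrix with one row per
#'   category present in `labels` (rownames = category ids).
#' @export
category_profile_matrix <- function(acts, labels) {
  if (is.matrix(acts)) acts <- activation_matrix(acts)
  if (length(labels) != nrow(acts$values))
    stopf("category_profile_matrix: %d labels for %d pictures",
          length(labels), nrow(acts$values))
  labels <- as.character(labels)
  g <- factor(labels, levels = unique(labels))
  prof <- rowsum(acts$values, g) / as.vector(table(g))
  structure(prof, class = c("category_profiles", "matrix"))
}

#' Extract layer responses from a backbone
#'
#' Runs the backbone forward on each image and returns one activation row
#' per image from the requested layer. The `classifier` layer is the final
#' category layer (one unit per trained category); `last_conv` is the
#' flattened final convolutional feature map (for an AlexNet-shaped
#' backbone, 256 x 13 x 13 = 43,264 values).
#'
#' @param backbone An object with a `forward(image)` method exposing both
#'   layers, e.g. from [train_mock_backbone()].
#' @param images List of H x W x 3 arrays with values in `[0, 255]`.
#' @param layer `"classifier"` or `"last_conv"`.
#' @param meta Optional metadata data frame (one row per image).
#' @return A raw (unnormalized) `activation_matrix`.
#' @export
extract_activations <- function(backbone, images,
                                layer = c("classifier", "last_conv"),
                                meta = NULL) {
  layer <- match.arg(layer)
  if (!inherits(backbone, "numsense_backbone"))
    stopf("extract_activations: 'backbone' does not satisfy the backbone contract")
  if (length(images) == 0L) stopf("extract_activations: no images")
  rows <- lapply(images, function(im) backbone_forward(backbone, im)[[layer]])
  acts <- do.call(rbind, rows)
  activation_matrix(acts, meta, layer = layer)
}
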