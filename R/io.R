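# Round-trip I/O: PNG images, CSV activation tables with JSON metadata
# sidecars, a compact binary array container, and CSV curve/matrix
# exports.

#' Write / read an image as PNG
#' @param image H x W x 3 array in `[0, 255]` or an `image_stim`.
#' @param path PNG file path.
#' @return `path` (write) or an H x W x 3 array in `[0, 255]` (read).
#' @export
write_image <- function(image, path) {
  png::writePNG(as_pixels(image) / 255, path)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  a[, , 1:3, drop = FALSE] * 255
}

#' Write / read an activation matrix as CSV plus JSON sidecar
#'
#' The CSV carries the metadata columns followed by one column per
#' unit; the sidecar (`<path>.json`) records the layer tag,
#' normalization state and degenerate-row flags.
#'
#' @param acts An `activation_matrix`.
#' @param path CSV file path.
#' @return `path` (write) or the reconstructed `activation_matrix`
#'   (read).
#' @export
write_activation_csv <- function(acts, path) {
  v <- as.data.frame(acts$values)
  names(v) <- sprintf("u%04d", seq_len(ncol(acts$values)))
  utils::write.csv(cbind(acts$meta, v), path, row.names = FALSE)
  jsonlite::write_json(list(layer = acts$layer, normalized = acts$normalized,
                            degenerate = acts$degenerate,
                            meta_cols = names(acts$meta)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_activation_csv
#' @export
read_activation_csv <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- df[, intersect(side$meta_cols, names(df)), drop = FALSE]
  vals <- as.matrix(df[, setdiff(names(df), side$meta_cols), drop = FALSE])
  activation_matrix(vals, meta, layer = side$layer,
                    normalized = isTRUE(side$normalized),
                    degenerate = as.logical(side$degenerate))
}

#' Write / read an activation matrix as a binary array container
#'
#' Stores the values as little-endian doubles with a JSON sidecar
#' holding dimensions and metadata; compact alternative to CSV for
#' large tables.
#'
#' @param acts An `activation_matrix`.
#' @param path Binary file path (sidecar at `<path>.json`).
#' @return `path` (write) or the reconstructed `activation_matrix`
#'   (read).
#' @export
write_activation_bin <- function(acts, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(acts$values), con, size = 8L, endian = "little")
  jsonlite::write_json(list(dim = dim(acts$values), layer = acts$layer,
                            normalized = acts$normalized,
                            degenerate = acts$degenerate, meta = acts$meta),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_activation_bin
#' @export
read_activation_bin <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = prod(side$dim), size = 8L, endian = "little")
  activation_matrix(matrix(v, side$dim[1L], side$dim[2L]),
                    as.data.frame(side$meta), layer = side$layer,
                    normalized = isTRUE(side$normalized),
                    degenerate = as.logical(side$degenerate))
}

#' Export a psychometric curve or performance matrix to CSV
#' @param x A `psych_curve` or `perf_matrix`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(x, path) {
  if (inherits(x, "psych_curve")) {
    df <- as.data.frame(x)
    df$agent <- attr(x, "agent"); df$condition <- attr(x, "condition")
    utils::write.csv(df, path, row.names = FALSE)
  } else if (inherits(x, "perf_matrix")) {
    m <- apply(x$rates, c(1, 2), mean)
    dimnames(m) <- list(x$levels, x$levels)
    utils::write.csv(as.data.frame(m), path)
  } else stopf("write_curve_csv: unsupported object")
  invisible(path)
}
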