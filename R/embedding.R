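#' Embedding coefficients of activation rows against category profiles
#'
#' The embedding coefficient of a response vector is the maximum Pearson
#' correlation between it and any category's mean activation profile;
#' the best-matching category is the "embedded" category (which need
#' not equal the nominal label).
#'
#' @param acts Normalized `activation_matrix` (one row per picture or
#'   box).
#' @param profiles A `category_profiles` matrix covering the same units.
#' @return Data frame with `picture_id`, `group` (if present in the
#'   metadata), `best_category` and `r`.
#' @export
embedding_scores <- function(acts, profiles) {
  if (is.matrix(acts)) acts <- activation_matrix(acts)
  P <- unclass(profiles)
  if (ncol(P) != ncol(acts$values))
    stopf("embedding_scores: profiles cover %d units, activations have %d",
          ncol(P), ncol(acts$values))
  degen <- apply(acts$values, 1L, stats::sd) == 0
  if (any(degen))
    stopf("embedding_scores: undefined correlation for constant rows: %s",
          paste(utils::head(acts$meta$picture_id[degen], 5L), collapse = ", "))
  C <- stats::cor(t(acts$values), t(P))
  best <- max.col(C, ties.method = "first")
  out <- data.frame(picture_id = acts$meta$picture_id,
                    best_category = rownames(P)[best] %||% best,
                    r = C[cbind(seq_len(nrow(C)), best)],
                    stringsAsFactors = FALSE)
  if (!is.null(acts$meta$group)) out$group <- acts$meta$group
  out
}

#' Embedding coefficient of one bounding box
#'
#' Crops the rectangular box content, runs it through the backbone,
#' normalizes the classifier response, and correlates it with every
#' category profile; returns the best-matching category and its
#' coefficient.
#'
#' @param backbone A backbone satisfying the layer contract.
#' @param image H x W x 3 array or `image_stim`.
#' @param box A [bbox()] inside the image.
#' @param profiles A `category_profiles` matrix.
#' @return List with `category` and `r`.
#' @export
box_embedding <- function(backbone, image, box, profiles) {
  img <- as_pixels(image)
  check_box_inside(box, img)
  crop <- img[box$y + seq_len(box$h), box$x + seq_len(box$w), , drop = FALSE]
  acts <- normalize_unit_range(extract_activations(backbone, list(crop)))
  if (acts$degenerate[1L])
    stopf("box_embedding: degenerate crop (constant activation) at box (%d,%d)",
          box$x, box$y)
  sc <- embedding_scores(acts, profiles)
  list(category = sc$best_category[1L], r = sc$r[1L])
}

#' Embedding coefficient of a picture
#'
#' The unweighted mean of the picture's per-box coefficients.
#'
#' @inheritParams box_embedding
#' @param boxes Non-empty list of [bbox()].
#' @return List with `score` (mean r) and `boxes` (per-box detail data
#'   frame).
#' @export
picture_embedding <- function(backbone, image, boxes, profiles) {
  if (length(boxes) == 0L) stopf("picture_embedding: no boxes")
  det <- do.call(rbind, lapply(seq_along(boxes), function(i) {
    be <- box_embedding(backbone, image, boxes[[i]], profiles)
    data.frame(box = i, category = be$category, r = be$r,
               label = boxes[[i]]$label, stringsAsFactors = FALSE)
  }))
  list(score = mean(det$r), boxes = det)
}

#' Category-based embedding coefficients
#'
#' Replaces every box's coefficient with the mean coefficient of its
#' nominal category label (mean over the full box population), then
#' averages within pictures. This scores a picture by the abstract
#' identity of its objects rather than their particular appearance.
#'
#' @param box_scores Data frame with one row per box: `picture_id`,
#'   `label` (nominal category) and `r`.
#' @return Data frame with `picture_id` and `score`; the label-level
#'   means are attached as attribute `"label_means"`.
#' @export
category_based_embedding <- function(box_scores) {
  need <- c("picture_id", "label", "r")
  miss <- setdiff(need, names(box_scores))
  if (length(miss)) stopf("category_based_embedding: missing columns %s",
                          paste(miss, collapse = ", "))
  if (any(is.na(box_scores$label) | !nzchar(as.character(box_scores$label))))
    stopf("category_based_embedding: unlabeled box present")
  lab_mean <- tapply(box_scores$r, box_scores$label, mean)
  repl <- lab_mean[as.character(box_scores$label)]
  score <- tapply(repl, box_scores$picture_id, mean)
  out <- data.frame(picture_id = names(score), score = as.vector(score),
                    stringsAsFactors = FALSE)
  attr(out, "label_means") <- lab_mean
  out
}

#' Split pictures into superior / inferior embedded subsets
#'
#' Within each numerosity group independently, the top `k` pictures by
#' embedding score form the superior subset and the bottom `k` the
#' inferior subset (deterministic tie-break by picture id).
#'
#' @param scores Data frame with `picture_id`, `group`, `score`.
#' @param k Subset size per group (default 50).
#' @return `scores` with an added `subset` column in
#'   `{"superior", "inferior", "none"}`.
#' @export
split_subsets <- function(scores, k = 50L) {
  k <- check_count(k, "k")
  if (is.null(scores$score) && !is.null(scores$r)) scores$score <- scores$r
  need <- c("picture_id", "group", "score")
  miss <- setdiff(need, names(scores))
  if (length(miss)) stopf("split_subsets: missing columns %s",
                          paste(miss, collapse = ", "))
  scores$subset <- "none"
  for (g in unique(scores$group)) {
    idx <- which(scores$group == g)
    if (length(idx) < 2L * k)
      stopf("split_subsets: group %s has %d pictures, need >= %d",
            g, length(idx), 2L * k)
    ord <- idx[order(-scores$score[idx], scores$picture_id[idx])]
    scores$subset[ord[seq_len(k)]] <- "superior"
    scores$subset[ord[length(ord) - k + seq_len(k)]] <- "inferior"
  }
  scores
}
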