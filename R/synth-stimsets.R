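# Seeded stimulus-set generators: numerosity-graded mosaic and
# area-matched ellipse-scene datasets built from a toy image pool.
# These bridge the procedural image generator and the stimulus
# composition operations so the whole pipeline runs without downloads.

#' Generate a mosaic stimulus dataset
#'
#' For each numerosity 1..`n_groups` draws `n_pictures_per_group`
#' mosaics whose sub-blocks are sampled from the toy pool (all from one
#' category when `flavor = "same"`, or replaced by white-noise patches
#' when `flavor = "noise"`).
#'
#' @param pool A toy set from [gen_image_dataset()].
#' @param n_pictures_per_group Pictures per numerosity.
#' @param n_groups Number of numerosity levels (default 7).
#' @param flavor `"different"`, `"same"` or `"noise"`.
#' @param seed RNG seed.
#' @return List with `images` (list of [image_stim()]) and `meta`
#'   (picture id, group, variant).
#' @export
gen_mosaic_dataset <- function(pool, n_pictures_per_group = 50L, n_groups = 7L,
                               flavor = c("different", "same", "noise"),
                               seed = 1L) {
  flavor <- match.arg(flavor)
  by_label <- split(seq_along(pool$images), pool$labels)
  images <- list()
  meta <- NULL
  sz <- dim(pool$images[[1L]])[1L]
  for (g in seq_len(n_groups)) for (i in seq_len(n_pictures_per_group)) {
    s <- derive_seed(seed, "mosaic", g, i)
    blocks <- with_seed(s, {
      if (flavor == "noise") {
        lapply(seq_len(g), function(k)
          noise_patch(sz, sz, seed = derive_seed(s, "np", k)))
      } else {
        idx <- if (flavor == "same") {
          sample(by_label[[sample.int(length(by_label), 1L)]], g, replace = TRUE)
        } else sample(seq_along(pool$images), g, replace = TRUE)
        pool$images[idx]
      }
    })
    st <- compose_mosaic(blocks, same_category = flavor == "same",
                         variant = if (flavor == "noise") "noise_patch" else NULL)
    images[[length(images) + 1L]] <- st
    meta <- rbind(meta, data.frame(picture_id = sprintf("m%d_%04d", g, i),
                                   group = g, variant = st$variant,
                                   stringsAsFactors = FALSE))
  }
  list(images = images, meta = meta)
}

#' Generate an area-matched ellipse-scene dataset
#'
#' For each numerosity 1..`n_groups` builds `n_pictures_per_group`
#' scenes: source images are ellipse-clipped to areas solved by
#' [solve_scales()] (total area matched to the configured target for
#' every numerosity, with per-object jitter) and placed in distinct
#' jittered grid cells.
#'
#' @param pool A toy set from [gen_image_dataset()].
#' @param cfg A [scene_layout_config()].
#' @param n_pictures_per_group Pictures per numerosity.
#' @param n_groups Number of numerosity levels (default 7).
#' @param flavor `"different"`, `"same"` or `"noise"` (noise-filled
#'   ellipses).
#' @param seed RNG seed.
#' @return List with `images` (list of [image_stim()]) and `meta`.
#' @export
gen_scene_dataset <- function(pool, cfg, n_pictures_per_group = 50L,
                              n_groups = 7L,
                              flavor = c("different", "same", "noise"),
                              seed = 1L) {
  flavor <- match.arg(flavor)
  by_label <- split(seq_along(pool$images), pool$labels)
  images <- list()
  meta <- NULL
  for (g in seq_len(n_groups)) for (i in seq_len(n_pictures_per_group)) {
    s <- derive_seed(seed, "scene", g, i)
    sc <- solve_scales(g, cfg, seed = s)
    patches <- with_seed(s, {
      src_idx <- if (flavor == "same") {
        sample(by_label[[sample.int(length(by_label), 1L)]], g, replace = TRUE)
      } else sample(seq_along(pool$images), g, replace = TRUE)
      lapply(seq_len(g), function(k) {
        if (flavor == "noise") {
          d <- max(cfg$fade_kernel + 2L, round(sqrt(4 * sc$areas[k] / pi)))
          clip_ellipse(noise_patch(d, d, seed = derive_seed(s, "snp", k)),
                       bbox(0L, 0L, d, d), cfg$fade_kernel)
        } else {
          ellipse_patch_from_image(pool$images[[src_idx[k]]], sc$areas[k],
                                   cfg$fade_kernel)
        }
      })
    })
    st <- compose_ellipse_scene(patches, cfg, seed = derive_seed(s, "place"))
    st$variant <- switch(flavor, different = "ellipse_scene",
                         same = "ellipse_scene_same", noise = "ellipse_scene_noise")
    images[[length(images) + 1L]] <- st
    meta <- rbind(meta, data.frame(picture_id = sprintf("e%d_%04d", g, i),
                                   group = g, variant = st$variant,
                                   stringsAsFactors = FALSE))
  }
  list(images = images, meta = meta)
}
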