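const_img <- function(h, w, value = 255) array(value, dim = c(h, w, 3))

test_that("mosaic composition places every sub-block unmodified in its slot", {
  set.seed(3)
  blocks <- lapply(1:7, function(i) array(runif(50 * 50 * 3, 0, 255),
                                          dim = c(50, 50, 3)))
  st <- compose_mosaic(blocks)
  expect_identical(st$item_count, 7L)
  expect_identical(dim(st$pixels), c(1L * 50L, 7L * 50L, 3L))  # exact 1x7 grid
  for (i in seq_along(blocks)) {
    b <- st$boxes[[i]]
    expect_equal(st$pixels[b$y + 1:50, b$x + 1:50, ], blocks[[i]],
                 tolerance = 1e-12)
  }
  # one sub-block: output is that image (padding only if grid larger)
  one <- compose_mosaic(blocks[1])
  expect_equal(one$pixels, blocks[[1]], tolerance = 1e-12)
  expect_error(compose_mosaic(list()), "1-7")
  # noise-patch mosaics exist as a tagged variant
  np <- compose_mosaic(lapply(1:3, function(i) noise_patch(20, 20, i)),
                       variant = "noise_patch")
  expect_identical(np$variant, "noise_patch")
})

test_that("ellipse clipping zeroes the outside and keeps the deep interior", {
  img <- const_img(100, 100)
  patch <- clip_ellipse(img, bbox(0, 0, 100, 100), fade_kernel = 15)
  expect_equal(patch[50, 50, 1], 255, tolerance = 1e-6)
  expect_equal(patch[1, 1, 1], 0)
  expect_equal(patch[100, 100, 3], 0)
  m <- attr(patch, "mask")
  # inscribed-ellipse support is pi/4 of the box, within one rim
  expect_lt(abs(sum(m > 0) / (100 * 100) - pi / 4), 0.05)
  expect_error(clip_ellipse(img, bbox(0, 0, 10, 100), fade_kernel = 15),
               "degenerate")
  expect_error(clip_ellipse(img, bbox(50, 50, 60, 60)), "outside")
})

test_that("fade rim matches a direct Gaussian-convolution oracle", {
  k <- 7
  m <- numsense:::ellipse_mask(40, 40, k)
  # direct dense 2-D convolution of the binary mask with the outer
  # product of the 1-D kernel, zero-padded
  kern1 <- numsense:::gaussian_kernel(k)
  K2 <- outer(kern1, kern1)
  inside <- (matrix(rep(1:40, each = 40), 40) - 20.5)^2 / 400 +
    (matrix(rep(1:40, 40), 40) - 20.5)^2 / 400 <= 1
  # note: ellipse_mask uses (x-0.5) pixel centres; recompute identically
  yy <- matrix(seq_len(40) - 0.5, 40, 40)
  xx <- matrix(rep(seq_len(40) - 0.5, each = 40), 40, 40)
  inside <- ((xx - 20) / 20)^2 + ((yy - 20) / 20)^2 <= 1
  half <- (k - 1) / 2
  pad <- matrix(0, 40 + 2 * half, 40 + 2 * half)
  pad[half + 1:40, half + 1:40] <- inside
  direct <- matrix(0, 40, 40)
  for (i in 1:40) for (j in 1:40)
    direct[i, j] <- sum(pad[i:(i + 2 * half), j:(j + 2 * half)] * K2)
  expect_lt(max(abs(m - direct * inside)) * 255, 1)
})

test_that("scale solving matches the target area and an exhaustive re-scan", {
  cfg <- scene_layout_config(seed = 77)
  # zero jitter: all factors equal, total exact
  cfg0 <- scene_layout_config(scale_jitter = 0, seed = 1)
  s0 <- solve_scales(5, cfg0)
  expect_true(all(s0$factors == 1))
  expect_equal(s0$achieved, cfg0$target_total_area)
  # average object size is target / n before jitter
  s <- solve_scales(6, cfg)
  expect_equal(mean(cfg$target_total_area / 6 * s$factors), mean(s$areas))
  expect_false(s$warning)
  expect_lt(abs(s$achieved - cfg$target_total_area),
            0.1 * cfg$target_total_area)
  # the returned combination minimizes |sum - target| among the same
  # seeded candidate set
  cand <- numsense:::with_seed(numsense:::derive_seed(cfg$seed, "scales", 6), {
    matrix(runif(cfg$n_candidates * 6, 1 - cfg$scale_jitter,
                 1 + cfg$scale_jitter), cfg$n_candidates)
  })
  obj <- abs(cfg$target_total_area / 6 * rowSums(cand) - cfg$target_total_area)
  expect_equal(abs(s$achieved - cfg$target_total_area), min(obj),
               tolerance = 1e-9)
})

test_that("composed scenes have disjoint items inside distinct cells", {
  toy <- toy_set()
  cfg <- scene_layout_config(canvas_size = 240, target_total_area = 18 * 18 * 7,
                             fade_kernel = 5, seed = 31)
  sc <- solve_scales(7, cfg)
  patches <- lapply(1:7, function(k)
    ellipse_patch_from_image(toy$images[[k * 10]], sc$areas[k], cfg$fade_kernel))
  st <- compose_ellipse_scene(patches, cfg)
  expect_identical(st$item_count, 7L)
  # pairwise intersection of non-black supports is empty: total equals sum
  total_nz <- sum(st$pixels[, , 1] + st$pixels[, , 2] + st$pixels[, , 3] > 0)
  each_nz <- sum(vapply(patches, function(p)
    sum(p[, , 1] + p[, , 2] + p[, , 3] > 0), numeric(1)))
  expect_identical(total_nz, as.integer(each_nz))
  # each box within a single grid cell
  for (b in st$boxes) {
    expect_identical(b$x %/% 60L, (b$x + b$w - 1L) %/% 60L)
    expect_identical(b$y %/% 60L, (b$y + b$h - 1L) %/% 60L)
  }
  # single patch: scene contains exactly that patch's non-black pixels
  st1 <- compose_ellipse_scene(patches[1], cfg)
  expect_identical(sum(st1$pixels > 0), sum(patches[[1]] > 0))
  # an oversized patch cannot be placed
  expect_error(compose_ellipse_scene(list(const_img(80, 80)), cfg), "fit")
})

test_that("noise overlay is additive, clipped, seeded and tagged", {
  img <- const_img(30, 30, 100)
  expect_equal(add_noise(img, 0)$pixels, img, tolerance = 1e-12)
  n1 <- add_noise(img, 0.5, seed = 4)
  n3 <- add_noise(img, 3, seed = 4)
  expect_identical(n1$variant, "noise_overlay(0.5)")
  expect_identical(n3$variant, "noise_overlay(3)")
  expect_gt(mean(abs(n3$pixels - img)), mean(abs(n1$pixels - img)))
  expect_true(all(vapply(c(0.5, 1, 2, 3), function(w)
    inherits(add_noise(img, w, seed = 1), "image_stim"), logical(1))))
  expect_error(add_noise(img, -1), "non-negative")
  expect_identical(add_noise(img, 2, seed = 9)$pixels,
                   add_noise(img, 2, seed = 9)$pixels)
})

test_that("region variants dissect foreground and background consistently", {
  set.seed(8)
  img <- array(runif(120 * 120 * 3, 10, 255), dim = c(120, 120, 3))
  boxes <- list(bbox(5, 5, 40, 40), bbox(60, 60, 50, 40))
  clip <- apply_region_variant(img, boxes, "clip", fade_kernel = 7)
  clear <- apply_region_variant(img, boxes, "bbox_cleared", fade_kernel = 7)
  # complementary masks: clip + bbox_cleared reassembles the original
  expect_equal(clip$pixels + clear$pixels, img, tolerance = 1e-6)
  nc <- apply_region_variant(img, boxes, "noise_clip", fade_kernel = 7, seed = 2)
  # outside the ellipses: black; inside interiors: no original pixels
  m <- numsense:::scene_soft_mask(img, boxes, 7)
  expect_true(all(nc$pixels[, , 1][m == 0] == 0))
  interior <- m > 0.999
  expect_gt(mean(nc$pixels[, , 1][interior] != img[, , 1][interior]), 0.99)
  expect_error(apply_region_variant(img, list(), "clip"), "boxes")
})

test_that("phase scrambling preserves the amplitude spectrum", {
  set.seed(5)
  img <- array(runif(64 * 64 * 3, 0, 255), dim = c(64, 64, 3))
  st <- phase_scramble(img, seed = 1)
  un <- attr(st$pixels, "unclipped")
  for (ch in 1:3) {
    a0 <- Mod(fft(img[, , ch]))
    a1 <- Mod(fft(un[, , ch]))
    expect_lt(max(abs(a1 - a0)) / max(a0), 1e-6)
  }
  # output is real-valued and different from the input
  expect_false(isTRUE(all.equal(un, img)))
  # constant image comes back unchanged (zero non-DC amplitude)
  flat <- const_img(32, 32, 128)
  expect_equal(phase_scramble(flat, seed = 2)$pixels, flat, tolerance = 1e-9,
               ignore_attr = TRUE)
  # two seeds: different pixels, identical amplitude spectra
  s1 <- attr(phase_scramble(img, seed = 1)$pixels, "unclipped")
  s2 <- attr(phase_scramble(img, seed = 2)$pixels, "unclipped")
  expect_false(isTRUE(all.equal(s1, s2)))
  expect_equal(Mod(fft(s1[, , 1])), Mod(fft(s2[, , 1])), tolerance = 1e-6)
})
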