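test_that("a row equal to a profile row scores a perfect coefficient", {
  p <- gen_category_profiles(5, 40, seed = 1)
  v <- rbind(unclass(p)[3, ], unclass(p)[1, ])
  sc <- embedding_scores(activation_matrix(v), p)
  expect_identical(sc$best_category, c("cat003", "cat001"))
  expect_equal(sc$r, c(1, 1), tolerance = 1e-12)
})

test_that("embedding argmax and coefficient match a brute-force scan", {
  set.seed(2)
  p <- gen_category_profiles(8, 30, seed = 3)
  v <- matrix(runif(12 * 30), 12)
  sc <- embedding_scores(activation_matrix(v), p)
  for (i in seq_len(12)) {
    rs <- apply(unclass(p), 1, function(row) pearson_direct(v[i, ], row))
    expect_identical(sc$best_category[i], rownames(p)[which.max(rs)])
    expect_equal(sc$r[i], max(rs), tolerance = 1e-12)
  }
  # degenerate row: undefined correlation error naming the picture
  v[3, ] <- 1
  expect_error(embedding_scores(activation_matrix(v), p), "3")
})

test_that("box and picture embedding recompose through the backbone", {
  toy <- toy_set()
  bb <- toy_backbone()
  # reference profiles from the toy set itself
  acts <- normalize_unit_range(extract_activations(bb, toy$images))
  profiles <- category_profile_matrix(acts, toy$labels)
  img <- compose_mosaic(toy$images[c(5, 45)])
  b1 <- box_embedding(bb, img, img$boxes[[1]], profiles)
  b2 <- box_embedding(bb, img, img$boxes[[2]], profiles)
  expect_true(abs(b1$r) <= 1 && abs(b2$r) <= 1)
  pe <- picture_embedding(bb, img, img$boxes, profiles)
  expect_equal(pe$score, mean(c(b1$r, b2$r)), tolerance = 1e-12)
  expect_identical(nrow(pe$boxes), 2L)
  # score is invariant to box order
  pe2 <- picture_embedding(bb, img, rev(img$boxes), profiles)
  expect_equal(pe2$score, pe$score, tolerance = 1e-12)
  expect_error(picture_embedding(bb, img, list(), profiles), "boxes")
})

test_that("category-based coefficients replace box scores by label means", {
  bs <- data.frame(picture_id = c("p1", "p1", "p2", "p3"),
                   label = c("cat", "dog", "cat", "dog"),
                   r = c(0.2, 0.8, 0.4, 0.6))
  out <- category_based_embedding(bs)
  lm <- attr(out, "label_means")
  expect_equal(unname(lm["cat"]), 0.3)
  expect_equal(unname(lm["dog"]), 0.7)
  expect_equal(out$score[out$picture_id == "p1"], 0.5)
  expect_equal(out$score[out$picture_id == "p2"], 0.3)
  # single label: every picture gets the global mean
  one <- category_based_embedding(data.frame(picture_id = c("a", "b"),
                                             label = "x", r = c(0.1, 0.5)))
  expect_true(all(one$score == 0.3))
  # oracle on random inputs
  set.seed(4)
  rnd <- data.frame(picture_id = sample(letters[1:6], 40, TRUE),
                    label = sample(c("u", "v", "w"), 40, TRUE),
                    r = runif(40))
  out2 <- category_based_embedding(rnd)
  lm2 <- tapply(rnd$r, rnd$label, mean)
  man <- tapply(lm2[rnd$label], rnd$picture_id, mean)
  expect_equal(out2$score, as.vector(man[out2$picture_id]), tolerance = 1e-12)
  rnd$label[1] <- NA
  expect_error(category_based_embedding(rnd), "unlabeled")
})

test_that("subset splitting takes the top and bottom k per group", {
  sc <- data.frame(picture_id = sprintf("p%03d", 1:150), group = 1,
                   score = 1:150)
  out <- split_subsets(sc, k = 50)
  expect_identical(out$subset[101:150], rep("superior", 50))
  expect_identical(out$subset[1:50], rep("inferior", 50))
  expect_identical(out$subset[51:100], rep("none", 50))
  # all-equal scores: deterministic id tie-break, sizes exactly k / k
  tie <- data.frame(picture_id = sprintf("p%03d", 1:120), group = 2, score = 1)
  out2 <- split_subsets(tie, k = 50)
  expect_identical(sum(out2$subset == "superior"), 50L)
  expect_identical(sum(out2$subset == "inferior"), 50L)
  expect_length(intersect(out2$picture_id[out2$subset == "superior"],
                          out2$picture_id[out2$subset == "inferior"]), 0)
  # order statistics on random scores
  set.seed(5)
  rnd <- data.frame(picture_id = sprintf("q%03d", 1:200),
                    group = rep(1:2, each = 100), score = runif(200))
  out3 <- split_subsets(rnd, k = 30)
  for (g in 1:2) {
    sup <- out3$score[out3$group == g & out3$subset == "superior"]
    inf <- out3$score[out3$group == g & out3$subset == "inferior"]
    expect_gte(min(sup), max(inf))
  }
  expect_error(split_subsets(sc[1:60, ], k = 50), "group")
})

test_that("embedding scores track the generator's fidelity knob", {
  cfg <- synth_activation_config(n_pictures_per_group = 15,
                                 embed_fidelity = c(0, 1), seed = 19)
  a <- normalize_unit_range(gen_activation_dataset(cfg))
  sc <- embedding_scores(a, attr(a, "profiles"))
  expect_gte(cor(a$meta$fidelity, sc$r, method = "spearman"), 0.8)
})
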