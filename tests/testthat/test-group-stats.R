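test_that("group summaries are exact sample means and n-1 standard deviations", {
  # trivial constants
  a <- activation_matrix(matrix(0.3, 6, 4),
                         data.frame(picture_id = 1:6, group = rep(1:2, 3)))
  s <- group_summary(a)
  expect_true(all(s$mean == 0.3))
  expect_true(all(s$sd == 0))
  # two pictures 0 and 1 on one unit
  b <- group_summary(activation_matrix(matrix(c(0, 1), 2, 1),
                                       data.frame(picture_id = 1:2,
                                                  group = c(1, 1))))
  expect_equal(as.vector(b$mean), 0.5)
  expect_equal(as.vector(b$sd), sd(c(0, 1)))
  expect_error(group_summary(activation_matrix(matrix(1, 3, 2),
                                               data.frame(picture_id = 1:3,
                                                          group = c(1, 1, 2)))),
               "std undefined")
})

test_that("summaries match a brute-force per-unit oracle to 1e-12", {
  set.seed(11)
  v <- matrix(runif(60 * 20), 60)
  g <- rep(1:3, each = 20)
  s <- group_summary(activation_matrix(v, data.frame(picture_id = 1:60, group = g)))
  for (gi in 1:3) for (u in c(1, 9, 20)) {
    x <- v[g == gi, u]
    expect_equal(unname(s$mean[gi, u]), sum(x) / length(x), tolerance = 1e-12)
    expect_equal(unname(s$sd[gi, u]),
                 sqrt(sum((x - mean(x))^2) / (length(x) - 1)),
                 tolerance = 1e-12)
  }
})

test_that("decile statistics follow the linear-interpolation convention", {
  # unit means 1..100 in a single group
  v <- rbind(1:100, 1:100)
  s <- group_summary(activation_matrix(v, data.frame(picture_id = 1:2,
                                                     group = c(1, 1))))
  expect_equal(unname(decile_stats(s, "mean90")), 90.1)
  # constant vector: percentile equals the constant
  sc <- group_summary(activation_matrix(matrix(2, 3, 5),
                                        data.frame(picture_id = 1:3,
                                                   group = rep(1, 3))))
  expect_equal(unname(decile_stats(sc, "mean90")), 2)
  # agreement with an independent sort-based oracle on random vectors
  set.seed(12)
  v2 <- matrix(runif(40 * 30), 40)
  g2 <- rep(1:2, each = 20)
  s2 <- group_summary(activation_matrix(v2, data.frame(picture_id = 1:40,
                                                       group = g2)))
  expect_equal(unname(decile_stats(s2, "mean90")[1]),
               sorted_quantile(s2$mean[1, ], 0.9), tolerance = 1e-12)
  expect_equal(unname(decile_stats(s2, "std10")[2]),
               sorted_quantile(s2$sd[2, ], 0.1), tolerance = 1e-12)
})

test_that("high-activation counts respect the threshold", {
  s <- group_summary(activation_matrix(rbind(c(0.8, 0.6, 0.9), c(0.8, 0.6, 0.9)),
                                       data.frame(picture_id = 1:2,
                                                  group = c(1, 1))))
  expect_equal(unname(high_count(s, 0.7)), 2)
  expect_equal(unname(high_count(s, 0.95)), 0)
})

test_that("resampling reproduces the full pool when it is exhausted, and is seeded", {
  sm <- planted_small()
  sub <- sm$acts[sm$acts$meta$group %in% 1:3]
  r1 <- resample_summary(sub, n_pick = 300, reps = 1, seed = 5)
  full <- group_summary(sub)
  expect_equal(r1[[1]]$mean, full$mean, tolerance = 1e-12)
  expect_equal(r1[[1]]$sd, full$sd, tolerance = 1e-12)
  r2 <- resample_summary(sub, n_pick = 100, reps = 3, seed = 9)
  r3 <- resample_summary(sub, n_pick = 100, reps = 3, seed = 9)
  expect_equal(r2[[2]]$mean, r3[[2]]$mean, tolerance = 1e-12)
  # small pool: flagged with-replacement
  r4 <- resample_summary(sub, n_pick = 500, reps = 1, seed = 1)
  expect_true(attr(r4, "with_replacement"))
})

test_that("decile trends on planted data go the right way in >= 9 of 10 draws", {
  sm <- planted_small()
  rs <- resample_summary(sm$acts, n_pick = 150, reps = 10, seed = 21)
  m90 <- t(vapply(rs, decile_stats, numeric(7), which = "mean90"))
  s10 <- t(vapply(rs, decile_stats, numeric(7), which = "std10"))
  expect_gte(sum(m90[, 7] > m90[, 1]), 9)
  expect_gte(sum(s10[, 7] < s10[, 1]), 9)
})

test_that("trend tests reduce to known identities", {
  # identical groups: degenerate variance flagged, p = 1
  a <- activation_matrix(matrix(0.4, 8, 6),
                         data.frame(picture_id = 1:8, group = rep(1:2, 4)))
  rep0 <- trend_tests(group_summary(a), "mean")
  expect_true(rep0$anova$degenerate)
  expect_equal(rep0$anova$p, 1)
  # two groups: F equals the squared pooled t statistic
  set.seed(13)
  v <- matrix(runif(40 * 25), 40)
  g <- rep(1:2, each = 20)
  s <- group_summary(activation_matrix(v, data.frame(picture_id = 1:40,
                                                     group = g)))
  rep1 <- trend_tests(s, "mean")
  tt <- t.test(s$mean[1, ], s$mean[2, ], var.equal = TRUE)
  expect_equal(rep1$anova$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(rep1$anova$p, tt$p.value, tolerance = 1e-9)
  # report serializes
  f <- tempfile(fileext = ".csv")
  write_trend_report(rep1, f)
  expect_true(file.exists(f))
})

test_that("statistics are invariant to unit reordering", {
  sm <- planted_small()
  sub <- sm$acts[c(1:40, 301:340, 601:640)]
  set.seed(31)
  p <- sample(ncol(sub$values))
  reord <- activation_matrix(sub$values[, p], sub$meta)
  s1 <- group_summary(sub); s2 <- group_summary(reord)
  expect_equal(sort(decile_stats(s1, "mean90")), sort(decile_stats(s2, "mean90")),
               tolerance = 1e-12)
  expect_equal(unname(s1$mean[, p]), unname(s2$mean), tolerance = 1e-12)
})
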