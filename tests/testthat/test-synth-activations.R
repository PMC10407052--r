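test_that("configuration errors name the offending field", {
  expect_error(synth_activation_config(n_units = 0), "n_units")
  expect_error(synth_activation_config(sigma_scale = 0), "sigma_scale")
  expect_error(synth_activation_config(sigma_scale = 1.2), "sigma_scale")
  expect_error(synth_activation_config(embed_fidelity = 1.5), "embed_fidelity")
  expect_error(synth_activation_config(embed_fidelity = c(0.8, 0.2)), "embed_fidelity")
  expect_error(synth_activation_config(n_units = 10, n_increasing = 8,
                                       n_decreasing = 4), "n_increasing")
  expect_error(synth_activation_config(n_units = 10, n_increasing = 2,
                                       n_decreasing = 2, n_categories = 20),
               "n_categories")
})

test_that("generation is seed-deterministic and separates structure from pictures", {
  cfg <- synth_activation_config(n_units = 60, n_pictures_per_group = 10,
                                 n_increasing = 8, n_decreasing = 3,
                                 n_categories = 5, seed = 42)
  a <- gen_activation_dataset(cfg)
  b <- gen_activation_dataset(cfg)
  expect_identical(a$values, b$values)
  expect_identical(attr(a, "planted"), attr(b, "planted"))
  # different picture seed: same structure, different pictures
  c <- gen_activation_dataset(cfg, picture_seed = 99)
  expect_identical(attr(a, "planted"), attr(c, "planted"))
  expect_identical(unclass(attr(a, "profiles")), unclass(attr(c, "profiles")))
  expect_false(identical(a$values, c$values))
  expect_true(all(a$values >= 0))
  expect_identical(dim(a$values), c(70L, 60L))
})

test_that("no planted effect leaves groups statistically exchangeable", {
  cfg <- synth_activation_config(n_units = 50, n_pictures_per_group = 200,
                                 n_increasing = 0, n_decreasing = 0,
                                 slope_mean = 0, sigma_scale = 1,
                                 profile_scale = 0, seed = 5)
  acts <- gen_activation_dataset(cfg)
  s <- group_summary(acts)
  # standardized difference between extreme groups, per unit
  se <- sqrt(s$sd[1, ]^2 / s$n[1] + s$sd[7, ]^2 / s$n[7])
  z <- (s$mean[7, ] - s$mean[1, ]) / se
  expect_lt(mean(abs(z) > 3), 0.05)
  expect_lt(abs(mean(z)), 0.5)
})

test_that("planted increasing means rise between consecutive groups (Monte Carlo)", {
  cfg <- synth_activation_config(n_units = 100, n_pictures_per_group = 4000,
                                 n_increasing = 10, n_decreasing = 0,
                                 slope_mean = 0.1, profile_scale = 0, seed = 9)
  acts <- gen_activation_dataset(cfg)
  s <- group_summary(acts)
  inc <- attr(acts, "planted")$increasing
  rises <- as.vector(apply(s$mean[, inc, drop = FALSE], 2, diff) > 0)
  expect_gte(mean(rises), 0.95)
})

test_that("sample moments match the rectified-normal population contract within 4 SE", {
  cfg <- synth_activation_config(n_units = 80, n_pictures_per_group = 1000,
                                 n_increasing = 15, n_decreasing = 10,
                                 profile_scale = 0, seed = 21)
  acts <- gen_activation_dataset(cfg)
  pl <- attr(acts, "planted")
  s <- group_summary(acts)
  pop <- planted_population_moments(cfg)
  for (kind in c("increasing", "decreasing")) {
    units <- pl[[kind]]
    for (g in c(1, 4, 7)) {
      p <- pop[pop$kind == kind & pop$group == g, ]
      se <- p$sd / sqrt(s$n[g])
      z <- (s$mean[g, units] - p$mean) / se
      expect_true(all(abs(z) < 4 + 1e-12))
      # sample sd close to population sd (relative check, generous)
      expect_true(all(abs(s$sd[g, units] / p$sd - 1) < 0.2))
    }
  }
})

test_that("category profiles peak at the preferred unit and rows are distinct", {
  p <- gen_category_profiles(10, 50, diag_strength = 0.8, seed = 3)
  expect_identical(unname(apply(p, 1, which.max)), 1:10)
  cc <- cor(t(unclass(p)))
  expect_true(all(cc[upper.tri(cc)] < 1))
  # diag_strength 1 with zero baseline: identity-like
  id <- gen_category_profiles(5, 5, diag_strength = 1, baseline_mean = 0,
                              baseline_sigma = 1e-12, seed = 4)
  for (i in 1:5) {
    ci <- cor(unclass(id)[i, ], t(unclass(id)))
    expect_equal(ci[i], 1, tolerance = 1e-9)
    expect_true(all(ci[-i] < 1))
  }
  expect_error(gen_category_profiles(10, 5), "dimension")
})

test_that("pairwise profile correlations match the direct Pearson formula", {
  p <- unclass(gen_category_profiles(20, 100, seed = 8))
  cc <- cor(t(p))
  for (i in c(1, 7)) for (j in c(3, 15)) {
    expect_equal(cc[i, j], pearson_direct(p[i, ], p[j, ]), tolerance = 1e-12)
  }
})
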