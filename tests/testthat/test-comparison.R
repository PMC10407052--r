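oracle_pools <- function(n_per = 20) {
  list(estimates = rep(1:7, each = n_per), groups = rep(1:7, each = n_per))
}

test_that("a perfect oracle decoder produces the step performance matrix", {
  p <- oracle_pools()
  pm <- run_comparison(p$estimates, p$groups, trials_per_cell = 40,
                       reps = 2, seed = 1)
  m <- apply(pm$rates, c(1, 2), mean)
  expect_true(all(m[lower.tri(m)] == 1))
  expect_true(all(m[upper.tri(m)] == 0))
  # diagonal resolved by the tie coin, near 0.5
  expect_lt(max(abs(diag(m) - 0.5)), 3 * sqrt(0.25 / 80))
})

test_that("comparison trials replay exactly from the seeded stream", {
  set.seed(5)
  est <- rnorm(140)
  grp <- rep(1:7, each = 20)
  pm <- run_comparison(est, grp, trials_per_cell = 30, reps = 2, seed = 77)
  pools <- split(est, factor(grp))
  for (r in 1:2) for (i in c(1, 3)) for (j in c(5, 7)) {
    trial <- numsense:::with_seed(numsense:::derive_seed(77, "cmp", r, i, j), {
      ia <- sample.int(length(pools[[i]]), 30, replace = TRUE)
      ib <- sample.int(length(pools[[j]]), 30, replace = TRUE)
      u <- runif(30)
      list(a = pools[[i]][ia], b = pools[[j]][ib], u = u)
    })
    win <- trial$a > trial$b | (trial$a == trial$b & trial$u < 0.5)
    expect_equal(pm$rates[i, j, r], mean(win))
    expect_equal(pm$rates[j, i, r], 1 - mean(win))
  }
  expect_error(run_comparison(est[1:40], grp[1:40], 10), "7 groups")
})

test_that("reported rates satisfy the exact mirror symmetry S(d) + S(-d) = 1", {
  set.seed(6)
  est <- rnorm(210, rep(1:7, each = 30), 1.5)
  cv <- psychometric(run_comparison(est, rep(1:7, each = 30),
                                    trials_per_cell = 25, reps = 3, seed = 9))
  off <- cv$distance != 0
  expect_equal(cv$rate[off] + rev(cv$rate)[off], rep(1, sum(off)),
               tolerance = 1e-12)
})

test_that("psychometric collapse averages the correct cells", {
  # uniform 0.5 matrix: flat curve
  flat <- perf_matrix(matrix(0.5, 7, 7), trials_per_cell = 10)
  expect_true(all(psychometric(flat)$rate == 0.5))
  # random matrix: hand-computed diagonal averages
  set.seed(7)
  m <- matrix(runif(49), 7)
  cv <- psychometric(perf_matrix(m, trials_per_cell = 10))
  dmat <- outer(1:7, 1:7, `-`)
  for (d in c(-6, -2, 0, 3, 6))
    expect_equal(cv$rate[cv$distance == d], mean(m[dmat == d]),
                 tolerance = 1e-12)
  # invariant to cell-order permutations within a distance class
  expect_equal(sum(cv$n_trials), 49 * 10)
})

test_that("percent correct folds the reported rate", {
  cv <- psych_curve(-6:6, c(rep(0.1, 6), 0.5, rep(0.9, 6)))
  pc <- percent_correct(cv)
  expect_true(all(pc$pct_correct == 0.9))
  expect_identical(pc$abs_distance, 1:6)
})

test_that("human-log ingestion resolves sides and flags biased participants", {
  cv <- logistic_psych_curve(0.9)
  log <- gen_trial_log(list(all = cv), n_participants = 2, trials_per_cell = 20,
                       seed = 4, bias = c(0, 0.35))
  pf <- perf_from_trials(log, bias_range = c(0.35, 0.65))
  expect_false(pf$participants$excluded[1])
  expect_true(pf$participants$excluded[2])
  # a response always on the larger side gives the oracle matrix
  larger <- log[log$participant == "s01", ]
  larger$response <- ifelse(larger$n_left > larger$n_right, "left",
                            ifelse(larger$n_left < larger$n_right, "right",
                                   larger$response))
  m <- apply(perf_from_trials(larger)$matrices[["s01"]][["all"]]$rates,
             c(1, 2), mean)
  expect_true(all(m[lower.tri(m)] == 1))
  expect_true(all(m[upper.tri(m)] == 0))
  # malformed rows are reported, not dropped
  broken <- log
  broken$n_left[3] <- 9
  expect_error(perf_from_trials(broken), "malformed rows: 3")
})

test_that("curve tests compare conditions with Bonferroni control", {
  set.seed(8)
  m1 <- matrix(runif(10 * 13, 0.55, 0.65), 10,
               dimnames = list(NULL, -6:6))
  expect_error(curve_tests(list(a = m1[1, , drop = FALSE])), "single replicate")
  # identical conditions: paired p = 1
  ct <- curve_tests(list(a = m1, b = m1))
  pair <- ct[ct$test == "a vs b", ]
  expect_true(all(pair$p == 1))
  # a real gap is detected at conventional power
  m2 <- m1 - 0.08 + matrix(rnorm(130, 0, 0.01), 10)
  ct2 <- curve_tests(list(hi = m1, lo = m2))
  pair2 <- ct2[ct2$test == "hi vs lo", ]
  expect_true(all(pair2$p_bonf < 0.05))
  expect_true(all(ct2$p_bonf >= ct2$p, na.rm = TRUE))
})

test_that("paired-test power agrees with the analytic calculation", {
  delta <- 0.06; sdev <- 0.05; n <- 12
  ana <- power.t.test(n = n, delta = delta, sd = sdev, type = "paired",
                      alternative = "two.sided")$power
  set.seed(9)
  rej <- mean(replicate(400, {
    d <- rnorm(n, delta, sdev)
    t.test(d)$p.value < 0.05
  }))
  expect_lt(abs(rej - ana), 0.1)
})

test_that("zero-weight noise reproduces the clean pipeline exactly", {
  toy <- toy_set()
  bb <- toy_backbone()
  mos <- gen_mosaic_dataset(toy, n_pictures_per_group = 10, seed = 14)
  imgs <- lapply(mos$images, function(s) s$pixels)
  acts <- normalize_unit_range(extract_activations(bb, imgs, meta = mos$meta))
  dm <- train_decoder(acts, unit_set(1:10), hidden = 16, epochs = 60, seed = 15)
  nr <- noise_robustness(dm, bb, imgs, mos$meta$group, weights = 0,
                         trials_per_cell = 10, reps = 1, seed = 16)
  # direct clean run with the same comparison seed, over the same
  # input-resolution images
  res <- lapply(imgs, numsense:::resize_image, size = bb$input_size)
  acts0 <- normalize_unit_range(extract_activations(bb, res))
  est0 <- decode(dm, acts0)
  cv0 <- psychometric(run_comparison(est0, mos$meta$group, trials_per_cell = 10,
                                     reps = 1,
                                     seed = numsense:::derive_seed(16, "noisecmp")))
  expect_equal(nr[["0"]]$rate, cv0$rate, tolerance = 1e-12)
  expect_error(noise_robustness(dm, bb, imgs, mos$meta$group, weights = -1),
               ">= 0")
})
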