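test_that("RSM construction enforces symmetry and a zero diagonal", {
  expect_error(rsm(matrix(1:6, 2, 3)), "square")
  m <- matrix(c(0, 1, 2, 0), 2)
  expect_error(rsm(m), "symmetric")
  expect_error(rsm(matrix(c(1, 2, 2, 0), 2)), "diagonal")
  ok <- rsm(matrix(c(0, 2, 2, 0), 2), agent = "x")
  expect_s3_class(ok, "rsm")
})

test_that("curves fill the condition-level RSM as discriminability", {
  flat <- psych_curve(-6:6, rep(0.5, 13))
  z <- rsm_from_curves(flat, flat)
  expect_true(all(unclass(z) == 0))
  step <- psych_curve(-6:6, c(rep(0, 6), 0.5, rep(1, 6)))
  s <- rsm_from_curves(step, step)
  blocks <- attr(s, "blocks")
  b1 <- unclass(s)[blocks[[1]], blocks[[1]]]
  expect_true(all(b1[upper.tri(b1)] == 0.5))
  expect_true(all(diag(b1) == 0))
  # identical curves for two agents: perfect RSM correlation
  cva <- logistic_psych_curve(0.8); cvb <- logistic_psych_curve(0.5)
  r1 <- rsm_from_curves(cva, cvb, agent = "a")
  r2 <- rsm_from_curves(cva, cvb, agent = "b")
  expect_equal(cor(numsense:::as_rsa_vec(r1), numsense:::as_rsa_vec(r2),
                   method = "spearman"), 1)
  # concat switch returns the stacked rate vector
  cc <- rsm_from_curves(cva, cvb, method = "concat")
  expect_s3_class(cc, "rsa_vector")
  expect_identical(cc$values, c(cva$rate, cvb$rate))
})

test_that("picture-wise RSMs are one minus the profile correlation", {
  # identical profiles: dissimilarity 0; anticorrelated: 2
  out <- matrix(0, 4, 4)
  out[1, ] <- c(0.5, 0.1, 0.9, 0.3)
  out[2, ] <- c(0.4, 0.5, 0.9, 0.3)     # same profile as 1 off the pair
  out[3, ] <- c(0.6, 0.1, 0.5, 0.3)
  out[4, ] <- 1 - out[3, ]              # anticorrelated with 3
  r <- rsm_picturewise(out)
  expect_equal(unclass(r)[1, 2], 0, tolerance = 1e-12)
  expect_equal(unclass(r)[3, 4], 2, tolerance = 1e-12)
  expect_equal(unclass(r), t(unclass(r)))
  expect_true(all(diag(unclass(r)) == 0))
  # brute-force oracle on random tables
  set.seed(6)
  o2 <- matrix(runif(100), 10)
  r2 <- rsm_picturewise(o2)
  for (i in c(1, 4)) for (j in c(7, 10)) {
    keep <- setdiff(1:10, c(i, j))
    expect_equal(unclass(r2)[i, j], 1 - pearson_direct(o2[i, keep], o2[j, keep]),
                 tolerance = 1e-12)
  }
  # constant profiles are flagged, not silently dropped
  o3 <- matrix(runif(36), 6); o3[2, ] <- 0.5
  r3 <- rsm_picturewise(o3)
  expect_true(2 %in% attr(r3, "degenerate"))
  expect_true(any(is.na(unclass(r3)[2, -2])))
})

test_that("a candidate identical to the references ranks first with correlation 1", {
  set.seed(7)
  base <- matrix(runif(49), 7); base <- (base + t(base)) / 2; diag(base) <- 0
  refs <- replicate(12, rsm(base), simplify = FALSE)
  noise <- matrix(runif(49), 7); noise <- (noise + t(noise)) / 2; diag(noise) <- 0
  rep <- compare_rsms(refs, list(same = rsm(base), other = rsm(noise)))
  ct <- rep$candidate_tests
  expect_identical(ct$candidate[1], "same")
  expect_equal(ct$mean_r[ct$candidate == "same"], 1)
  expect_true(ct$significant[ct$candidate == "same"])
  expect_identical(nrow(rep$pairwise), 1L)
  expect_error(compare_rsms(refs[1:5], list(same = rsm(base))), ">= 12")
  expect_error(compare_rsms(refs, list(bad = rsm(matrix(0, 3, 3)))), "mismatch")
})

test_that("RSM comparison is invariant to a common item permutation", {
  set.seed(8)
  mk <- function() {
    m <- matrix(runif(64), 8); m <- (m + t(m)) / 2; diag(m) <- 0; rsm(m)
  }
  refs <- replicate(12, mk(), simplify = FALSE)
  cand <- list(a = mk(), b = mk())
  r1 <- compare_rsms(refs, cand)
  p <- sample(8)
  permute <- function(x) rsm(unclass(x)[p, p])
  r2 <- compare_rsms(lapply(refs, permute), lapply(cand, permute))
  expect_equal(r1$correlations, r2$correlations, tolerance = 1e-12)
})

test_that("shuffling preserves the dissimilarity multiset", {
  cva <- logistic_psych_curve(0.9); cvb <- logistic_psych_curve(0.5)
  r <- rsm_from_curves(cva, cvb)
  s <- shuffle_rsm(r, seed = 3)
  expect_equal(sort(numsense:::as_rsa_vec(s)), sort(numsense:::as_rsa_vec(r)),
               tolerance = 1e-12)
  e <- shuffle_rsm(r, seed = 4, scope = "entries")
  expect_s3_class(e, "rsa_vector")
  expect_equal(sort(e$values), sort(numsense:::as_rsa_vec(r)), tolerance = 1e-12)
  expect_false(identical(e$values, numsense:::as_rsa_vec(r)))
})
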