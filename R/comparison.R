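#' Performance matrix container
#'
#' Cell `(a, b)` holds the fraction of trials on which the agent
#' reported "stimulus A (numerosity a) > stimulus B (numerosity b)".
#'
#' @param rates 7 x 7 matrix or 7 x 7 x reps array of reported rates.
#' @param trials_per_cell Trials per cell per replicate.
#' @param levels Numerosity levels (default 1..7).
#' @param agent,condition Tags.
#' @return A `perf_matrix` object.
#' @export
perf_matrix <- function(rates, trials_per_cell, levels = 1:7,
                        agent = "network", condition = "all") {
  if (length(dim(rates)) == 2L) rates <- array(rates, dim = c(dim(rates), 1L))
  if (any(rates < 0 | rates > 1, na.rm = TRUE))
    stopf("perf_matrix: rates outside [0, 1]")
  if (any(trials_per_cell <= 0)) stopf("perf_matrix: trial counts must be positive")
  structure(list(rates = rates, trials_per_cell = trials_per_cell,
                 levels = levels, agent = agent, condition = condition),
            class = "perf_matrix")
}

#' @export
print.perf_matrix <- function(x, ...) {
  cat(sprintf("<perf_matrix> %dx%d, %d replicate(s), %d trials/cell [%s/%s]\n",
              dim(x$rates)[1L], dim(x$rates)[2L], dim(x$rates)[3L],
              x$trials_per_cell, x$agent, x$condition))
  print(round(apply(x$rates, c(1, 2), mean), 3))
  invisible(x)
}

#' Run the numerosity comparison task on decoded estimates
#'
#' For every cell `(a, b)` of the 7 x 7 design, pairs of pictures are
#' drawn from the numerosity-`a` and numerosity-`b` pools (with
#' replacement across trials; without replacement within a trial on the
#' diagonal) and the trial is reported "A > B" iff the decoded estimate
#' of A exceeds that of B, exact ties broken by a seeded fair coin.
#' Cells `(a, b)` and `(b, a)` replay the same seeded trials with the
#' roles mirrored (tie-coin mirrored too), so `S(d) + S(-d) = 1` holds
#' exactly for d != 0. The whole matrix is repeated `reps` times with
#' independent draws.
#'
#' @param estimates Numeric decoded estimate per picture.
#' @param groups True numerosity per picture (levels 1..7).
#' @param trials_per_cell Trials per cell (100 for full pools, 33 for
#'   embedding subsets).
#' @param reps Independent repetitions (default 10).
#' @param seed RNG seed.
#' @param agent,condition Tags.
#' @return A [perf_matrix()] with one slice per repetition.
#' @export
run_comparison <- function(estimates, groups, trials_per_cell = 100L,
                           reps = 10L, seed = 1L, agent = "network",
                           condition = "all") {
  trials_per_cell <- check_count(trials_per_cell, "trials_per_cell")
  g <- factor(groups, levels = sort(unique(as.integer(groups))))
  lev <- as.integer(levels(g))
  k <- length(lev)
  if (k != 7L) stopf("run_comparison: need pools for all 7 groups, got %d", k)
  pools <- split(as.numeric(estimates), g)
  if (any(vapply(pools, length, integer(1)) < 2L))
    stopf("run_comparison: empty or singleton picture pool")
  rates <- array(NA_real_, dim = c(k, k, reps))
  for (r in seq_len(reps)) {
    for (i in seq_len(k)) for (j in i:k) {
      trial <- with_seed(derive_seed(seed, "cmp", r, i, j), {
        pi <- pools[[i]]; pj <- pools[[j]]
        if (i == j) {
          ab <- vapply(seq_len(trials_per_cell),
                       function(t) sample.int(length(pi), 2L), integer(2))
          ia <- ab[1L, ]; ib <- ab[2L, ]
        } else {
          ia <- sample.int(length(pi), trials_per_cell, replace = TRUE)
          ib <- sample.int(length(pj), trials_per_cell, replace = TRUE)
        }
        u <- stats::runif(trials_per_cell)
        list(a = pi[ia], b = pj[ib], u = u)
      })
      win <- trial$a > trial$b | (trial$a == trial$b & trial$u < 0.5)
      rates[i, j, r] <- mean(win)
      if (i != j) rates[j, i, r] <- 1 - mean(win)   # mirrored replay of the same trials
    }
  }
  dimnames(rates) <- list(lev, lev, NULL)
  perf_matrix(rates, trials_per_cell, levels = lev, agent = agent,
              condition = condition)
}

#' Collapse a performance matrix onto the psychometric curve
#'
#' `S(d)` is the trial-weighted mean of the cells with numerical
#' distance `a - b = d` (the diagonal cells give `S(0)`), averaged over
#' replicates; the per-replicate curves are kept in attribute
#' `"per_rep"` for error bars and paired tests.
#'
#' @param perf A [perf_matrix()].
#' @return A [psych_curve()] over distances `-(k-1) .. k-1`.
#' @export
psychometric <- function(perf) {
  k <- length(perf$levels)
  reps <- dim(perf$rates)[3L]
  dist <- -(k - 1L):(k - 1L)
  per_rep <- matrix(NA_real_, reps, length(dist),
                    dimnames = list(NULL, dist))
  dmat <- outer(perf$levels, perf$levels, `-`)
  for (r in seq_len(reps)) {
    sl <- perf$rates[, , r]
    per_rep[r, ] <- vapply(dist, function(d) mean(sl[dmat == d]), numeric(1))
  }
  n_d <- vapply(dist, function(d) sum(dmat == d), integer(1)) *
    perf$trials_per_cell * reps
  cv <- psych_curve(dist, colMeans(per_rep), n_trials = n_d,
                    agent = perf$agent, condition = perf$condition)
  attr(cv, "per_rep") <- per_rep
  cv
}

#' Percent correct at each absolute numerical distance
#'
#' Derived reading of a psychometric curve: `max(S, 1 - S)` averaged
#' over the two signs of each non-zero distance.
#'
#' @param curve A [psych_curve()].
#' @return Data frame with `abs_distance` and `pct_correct`.
#' @export
percent_correct <- function(curve) {
  ad <- sort(unique(abs(curve$distance)))
  ad <- ad[ad > 0]
  pc <- vapply(ad, function(d) {
    s <- curve$rate[abs(curve$distance) == d]
    mean(pmax(s, 1 - s))
  }, numeric(1))
  data.frame(abs_distance = ad, pct_correct = pc)
}

#' Performance matrices from a trial log
#'
#' Builds one 7 x 7 matrix per participant and condition. Cell `(a, b)`
#' is the fraction of trials showing the pair `{a, b}` on which the side
#' displaying `a` was chosen (side counterbalancing resolved from the
#' left/right fields); diagonal cells report the left-choice rate, which
#' is also used for the side-bias screen. Trials with a missing response
#' are excluded and counted; malformed rows raise an error listing the
#' offending row numbers.
#'
#' @param log A `trial_log` data frame (see [gen_trial_log()] /
#'   [read_trial_log()]).
#' @param bias_range Acceptable overall left-choice range; participants
#'   outside it are flagged `excluded` (threshold configurable, not
#'   silently dropped).
#' @return List with `matrices` (nested list participant -> condition of
#'   [perf_matrix()]), `participants` summary data frame (left-choice
#'   rate, exclusion flag, missing-response count).
#' @export
perf_from_trials <- function(log, bias_range = c(0.35, 0.65)) {
  need <- c("participant", "n_left", "n_right", "condition", "response")
  miss <- setdiff(need, names(log))
  if (length(miss)) stopf("perf_from_trials: missing columns %s",
                          paste(miss, collapse = ", "))
  bad <- which(!(log$n_left %in% 1:7) | !(log$n_right %in% 1:7) |
                 !(log$response %in% c("left", "right", NA)))
  if (length(bad))
    stopf("perf_from_trials: malformed rows: %s",
          paste(utils::head(bad, 10L), collapse = ", "))
  missing_resp <- is.na(log$response)
  log_ok <- log[!missing_resp, , drop = FALSE]
  parts <- unique(log$participant)
  conds <- unique(log$condition)
  matrices <- list()
  summary <- data.frame(participant = parts,
                        left_rate = NA_real_, n_missing = NA_integer_,
                        excluded = NA)
  for (pi in seq_along(parts)) {
    pl <- log_ok[log_ok$participant == parts[pi], , drop = FALSE]
    lr <- mean(pl$response == "left")
    summary$left_rate[pi] <- lr
    summary$n_missing[pi] <- sum(missing_resp[log$participant == parts[pi]])
    summary$excluded[pi] <- lr < bias_range[1L] || lr > bias_range[2L]
    matrices[[parts[pi]]] <- lapply(stats::setNames(conds, conds), function(cd) {
      cl <- pl[pl$condition == cd, , drop = FALSE]
      m <- matrix(NA_real_, 7, 7)
      nt <- matrix(0L, 7, 7)
      for (a in 1:7) for (b in 1:7) {
        if (a == b) {
          sel <- cl$n_left == a & cl$n_right == a
          m[a, b] <- mean(cl$response[sel] == "left")
          nt[a, b] <- sum(sel)
        } else {
          sel_l <- cl$n_left == a & cl$n_right == b
          sel_r <- cl$n_left == b & cl$n_right == a
          chose_a <- c(cl$response[sel_l] == "left", cl$response[sel_r] == "right")
          m[a, b] <- mean(chose_a)
          nt[a, b] <- length(chose_a)
        }
      }
      perf_matrix(m, max(1L, round(mean(nt))), agent = parts[pi], condition = cd)
    })
  }
  list(matrices = matrices, participants = summary)
}

#' Tests on psychometric curves
#'
#' Per-distance one-sample t-tests against the 50 percent chance level,
#' and (for exactly two conditions) per-distance paired t-tests between
#' conditions, both reported raw and Bonferroni-corrected over the 13
#' distances.
#'
#' @param curves Named list of replicate-by-distance rate matrices (rows
#'   = replicates or participants, columns named by distance), or of
#'   [psych_curve()]s carrying a `"per_rep"` attribute.
#' @param baseline Chance level (default 0.5).
#' @return Data frame with one row per (test, distance).
#' @export
curve_tests <- function(curves, baseline = 0.5) {
  as_mat <- function(x) {
    if (inherits(x, "psych_curve")) {
      m <- attr(x, "per_rep")
      if (is.null(m)) stopf("curve_tests: curve has no replicate data")
      m
    } else as.matrix(x)
  }
  mats <- lapply(curves, as_mat)
  if (any(vapply(mats, nrow, integer(1)) < 2L))
    stopf("curve_tests: tests undefined with a single replicate")
  dist <- as.integer(colnames(mats[[1L]]))
  one <- do.call(rbind, lapply(names(mats), function(nm) {
    m <- mats[[nm]]
    do.call(rbind, lapply(seq_along(dist), function(i) {
      x <- m[, i]
      if (stats::sd(x) == 0) {
        data.frame(test = paste0(nm, " vs chance"), distance = dist[i],
                   estimate = mean(x), t = NA, df = NA,
                   p = as.numeric(all(x == baseline)))
      } else {
        tt <- stats::t.test(x, mu = baseline)
        data.frame(test = paste0(nm, " vs chance"), distance = dist[i],
                   estimate = mean(x), t = unname(tt$statistic),
                   df = unname(tt$parameter), p = tt$p.value)
      }
    }))
  }))
  out <- one
  if (length(mats) == 2L) {
    m1 <- mats[[1L]]; m2 <- mats[[2L]]
    pair <- do.call(rbind, lapply(seq_along(dist), function(i) {
      d <- m1[, i] - m2[, i]
      if (stats::sd(d) == 0) {
        data.frame(test = paste(names(mats), collapse = " vs "),
                   distance = dist[i], estimate = mean(d), t = NA, df = NA,
                   p = 1)
      } else {
        tt <- stats::t.test(m1[, i], m2[, i], paired = TRUE)
        data.frame(test = paste(names(mats), collapse = " vs "),
                   distance = dist[i], estimate = mean(d),
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p = tt$p.value)
      }
    }))
    out <- rbind(out, pair)
  }
  out$p_bonf <- NA_real_
  for (tn in unique(out$test)) {
    sel <- out$test == tn
    out$p_bonf[sel] <- pmin(out$p[sel] * sum(sel), 1)
  }
  out
}

#' Noise-robustness sweep of the full pipeline
#'
#' For each noise weight, overlays white noise on the images (the same
#' per-image noise seed across weights, so comparisons are paired),
#' extracts and normalizes classifier activations, decodes, and runs
#' the comparison task with identical comparison seeds across weights.
#' Images are first brought to the backbone's input resolution so that
#' every picture receives noise of the same granularity, as in a
#' dataset of equally sized pictures.
#'
#' @param decoder A trained [train_decoder()] model.
#' @param backbone The backbone used for extraction.
#' @param images List of `image_stim` (or pixel arrays).
#' @param groups True numerosity per image.
#' @param weights Non-negative noise weights (canonically 0, 0.5, 1, 2, 3).
#' @param trials_per_cell,reps,seed Comparison-task parameters.
#' @return Named list of [psych_curve()]s, one per weight.
#' @export
noise_robustness <- function(decoder, backbone, images, groups,
                             weights = c(0, 0.5, 1, 2, 3),
                             trials_per_cell = 50L, reps = 5L, seed = 1L) {
  if (any(weights < 0)) stopf("noise_robustness: weights must be >= 0")
  out <- list()
  for (w in weights) {
    noisy <- lapply(seq_along(images), function(i)
      as_pixels(add_noise(resize_image(as_pixels(images[[i]]), backbone$input_size),
                          w, seed = derive_seed(seed, "imgnoise", i))))
    acts <- normalize_unit_range(extract_activations(backbone, noisy))
    est <- decode(decoder, acts)
    pm <- run_comparison(est, groups, trials_per_cell = trials_per_cell,
                         reps = reps, seed = derive_seed(seed, "noisecmp"),
                         condition = sprintf("noise_%g", w))
    out[[sprintf("%g", w)]] <- psychometric(pm)
  }
  out
}
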