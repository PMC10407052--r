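#' Per-group, per-unit activation summaries
#'
#' For each numerosity group, computes the sample mean and sample
#' standard deviation (n - 1 denominator) of every unit's response
#' across the group's pictures. These are the ingredients of the
#' group-coding pattern: pictures with more items show higher per-unit
#' means and smaller cross-picture standard deviations.
#'
#' @param acts An `activation_matrix` (normalized rows recommended).
#' @param groups Integer group label per picture; defaults to
#'   `acts$meta$group`.
#' @return A `group_summary` object: matrices `mean` and `sd`
#'   (groups x units), vector `n`, and `groups` levels.
#' @export
group_summary <- function(acts, groups = NULL) {
  if (is.matrix(acts)) acts <- activation_matrix(acts)
  groups <- groups %||% acts$meta$group
  if (is.null(groups)) stopf("group_summary: no group labels supplied")
  if (length(groups) != nrow(acts$values))
    stopf("group_summary: %d labels for %d pictures", length(groups), nrow(acts$values))
  g <- factor(groups)
  n <- as.vector(table(g))
  if (any(n < 2L))
    stopf("group_summary: group '%s' has < 2 pictures; std undefined",
          levels(g)[which(n < 2L)[1L]])
  s1 <- rowsum(acts$values, g)
  s2 <- rowsum(acts$values^2, g)
  m <- s1 / n
  v <- (s2 - n * m^2) / (n - 1)
  structure(list(mean = m, sd = sqrt(pmax(v, 0)), n = n,
                 groups = levels(g)),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary> %d groups x %d units (n per group: %s)\n",
              nrow(x$mean), ncol(x$mean), paste(x$n, collapse = " ")))
  invisible(x)
}

#' Decile statistics of a group summary
#'
#' `mean90` is the 9th decile (90th percentile) of the per-unit means of
#' each group; `std10` the 1st decile (10th percentile) of the per-unit
#' standard deviations. Percentiles use linear interpolation between
#' order statistics (R quantile type 7), the documented convention.
#'
#' @param summary A [group_summary()].
#' @param which `"mean90"` or `"std10"`.
#' @return Named numeric vector, one value per group.
#' @export
decile_stats <- function(summary, which = c("mean90", "std10")) {
  which <- match.arg(which)
  m <- if (which == "mean90") summary$mean else summary$sd
  p <- if (which == "mean90") 0.9 else 0.1
  out <- apply(m, 1L, stats::quantile, probs = p, type = 7, names = FALSE)
  names(out) <- summary$groups
  out
}

#' Count of highly activated units per group
#'
#' @param summary A [group_summary()].
#' @param threshold Activation threshold (default 0.7).
#' @return Named integer vector: number of units whose group mean
#'   exceeds the threshold, per group.
#' @export
high_count <- function(summary, threshold = 0.7) {
  out <- rowSums(summary$mean > threshold)
  names(out) <- summary$groups
  out
}

#' Resampled group summaries
#'
#' Mirrors the resampling protocol: `n_pick` pictures are drawn at
#' random from each group's pool, summarized, and the draw is repeated
#' `reps` times (independent seeded draws) so that error bars can be put
#' on the decile statistics. If a pool is smaller than `n_pick`,
#' sampling is with replacement and the result is flagged.
#'
#' @param acts An `activation_matrix` with group metadata.
#' @param n_pick Pictures drawn per group per replicate (default 500).
#' @param reps Number of replicates (default 10).
#' @param seed RNG seed.
#' @param groups Optional group labels (default from metadata).
#' @return List of [group_summary()] objects (class
#'   `resample_summary`), with attribute `with_replacement`.
#' @export
resample_summary <- function(acts, n_pick = 500L, reps = 10L, seed = 1L,
                             groups = NULL) {
  groups <- groups %||% acts$meta$group
  g <- factor(groups)
  pools <- split(seq_along(g), g)
  replace <- any(vapply(pools, length, integer(1)) < n_pick)
  out <- lapply(seq_len(reps), function(r) {
    idx <- with_seed(derive_seed(seed, "resample", r), {
      unlist(lapply(pools, function(p)
        sample(p, n_pick, replace = replace || length(p) < n_pick)))
    })
    s <- group_summary(activation_matrix(acts$values[idx, , drop = FALSE],
                                         data.frame(picture_id = idx,
                                                    group = g[idx])))
    s$replicate <- r
    s
  })
  structure(out, class = "resample_summary", with_replacement = replace)
}

#' Trend tests on group summaries
#'
#' One-way ANOVA comparing a statistic across numerosity groups, with
#' Bonferroni-corrected pairwise post-hoc t-tests. Given a single
#' [group_summary()], the observations are the per-unit values (means or
#' standard deviations; e.g. 7 groups x 1000 units gives F(6, 6993)).
#' Given a [resample_summary()], the observations are the per-replicate
#' decile statistics (`mean90` for `"mean"`, `std10` for `"sd"`; 7
#' groups x 10 replicates gives F(6, 63)).
#'
#' @param summaries A `group_summary` or `resample_summary`.
#' @param statistic `"mean"` or `"sd"`.
#' @return A `trend_test_report`: list with `anova` (data frame: F,
#'   degrees of freedom, p) and `posthoc` (Bonferroni-adjusted pairwise
#'   p-value matrix), plus the raw observations.
#' @export
trend_tests <- function(summaries, statistic = c("mean", "sd")) {
  statistic <- match.arg(statistic)
  if (inherits(summaries, "group_summary")) {
    m <- if (statistic == "mean") summaries$mean else summaries$sd
    value <- as.vector(t(m))
    group <- factor(rep(summaries$groups, each = ncol(m)))
    label <- sprintf("per-unit %s", statistic)
  } else if (inherits(summaries, "resample_summary")) {
    which <- if (statistic == "mean") "mean90" else "std10"
    dec <- t(vapply(summaries, decile_stats, numeric(length(summaries[[1]]$groups)),
                    which = which))
    value <- as.vector(dec)
    group <- factor(rep(summaries[[1]]$groups, each = nrow(dec)))
    label <- which
  } else stopf("trend_tests: input must be a group_summary or resample_summary")
  if (nlevels(group) < 2L) stopf("trend_tests: need >= 2 groups")
  degenerate <- stats::var(value) == 0
  if (degenerate) {
    an <- data.frame(statistic = label, F = 0, df1 = nlevels(group) - 1L,
                     df2 = length(value) - nlevels(group), p = 1,
                     degenerate = TRUE)
    ph <- NULL
  } else {
    fit <- stats::aov(value ~ group)
    tab <- summary(fit)[[1L]]
    an <- data.frame(statistic = label, F = tab[1L, "F value"],
                     df1 = tab[1L, "Df"], df2 = tab[2L, "Df"],
                     p = tab[1L, "Pr(>F)"], degenerate = FALSE)
    ph <- tryCatch(
      stats::pairwise.t.test(value, group, p.adjust.method = "bonferroni",
                             pool.sd = FALSE)$p.value,
      error = function(e) NULL)   # constant within-group data: no post-hoc
  }
  structure(list(anova = an, posthoc = ph, value = value, group = group),
            class = "trend_test_report")
}

#' @export
print.trend_test_report <- function(x, ...) {
  a <- x$anova
  cat(sprintf("One-way ANOVA on %s: F(%d, %d) = %.2f, p = %.3g%s\n",
              a$statistic, a$df1, a$df2, a$F, a$p,
              if (a$degenerate) " [degenerate variance]" else ""))
  invisible(x)
}

#' Serialize a trend test report to CSV
#' @param x A `trend_test_report`.
#' @param path Output file path (the post-hoc matrix goes to
#'   `<path base>_posthoc.csv`).
#' @return `path`, invisibly.
#' @export
write_trend_report <- function(x, path) {
  utils::write.csv(x$anova, path, row.names = FALSE)
  if (!is.null(x$posthoc))
    utils::write.csv(as.data.frame(x$posthoc),
                     sub("(\\.csv)?$", "_posthoc.csv", path, perl = TRUE)[1L])
  invisible(path)
}
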