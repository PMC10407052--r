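#!/usr/bin/env Rscript
# Group coding of numerosity in the classifier layer.
#
# Generates the planted-structure activation study (50 increasing / 15
# decreasing units over a 300-unit layer, 1000 pictures per numerosity),
# normalizes each picture's responses to [0, 1], and summarizes the
# group-coding pattern: per-unit means and standard deviations by item
# count, their 9th/1st deciles under the 500-picture x 10 resampling
# protocol, and the one-way ANOVA trend tests.

library(numsense)
out <- "results/analysis"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- synth_activation_config(n_pictures_per_group = 1000L, seed = 101L)
acts <- normalize_unit_range(gen_activation_dataset(cfg))

rs <- resample_summary(acts, n_pick = 500L, reps = 10L, seed = 102L)
deciles <- data.frame(
  group = rs[[1L]]$groups,
  mean90 = colMeans(t(vapply(rs, decile_stats, numeric(7), which = "mean90"))),
  mean90_sd = apply(t(vapply(rs, decile_stats, numeric(7), which = "mean90")), 2, sd),
  std10 = colMeans(t(vapply(rs, decile_stats, numeric(7), which = "std10"))),
  std10_sd = apply(t(vapply(rs, decile_stats, numeric(7), which = "std10")), 2, sd))
write.csv(deciles, file.path(out, "01_decile_stats.csv"), row.names = FALSE)

tm <- trend_tests(rs, "mean")
ts <- trend_tests(rs, "sd")
write_trend_report(tm, file.path(out, "01_trend_mean90.csv"))
write_trend_report(ts, file.path(out, "01_trend_std10.csv"))

cat("Group-coding pattern over", nrow(acts$values), "pictures:\n")
print(cbind(deciles[1], round(deciles[-1], 4)))
cat(sprintf("mean90 rises monotonically: %s (ANOVA F(%d,%d) = %.1f, p = %.2g)\n",
            all(diff(deciles$mean90) > 0), tm$anova$df1, tm$anova$df2,
            tm$anova$F, tm$anova$p))
cat(sprintf("std10 falls from 1 to 7 items: %s (ANOVA F(%d,%d) = %.1f, p = %.2g); the step between the lowest counts is shallow\n",
            deciles$std10[7] < deciles$std10[1], ts$anova$df1, ts$anova$df2,
            ts$anova$F, ts$anova$p))
cat("Pictures with more items recruit stronger, more consistent",
    "co-activations across the classifier units.\n")
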