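#' Pipeline run configuration
#'
#' Bundles the stage configurations for an end-to-end synthetic run:
#' planted-structure training and validation activation sets, unit
#' selection, decoder training, the comparison task, embedding subsets
#' and the RSA stage. One global seed is fanned out to every stage
#' through a deterministic seed sequence.
#'
#' @param seed Global seed.
#' @param n_units,n_train_per_group,n_val_per_group Synthetic dataset
#'   sizes.
#' @param n_increasing,n_decreasing Planted monotone unit counts.
#' @param embed_fidelity Fidelity value or range for the generated
#'   pictures (a range spans inferior to superior embedding).
#' @param alpha Unit-selection threshold.
#' @param hidden,epochs,lr Decoder hyperparameters.
#' @param trials_per_cell,subset_trials,reps Comparison-task design
#'   (full pools / embedding subsets trials per cell, repetitions).
#' @param k Subset size per group for the embedding split.
#' @param n_reference_agents,rsa_min_refs RSA protocol parameters.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, n_units = 300L,
                            n_increasing = 50L, n_decreasing = 15L,
                            n_train_per_group = 400L, n_val_per_group = 150L,
                            embed_fidelity = c(0.1, 1), alpha = 0.1,
                            hidden = 200L, epochs = 250L, lr = 0.01,
                            trials_per_cell = 100L, subset_trials = 33L,
                            reps = 10L, k = 50L, n_reference_agents = 12L,
                            rsa_min_refs = 12L) {
  structure(list(seed = check_count(seed, "seed", min = 0L),
                 n_units = n_units, n_increasing = n_increasing,
                 n_decreasing = n_decreasing,
                 n_train_per_group = n_train_per_group,
                 n_val_per_group = n_val_per_group,
                 embed_fidelity = embed_fidelity, alpha = alpha,
                 hidden = hidden, epochs = epochs, lr = lr,
                 trials_per_cell = trials_per_cell,
                 subset_trials = subset_trials, reps = reps, k = k,
                 n_reference_agents = n_reference_agents,
                 rsa_min_refs = rsa_min_refs),
            class = "pipeline_config")
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the stages in dependency order -- synthetic activation
#' generation, normalization and group statistics, monotone-unit
#' selection, decoder training, the comparison task, embedding scoring
#' with superior/inferior subsets, and RSA across simulated agents --
#' writing every tabular artifact as CSV and reports as JSON under
#' `out_dir`, with a provenance file recording the configuration and
#' seed. Completed stages are cached under `out_dir/cache` and reused
#' unless `overwrite = TRUE`.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @param overwrite Recompute stages even if cached.
#' @param quiet Suppress progress messages.
#' @return A list with the main stage results (invisible).
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = "results/pipeline",
                         overwrite = FALSE, quiet = FALSE) {
  dir.create(file.path(out_dir, "cache"), recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    f <- file.path(out_dir, "cache", paste0(name, ".rds"))
    if (!overwrite && file.exists(f)) {
      say("[%s] cached", name)
      return(readRDS(f))
    }
    say("[%s] running", name)
    val <- force(expr)
    saveRDS(val, f)
    val
  }
  jsonlite::write_json(list(config = unclass(cfg),
                            package_version = as.character(utils::packageVersion("numsense")),
                            r_version = R.version.string),
                       file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  data <- stage("data", {
    structure_seed <- derive_seed(cfg$seed, "synth")
    train <- gen_activation_dataset(synth_activation_config(
      n_units = cfg$n_units, n_increasing = cfg$n_increasing,
      n_decreasing = cfg$n_decreasing,
      n_pictures_per_group = cfg$n_train_per_group,
      embed_fidelity = cfg$embed_fidelity, seed = structure_seed))
    val <- gen_activation_dataset(synth_activation_config(
      n_units = cfg$n_units, n_increasing = cfg$n_increasing,
      n_decreasing = cfg$n_decreasing,
      n_pictures_per_group = cfg$n_val_per_group,
      embed_fidelity = cfg$embed_fidelity, seed = structure_seed),
      picture_seed = derive_seed(cfg$seed, "valpics"))
    list(train = normalize_unit_range(train), val = normalize_unit_range(val),
         planted = attr(train, "planted"), profiles = attr(train, "profiles"))
  })

  stats_out <- stage("group_stats", {
    rs <- resample_summary(data$train, n_pick = min(500L, cfg$n_train_per_group),
                           reps = 10L, seed = derive_seed(cfg$seed, "resample"))
    dec <- data.frame(group = rs[[1L]]$groups,
                      mean90 = colMeans(t(vapply(rs, decile_stats,
                                                 numeric(7), which = "mean90"))),
                      std10 = colMeans(t(vapply(rs, decile_stats,
                                                numeric(7), which = "std10"))),
                      high_gt_0.7 = colMeans(t(vapply(rs, high_count,
                                                      numeric(7)))))
    utils::write.csv(dec, file.path(out_dir, "decile_stats.csv"), row.names = FALSE)
    tm <- trend_tests(rs, "mean"); ts <- trend_tests(rs, "sd")
    write_trend_report(tm, file.path(out_dir, "trend_mean90.csv"))
    write_trend_report(ts, file.path(out_dir, "trend_std10.csv"))
    list(deciles = dec, trend_mean = tm$anova, trend_sd = ts$anova)
  })

  units <- stage("units", {
    u <- select_monotone_units(data$train, alpha = cfg$alpha)
    utils::write.csv(data.frame(unit = c(u$increasing, u$decreasing),
                                direction = rep(c("increasing", "decreasing"),
                                                c(length(u$increasing),
                                                  length(u$decreasing)))),
                     file.path(out_dir, "selected_units.csv"), row.names = FALSE)
    u
  })

  dec_model <- stage("decoder", {
    train_decoder(data$train, units, hidden = cfg$hidden, epochs = cfg$epochs,
                  lr = cfg$lr, seed = derive_seed(cfg$seed, "decoder"))
  })

  comparison <- stage("comparison", {
    est <- decode(dec_model, data$val)
    utils::write.csv(cbind(data$val$meta, estimate = est),
                     file.path(out_dir, "decoded_estimates.csv"), row.names = FALSE)
    pm <- run_comparison(est, data$val$meta$group,
                         trials_per_cell = cfg$trials_per_cell, reps = cfg$reps,
                         seed = derive_seed(cfg$seed, "compare"))
    cv <- psychometric(pm)
    write_curve_csv(pm, file.path(out_dir, "performance_matrix.csv"))
    write_curve_csv(cv, file.path(out_dir, "psychometric_curve.csv"))
    list(estimates = est, perf = pm, curve = cv)
  })

  embed <- stage("embedding", {
    sc <- embedding_scores(data$val, data$profiles)
    sc <- split_subsets(sc, k = min(cfg$k, floor(cfg$n_val_per_group / 2)))
    utils::write.csv(sc, file.path(out_dir, "embedding_scores.csv"), row.names = FALSE)
    run_sub <- function(sub, seed_tag) {
      keep <- sc$subset == sub
      pm <- run_comparison(comparison$estimates[keep], sc$group[keep],
                           trials_per_cell = cfg$subset_trials, reps = cfg$reps,
                           seed = derive_seed(cfg$seed, seed_tag),
                           condition = sub)
      psychometric(pm)
    }
    cs <- run_sub("superior", "cmp_sup")
    ci <- run_sub("inferior", "cmp_inf")
    write_curve_csv(cs, file.path(out_dir, "curve_superior.csv"))
    write_curve_csv(ci, file.path(out_dir, "curve_inferior.csv"))
    tests <- curve_tests(list(superior = cs, inferior = ci))
    utils::write.csv(tests, file.path(out_dir, "curve_tests.csv"), row.names = FALSE)
    list(scores = sc, curve_superior = cs, curve_inferior = ci, tests = tests)
  })

  rsa_out <- stage("rsa", {
    agent_rsm <- function(seed_tag, est, groups, sub_tags) {
      cs <- psychometric(run_comparison(est[sub_tags == "superior"],
                                        groups[sub_tags == "superior"],
                                        trials_per_cell = cfg$subset_trials,
                                        reps = 1L, seed = seed_tag))
      ci <- psychometric(run_comparison(est[sub_tags == "inferior"],
                                        groups[sub_tags == "inferior"],
                                        trials_per_cell = cfg$subset_trials,
                                        reps = 1L, seed = seed_tag + 1L))
      rsm_from_curves(cs, ci)
    }
    sc <- embed$scores
    refs <- lapply(seq_len(cfg$n_reference_agents), function(i)
      agent_rsm(derive_seed(cfg$seed, "rsaref", i), comparison$estimates,
                data$val$meta$group, sc$subset))
    cand_self <- agent_rsm(derive_seed(cfg$seed, "rsacand"), comparison$estimates,
                           data$val$meta$group, sc$subset)
    null_units <- unit_set(seq_len(ncol(data$train$values)))
    null_dec <- train_decoder(data$train, null_units,
                              targets = with_seed(derive_seed(cfg$seed, "shuf"),
                                                  sample(data$train$meta$group)),
                              hidden = cfg$hidden, epochs = cfg$epochs,
                              lr = cfg$lr, seed = derive_seed(cfg$seed, "nulldec"))
    cand_null <- agent_rsm(derive_seed(cfg$seed, "rsanull"),
                           decode(null_dec, data$val), data$val$meta$group,
                           sc$subset)
    cands <- list(network = cand_self,
                  shuffled = shuffle_rsm(cand_self,
                                         seed = derive_seed(cfg$seed, "rsaperm")),
                  label_shuffled_decoder = cand_null)
    rep <- compare_rsms(refs, cands, min_refs = cfg$rsa_min_refs)
    jsonlite::write_json(list(candidate_tests = rep$candidate_tests,
                              pairwise = rep$pairwise),
                         file.path(out_dir, "rsa_report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    utils::write.csv(rep$candidate_tests, file.path(out_dir, "rsa_candidates.csv"),
                     row.names = FALSE)
    rep
  })

  say("pipeline complete: %s", out_dir)
  invisible(list(data = data, group_stats = stats_out, units = units,
                 decoder = dec_model, comparison = comparison,
                 embedding = embed, rsa = rsa_out))
}
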