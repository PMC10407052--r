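#' Configuration for the planted-structure activation generator
#'
#' Describes a synthetic category-layer activation dataset with the
#' statistical structure seen in classifier layers of object-recognition
#' networks viewing scenes with 1..`n_groups` objects: a background of
#' weak non-negative co-activations, a set of planted units whose
#' cross-picture mean increases (or decreases) with the item count while
#' the cross-picture standard deviation shrinks, plus a category-profile
#' component whose strength per picture is governed by an embedding
#' fidelity knob.
#'
#' @param n_units Number of classifier units (columns).
#' @param n_groups Number of numerosity levels (default 7, counts 1..7).
#' @param n_pictures_per_group Pictures per numerosity level.
#' @param n_increasing,n_decreasing Counts of planted monotone units.
#' @param slope_mean Per-level increment of a planted unit's mean
#'   activation (activation units).
#' @param sigma_scale Multiplicative per-level shrink factor in `(0, 1]`
#'   applied to the planted units' cross-picture standard deviation.
#' @param baseline_mean,baseline_sigma Mean and standard deviation of the
#'   background co-activation (before rectification at zero).
#' @param n_categories Number of object categories used for the
#'   category-profile component.
#' @param diag_strength Height of a category profile's preferred-unit
#'   response, in `(0, 1]`.
#' @param profile_scale Weight of the category-profile component added to
#'   a picture's mean activation.
#' @param embed_fidelity Either a single value in `[0, 1]` or a length-2
#'   range; each picture's activation vector is a convex mixture
#'   `f * structured + (1 - f) * noise`, so `f` maps directly onto the
#'   Pearson coefficient used by the embedding analysis.
#' @param seed RNG seed.
#' @return A validated `synth_activation_config` list.
#' @export
synth_activation_config <- function(n_units = 300L, n_groups = 7L,
                                    n_pictures_per_group = 150L,
                                    n_increasing = 50L, n_decreasing = 15L,
                                    slope_mean = 0.05, sigma_scale = 0.9,
                                    baseline_mean = 0.15, baseline_sigma = 0.15,
                                    n_categories = 20L, diag_strength = 0.8,
                                    profile_scale = 1, embed_fidelity = 1,
                                    seed = 1L) {
  cfg <- list(
    n_units = check_count(n_units, "n_units"),
    n_groups = check_count(n_groups, "n_groups", min = 2L),
    n_pictures_per_group = check_count(n_pictures_per_group, "n_pictures_per_group"),
    n_increasing = check_count(n_increasing, "n_increasing", min = 0L),
    n_decreasing = check_count(n_decreasing, "n_decreasing", min = 0L),
    slope_mean = check_real(slope_mean, "slope_mean", lo = 0),
    sigma_scale = check_real(sigma_scale, "sigma_scale", lo = 0, hi = 1, lo_open = TRUE),
    baseline_mean = check_real(baseline_mean, "baseline_mean", lo = 0),
    baseline_sigma = check_real(baseline_sigma, "baseline_sigma", lo = 0, lo_open = TRUE),
    n_categories = check_count(n_categories, "n_categories"),
    diag_strength = check_real(diag_strength, "diag_strength", lo = 0, hi = 1, lo_open = TRUE),
    profile_scale = check_real(profile_scale, "profile_scale", lo = 0),
    embed_fidelity = embed_fidelity,
    seed = check_count(seed, "seed", min = 0L))
  f <- cfg$embed_fidelity
  if (!is.numeric(f) || !length(f) %in% 1:2 || any(is.na(f)) ||
      any(f < 0) || any(f > 1) || (length(f) == 2L && f[1] > f[2]))
    stopf("configuration error: 'embed_fidelity' must be a value or ascending range in [0, 1]")
  if (cfg$n_increasing + cfg$n_decreasing > cfg$n_units)
    stopf("configuration error: 'n_increasing' + 'n_decreasing' exceeds 'n_units'")
  if (cfg$n_categories > cfg$n_units)
    stopf("configuration error: 'n_categories' exceeds 'n_units'")
  class(cfg) <- "synth_activation_config"
  cfg
}

#' Population moments implied by a planted-activation configuration
#'
#' Returns the per-group mean and standard deviation of a planted
#' increasing unit, a planted decreasing unit, and a background unit,
#' after rectification at zero (with `embed_fidelity = 1` and ignoring
#' the category-profile component). Used to verify the generator's
#' effect-size contract against sample estimates.
#'
#' @param cfg A `synth_activation_config`.
#' @return Data frame with columns `group`, `kind`, `mean`, `sd`.
#' @export
planted_population_moments <- function(cfg) {
  g <- seq_len(cfg$n_groups)
  grid <- expand.grid(group = g, kind = c("increasing", "decreasing", "background"),
                      stringsAsFactors = FALSE)
  mu <- with(grid, ifelse(kind == "increasing",
                          cfg$baseline_mean + cfg$slope_mean * (group - 1),
                   ifelse(kind == "decreasing",
                          cfg$baseline_mean + cfg$slope_mean * (cfg$n_groups - group),
                          cfg$baseline_mean)))
  sd0 <- with(grid, ifelse(kind == "background", cfg$baseline_sigma,
                           cfg$baseline_sigma * cfg$sigma_scale^(group - 1)))
  grid$mean <- rectnorm_mean(mu, sd0)
  grid$sd <- rectnorm_sd(mu, sd0)
  grid
}

#' Generate a planted-structure activation dataset
#'
#' Draws a raw (unnormalized, non-negative) pictures x units activation
#' table. Planted increasing units have population means strictly
#' increasing in the numerosity group and cross-picture standard
#' deviations shrinking by `sigma_scale` per level; decreasing units
#' mirror them. Every picture is assigned a category whose profile row
#' (see [gen_category_profiles()]) is added with weight `profile_scale`,
#' and the whole structured vector is mixed with unstructured noise
#' according to the picture's embedding fidelity.
#'
#' @param cfg A `synth_activation_config`. The planted-unit layout and
#'   the category profiles (the "network structure") are derived from
#'   `cfg$seed` alone, so datasets generated from the same config seed
#'   share the same tuned units and profiles.
#' @param picture_seed Seed for the picture-level randomness (category
#'   assignment, fidelity, response noise); defaults to `cfg$seed`. Use
#'   a different value to draw an independent validation set over the
#'   same network structure.
#' @return A raw `activation_matrix` whose metadata records the true
#'   group, category and fidelity per picture, with attributes `planted`
#'   (list of increasing/decreasing unit indices), `profiles` (the
#'   category-profile matrix used) and `config`.
#' @export
gen_activation_dataset <- function(cfg, picture_seed = cfg$seed) {
  if (!inherits(cfg, "synth_activation_config")) cfg <- do.call(synth_activation_config, cfg)
  n <- cfg$n_groups * cfg$n_pictures_per_group
  # profile rows are category means, so their background scatter is
  # smaller than the single-picture noise (half sigma)
  profiles <- gen_category_profiles(cfg$n_categories, cfg$n_units,
                                    diag_strength = cfg$diag_strength,
                                    baseline_mean = cfg$baseline_mean,
                                    baseline_sigma = cfg$baseline_sigma / 2,
                                    seed = derive_seed(cfg$seed, "profiles"))
  # planted units avoid the categories' preferred units where possible;
  # drawn from the structure seed only, independent of the picture draw
  planted <- with_seed(derive_seed(cfg$seed, "structure"), {
    pool <- setdiff(seq_len(cfg$n_units), seq_len(cfg$n_categories))
    need <- cfg$n_increasing + cfg$n_decreasing
    if (length(pool) < need) pool <- seq_len(cfg$n_units)
    picked <- if (need > 0L) sample(pool, need) else integer(0)
    inc <- sort(picked[seq_len(cfg$n_increasing)])
    list(increasing = inc, decreasing = sort(setdiff(picked, inc)))
  })
  inc <- planted$increasing
  dec <- planted$decreasing
  with_seed(derive_seed(picture_seed, "pictures"), {
    group <- rep(seq_len(cfg$n_groups), each = cfg$n_pictures_per_group)
    category <- sample.int(cfg$n_categories, n, replace = TRUE)
    f <- cfg$embed_fidelity
    fidelity <- if (length(f) == 2L) stats::runif(n, f[1], f[2]) else rep(f, n)

    # per-group mean / sd templates over units
    mu_g <- matrix(cfg$baseline_mean, cfg$n_groups, cfg$n_units)
    sd_g <- matrix(cfg$baseline_sigma, cfg$n_groups, cfg$n_units)
    lev <- seq_len(cfg$n_groups) - 1L
    mu_g[, inc] <- cfg$baseline_mean + cfg$slope_mean * lev
    mu_g[, dec] <- cfg$baseline_mean + cfg$slope_mean * rev(lev)
    sd_g[, c(inc, dec)] <- cfg$baseline_sigma * cfg$sigma_scale^lev

    mu <- mu_g[group, , drop = FALSE] +
      cfg$profile_scale * unclass(profiles)[category, , drop = FALSE]
    sdm <- sd_g[group, , drop = FALSE]
    # the preferred-category response is the most stereotyped one: the
    # picture's top unit varies less across exemplars than the sidebands
    idx_pref <- cbind(seq_len(n), category)
    sdm[idx_pref] <- sdm[idx_pref] / 2
    structured <- mu + matrix(stats::rnorm(n * cfg$n_units), n) * sdm
    noise <- matrix(stats::rnorm(n * cfg$n_units, cfg$baseline_mean,
                                 cfg$baseline_sigma), n)
    raw <- pmax(fidelity * structured + (1 - fidelity) * noise, 0)

    meta <- data.frame(picture_id = sprintf("p%05d", seq_len(n)),
                       group = group, category = category,
                       fidelity = fidelity, variant = "synthetic",
                       stringsAsFactors = FALSE)
    acts <- activation_matrix(raw, meta, layer = "classifier")
    attr(acts, "planted") <- list(increasing = inc, decreasing = dec)
    attr(acts, "profiles") <- profiles
    attr(acts, "config") <- cfg
    acts
  })
}

#' Generate synthetic category activation profiles
#'
#' Builds a categories x units matrix in which row `i` peaks at unit `i`
#' (height `diag_strength`) over a background of weak rectified-Gaussian
#' co-activations, mirroring the diagonal structure of a classifier
#' layer's category-averaged response matrix.
#'
#' @param n_categories Number of categories (rows); must not exceed
#'   `n_units`.
#' @param n_units Number of classifier units (columns).
#' @param diag_strength Preferred-unit response height in `(0, 1]`.
#' @param baseline_mean,baseline_sigma Background co-activation
#'   parameters (rectified Gaussian; pass 0 and a tiny sigma for an
#'   identity-like matrix).
#' @param seed RNG seed.
#' @return A `category_profiles` matrix.
#' @export
gen_category_profiles <- function(n_categories, n_units, diag_strength = 0.8,
                                  baseline_mean = 0.15, baseline_sigma = 0.15,
                                  seed = 1L) {
  n_categories <- check_count(n_categories, "n_categories")
  n_units <- check_count(n_units, "n_units")
  check_real(diag_strength, "diag_strength", lo = 0, hi = 1, lo_open = TRUE)
  if (n_categories > n_units)
    stopf("dimension error: n_categories (%d) exceeds n_units (%d)",
          n_categories, n_units)
  with_seed(seed, {
    prof <- matrix(pmax(stats::rnorm(n_categories * n_units, baseline_mean,
                                     baseline_sigma), 0),
                   n_categories, n_units)
    # background stays strictly below the preferred-unit response
    prof <- pmin(prof, diag_strength * 0.95)
    prof[cbind(seq_len(n_categories), seq_len(n_categories))] <- diag_strength
    rownames(prof) <- sprintf("cat%03d", seq_len(n_categories))
    structure(prof, class = c("category_profiles", "matrix"))
  })
}
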