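# Shared fixtures, built once per test run and cached in an environment.
# The large planted dataset reproduces the reference study conditions
# (50 increasing / 15 decreasing units, slope 0.05, sigma shrink 0.9,
# 1000 pictures per numerosity).

fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = fixtures, inherits = FALSE))
    assign(name, force(expr), envir = fixtures)
  get(name, envir = fixtures, inherits = FALSE)
}

planted_big <- function() fixture("planted_big", {
  cfg <- synth_activation_config(n_pictures_per_group = 1000, seed = 101)
  raw <- gen_activation_dataset(cfg)
  acts <- normalize_unit_range(raw)
  list(cfg = cfg, acts = acts, planted = attr(raw, "planted"),
       profiles = attr(raw, "profiles"))
})

planted_big_val <- function() fixture("planted_big_val", {
  cfg <- synth_activation_config(n_pictures_per_group = 150, seed = 101)
  normalize_unit_range(gen_activation_dataset(cfg, picture_seed = 202))
})

planted_small <- function() fixture("planted_small", {
  cfg <- synth_activation_config(n_units = 100L, n_pictures_per_group = 300L,
                                 n_increasing = 20L, n_decreasing = 5L,
                                 seed = 7)
  raw <- gen_activation_dataset(cfg)
  list(cfg = cfg, acts = normalize_unit_range(raw),
       planted = attr(raw, "planted"), profiles = attr(raw, "profiles"))
})

toy_set <- function() fixture("toy_set", {
  gen_image_dataset(n_categories = 10L, n_per_category = 30L,
                    image_size = 64L, seed = 11)
})

toy_backbone <- function() fixture("toy_backbone", {
  toy <- toy_set()
  train_mock_backbone(toy$images, toy$labels, epochs = 300L, seed = 12)
})

# quantile oracle: linear interpolation between order statistics,
# implemented directly from the definition (independent of quantile())
sorted_quantile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
}

# Pearson correlation from the direct formula
pearson_direct <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
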