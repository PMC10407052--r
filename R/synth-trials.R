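#' Psychometric curve container
#'
#' Reported-choice rate as a function of signed numerical distance.
#'
#' @param distance Signed distances (typically -6..6).
#' @param rate Reported rate `S(d)` in `[0, 1]`.
#' @param n_trials Trials per distance.
#' @param agent Agent tag (network / human / participant id).
#' @param condition Condition tag (e.g. `"superior"`, `"inferior"`).
#' @return A `psych_curve` data frame.
#' @export
psych_curve <- function(distance, rate, n_trials = NA_integer_,
                        agent = "network", condition = "all") {
  if (any(rate < 0 | rate > 1, na.rm = TRUE))
    stopf("psych_curve: rates outside [0, 1]")
  structure(data.frame(distance = as.integer(distance), rate = rate,
                       n_trials = n_trials),
            agent = agent, condition = condition,
            class = c("psych_curve", "data.frame"))
}

#' Logistic psychometric curve
#'
#' `S(d) = lapse/2 + (1 - lapse) * logistic(slope * d)`: the canonical
#' S-shaped numerical-distance function crossing 0.5 at distance 0.
#'
#' @param slope Logistic slope per unit of numerical distance.
#' @param lapse Lapse rate in `[0, 1]` (default 0).
#' @param distances Distance support (default -6..6).
#' @param agent,condition Tags.
#' @return A [psych_curve()].
#' @export
logistic_psych_curve <- function(slope = 0.8, lapse = 0, distances = -6:6,
                                 agent = "generator", condition = "all") {
  check_real(lapse, "lapse", lo = 0, hi = 1)
  psych_curve(distances, lapse / 2 + (1 - lapse) * stats::plogis(slope * distances),
              agent = agent, condition = condition)
}

curve_rate_at <- function(curve, d) {
  i <- match(d, curve$distance)
  if (anyNA(i)) stopf("curve does not cover distance %s",
                      paste(d[is.na(i)], collapse = ", "))
  curve$rate[i]
}

#' Generate a synthetic human trial log
#'
#' Simulates the two-alternative numerosity comparison session: for each
#' participant and condition, every ordered pair of numerosities 1..7
#' appears `trials_per_cell` times (so sides are counterbalanced by
#' design), and the probability of choosing the left side is the
#' condition's psychometric curve evaluated at `n_left - n_right`,
#' optionally distorted by a per-participant lapse rate and additive
#' left-side bias (both recorded). With two conditions and 50
#' trials per cell this yields the standard 7 x 7 x 50 x 2 = 4900 rows
#' per participant.
#'
#' @param curves Named list of [psych_curve()]s, one per condition; all
#'   rates must lie in `[0, 1]`.
#' @param n_participants Number of simulated participants.
#' @param trials_per_cell Trials per (condition, ordered cell).
#' @param seed RNG seed.
#' @param lapse,bias Scalars or per-participant vectors.
#' @return A `trial_log` data frame with columns `participant`, `trial`,
#'   `n_left`, `n_right`, `picture_left`, `picture_right`, `condition`,
#'   `response` (`"left"`/`"right"`), `rt`; participant parameters in
#'   attribute `"params"`.
#' @export
gen_trial_log <- function(curves, n_participants = 12L, trials_per_cell = 50L,
                          seed = 1L, lapse = 0, bias = 0) {
  if (inherits(curves, "psych_curve")) curves <- list(all = curves)
  if (is.null(names(curves)) || any(!nzchar(names(curves))))
    names(curves) <- paste0("cond", seq_along(curves))
  for (cv in curves)
    if (any(cv$rate < 0 | cv$rate > 1))
      stopf("gen_trial_log: curve rates outside [0, 1]")
  n_participants <- check_count(n_participants, "n_participants")
  trials_per_cell <- check_count(trials_per_cell, "trials_per_cell")
  lapse <- rep_len(lapse, n_participants)
  bias <- rep_len(bias, n_participants)
  cells <- expand.grid(n_left = 1:7, n_right = 1:7)
  logs <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    rows <- do.call(rbind, lapply(names(curves), function(cond) {
      df <- cells[rep(seq_len(nrow(cells)), each = trials_per_cell), ]
      df$condition <- cond
      df$p_left <- pmin(pmax(
        lapse[p] / 2 + (1 - lapse[p]) *
          curve_rate_at(curves[[cond]], df$n_left - df$n_right) + bias[p], 0), 1)
      df
    }))
    with_seed(derive_seed(seed, "trials", p), {
      rows <- rows[sample.int(nrow(rows)), ]
      rows$response <- ifelse(stats::runif(nrow(rows)) < rows$p_left, "left", "right")
      rows$rt <- round(stats::rlnorm(nrow(rows), log(0.7), 0.3), 3)
    })
    rows$participant <- sprintf("s%02d", p)
    rows$trial <- seq_len(nrow(rows))
    rows$picture_left <- sprintf("p%d_%05d", rows$n_left, seq_len(nrow(rows)))
    rows$picture_right <- sprintf("p%d_%05d", rows$n_right, seq_len(nrow(rows)))
    rows$p_left <- NULL
    logs[[p]] <- rows
  }
  out <- do.call(rbind, logs)
  rownames(out) <- NULL
  out <- out[, c("participant", "trial", "n_left", "n_right", "picture_left",
                 "picture_right", "condition", "response", "rt")]
  structure(out, params = data.frame(participant = sprintf("s%02d", seq_len(n_participants)),
                                     lapse = lapse, bias = bias),
            class = c("trial_log", "data.frame"))
}

#' Write / read a trial log as CSV
#' @param log A `trial_log` data frame.
#' @param path CSV file path.
#' @return `path` (write) or a validated `trial_log` (read).
#' @export
write_trial_log <- function(log, path) {
  utils::write.csv(log, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "n_left", "n_right", "condition", "response")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("trial log missing columns: %s", paste(miss, collapse = ", "))
  structure(df, class = c("trial_log", "data.frame"))
}
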