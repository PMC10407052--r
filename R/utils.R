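# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stopf("configuration error: '%s' must be an integer >= %d", name, min)
  as.integer(x)
}

check_real <- function(x, name, lo = -Inf, hi = Inf, lo_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi ||
      (lo_open && x <= lo))
    stopf("configuration error: '%s' must be a real in %s%g, %g]",
          name, if (lo_open) "(" else "[", lo, hi)
  as.numeric(x)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so seeded helpers do not
#' disturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage / per-cell seed derivation. Keeps every stream
# independent while reproducible from one global seed; values stay < 2^31.
derive_seed <- function(seed, ...) {
  parts <- c(...)
  h <- as.double(seed) %% 2147483647
  for (p in parts) {
    v <- if (is.character(p)) sum(utf8ToInt(p) * seq_along(utf8ToInt(p))) else as.double(p)
    h <- (h * 48271 + v + 1) %% 2147483647
  }
  as.integer(h)
}

# Rectified-normal moments: X = max(Z, 0), Z ~ N(mu, sd).
# Used by the synthetic generators and their effect-size contract tests.
rectnorm_mean <- function(mu, sd) {
  z <- mu / sd
  mu * stats::pnorm(z) + sd * stats::dnorm(z)
}

rectnorm_sd <- function(mu, sd) {
  z <- mu / sd
  m1 <- rectnorm_mean(mu, sd)
  m2 <- (mu^2 + sd^2) * stats::pnorm(z) + mu * sd * stats::dnorm(z)
  sqrt(pmax(m2 - m1^2, 0))
}
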