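# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards so library code never clobbers user seeds.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Draw n child seeds (< 2^31) from a parent seed, for seeding sub-stages.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Truncated-normal draws by inverse-CDF; deterministic draw count.
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  p_lo <- stats::pnorm(lower, mean, sd)
  p_hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, p_lo, p_hi), mean, sd)
}

# Stationary AR(1) series with marginal standard deviation `sd_marginal`.
ar1_series <- function(n, sd_marginal, phi) {
  if (sd_marginal == 0 || n == 0L) return(numeric(n))
  innov <- stats::rnorm(n, 0, sd_marginal * sqrt(1 - phi^2))
  innov[1L] <- stats::rnorm(1L, 0, sd_marginal)
  as.numeric(stats::filter(innov, phi, method = "recursive"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_stage <- function(stage, msg) {
  stop(sprintf("[%s] %s", stage, msg), call. = FALSE)
}
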