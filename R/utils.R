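# Small internal helpers.

# Evaluate expr with a locally-seeded RNG, restoring the caller's RNG state
# afterwards so package functions never perturb the user's random stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a reproducible child seed from a base seed and a stream label,
# keeping the result inside the 32-bit signed integer range.
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1103515245 + stream * 12345) %% 2147483647)
}

# log(sum(exp(x))) without overflow
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Weighted quantile of a Gaussian mixture sum_k w_k N(mu_k, sd_k^2), by
# monotone root-finding on the mixture CDF.
mixnorm_quantile <- function(p, w, mu, sd) {
  sd <- pmax(sd, 1e-300)
  cdf <- function(x) sum(w * stats::pnorm(x, mu, sd))
  lo <- min(mu - 10 * sd); hi <- max(mu + 10 * sd)
  vapply(p, function(pp) stats::uniroot(function(x) cdf(x) - pp, c(lo, hi),
                                        tol = 1e-10)$root, numeric(1))
}
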