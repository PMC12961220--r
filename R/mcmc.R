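# Independent MCMC oracle for small instances. Latent updates draw from the
# exact sparse-Gaussian conditional (gaussian/lognormal) or an
# independence-Metropolis proposal built from the local Laplace
# approximation (gamma). Hyperparameter updates are *joint* moves: a
# random-walk proposal on one log-hyperparameter is accompanied by a fresh
# latent draw from the proposal-side conditional, with the proposal density
# appearing in the acceptance ratio -- a valid Metropolis-Hastings kernel on
# the joint space whose theta-marginal behaves like a marginal sampler, so
# hyperparameters are not damped by conditioning on the current field. The
# acceptance ratios use only conditional densities and proposal
# corrections; the grid engine's marginal-likelihood formula is never used.

latent_logdens <- function(md, spec, theta, x, eta) {
  prior <- build_prior_precision(md, spec, theta)
  lp <- prior$logdet / 2 - 0.5 * as.numeric(x %*% (prior$Q0 %*% x))
  ll <- if (spec$family == "gamma") {
    gamma_loglik(md$y, eta, exp(theta[["log_shape"]]))
  } else {
    sum(stats::dnorm(md$z, eta, exp(theta[["log_sigma_obs"]]), log = TRUE))
  }
  list(lp_x = lp, ll = ll)
}

# Gaussian proposal machinery at a given theta: the exact conditional for
# gaussian/lognormal, the Laplace approximation for gamma.
oracle_proposal <- function(md, spec, theta, MtM, Mtz, x_init = NULL) {
  res <- if (spec$family == "gamma") {
    inner_gamma(md, spec, theta, want_chol = TRUE, x_init = x_init)
  } else {
    inner_gaussian(md, spec, theta, MtM, Mtz, want_chol = TRUE)
  }
  if (!is.finite(res$logml)) return(NULL)
  res$ldet <- as.numeric(Matrix::determinant(res$ch, logarithm = TRUE,
                                             sqrt = TRUE)$modulus)
  res
}

proposal_draw <- function(prop, d_lat) {
  zz <- stats::rnorm(d_lat)
  pert <- Matrix::solve(prop$ch, Matrix::solve(prop$ch, zz, system = "Lt"),
                        system = "Pt")
  prop$mu + as.vector(pert)
}

proposal_logdens <- function(prop, x) {
  dv <- x - prop$mu
  prop$ldet - 0.5 * as.numeric(dv %*% (prop$Qp %*% dv))
}

#' MCMC oracle for a model specification
#'
#' Used in tests to validate the deterministic grid engine on small
#' instances (a few hundred mesh nodes at most). Returns recorded draws of
#' the fixed effects and hyperparameters with split-R-hat and effective
#' sample sizes; a split-R-hat above 1.1 raises a warning.
#'
#' @param spec A [model_spec()].
#' @param data Modeling table (same contract as [fit_spde()]).
#' @param mesh A `soil_mesh` or `NULL`.
#' @param iterations Total iterations (first half is burn-in).
#' @param seed Integer seed (fixed seed gives identical chains).
#' @param control List: `response`, `rw_sd` initial random-walk scale.
#' @return An `mcmc_oracle` object: `samples` (matrix, post-burn-in),
#'   `summary` (mean, MCSE, ESS, split-R-hat per column), `accept_rates`.
#' @export
mcmc_oracle <- function(spec, data, mesh = NULL, iterations = 4000L, seed = 1L,
                        control = list()) {
  stopifnot(inherits(spec, "model_spec"))
  md <- build_model_data(spec, data, mesh, response = control$response %||% "conc")
  MtM <- Matrix::forceSymmetric(Matrix::crossprod(md$M))
  Mtz <- as.vector(Matrix::crossprod(md$M, md$z))
  tnames <- theta_names_for(spec)
  range_u <- spec$priors$pc_range[["u"]]
  if (is.na(range_u)) range_u <- default_range_threshold(md$data)
  log_hyperprior <- make_log_hyperprior(spec, range_u)

  z0 <- if (spec$family == "gamma") log(md$y) else md$z
  sk <- stats::lm.fit(md$X, z0)
  sd_r <- max(stats::sd(sk$residuals), 1e-3)
  theta <- c(log_range = log(max(diff(range(md$data$x_km)), 1) / 4),
             log_sigma = log(0.7 * sd_r + 1e-4),
             log_sigma_obs = log(0.7 * sd_r + 1e-4),
             log_shape = log(max(1 / sd_r^2, 0.1)),
             log_tau_state = log(1 / (0.25 * sd_r^2 + 1e-4)))[tnames]

  d_lat <- md$p + md$m + md$k
  burn <- floor(iterations / 2)
  keep_cols <- c(colnames(md$X), sub("^log_", "", tnames))
  samples <- matrix(NA_real_, iterations - burn, length(keep_cols),
                    dimnames = list(NULL, keep_cols))
  rw_sd <- rep(control$rw_sd %||% 0.4, length(tnames))
  acc <- num <- rep(0, length(tnames))
  acc_lat <- 0; num_lat <- 0

  with_seed(seed, {
    cur_prop <- oracle_proposal(md, spec, theta, MtM, Mtz)
    x <- proposal_draw(cur_prop, d_lat)
    eta <- as.vector(md$M %*% x)
    cur <- latent_logdens(md, spec, theta, x, eta)
    for (it in seq_len(iterations)) {
      # ---- latent refresh at the current hyperparameters
      if (spec$family == "gamma") {
        x_new <- proposal_draw(cur_prop, d_lat)
        eta_new <- as.vector(md$M %*% x_new)
        new <- latent_logdens(md, spec, theta, x_new, eta_new)
        la <- (new$ll + new$lp_x - proposal_logdens(cur_prop, x_new)) -
          (cur$ll + cur$lp_x - proposal_logdens(cur_prop, x))
        num_lat <- num_lat + 1
        if (is.finite(la) && log(stats::runif(1)) < la) {
          x <- x_new; eta <- eta_new; cur <- new; acc_lat <- acc_lat + 1
        }
      } else {
        x <- proposal_draw(cur_prop, d_lat)   # exact conditional: always accept
        eta <- as.vector(md$M %*% x)
        cur <- latent_logdens(md, spec, theta, x, eta)
      }
      # ---- joint hyperparameter + latent moves, one component at a time
      for (j in seq_along(tnames)) {
        theta_new <- theta
        theta_new[j] <- theta[j] + stats::rnorm(1, sd = rw_sd[j])
        prop_new <- oracle_proposal(md, spec, theta_new, MtM, Mtz, x_init = x)
        num[j] <- num[j] + 1
        if (!is.null(prop_new)) {
          x_new <- proposal_draw(prop_new, d_lat)
          eta_new <- as.vector(md$M %*% x_new)
          new <- latent_logdens(md, spec, theta_new, x_new, eta_new)
          la <- (new$ll + new$lp_x + log_hyperprior(theta_new) -
                   proposal_logdens(prop_new, x_new)) -
            (cur$ll + cur$lp_x + log_hyperprior(theta) -
               proposal_logdens(cur_prop, x))
          if (is.finite(la) && log(stats::runif(1)) < la) {
            theta <- theta_new; x <- x_new; eta <- eta_new
            cur <- new; cur_prop <- prop_new
            acc[j] <- acc[j] + 1
          }
        }
        if (it <= burn && it %% 25 == 0) {   # scale adaptation during burn-in
          rate <- acc[j] / max(num[j], 1)
          rw_sd[j] <- min(3, max(0.02, rw_sd[j] * exp(0.6 * (rate - 0.3))))
          acc[j] <- num[j] <- 0
        }
      }
      if (it > burn)
        samples[it - burn, ] <- c(x[md$beta_idx], exp(theta))
    }
  })
  summ <- mcmc_summary(samples)
  if (any(summ$rhat > 1.1, na.rm = TRUE))
    warning("split R-hat > 1.1 for: ",
            paste(summ$parameter[summ$rhat > 1.1], collapse = ", "))
  structure(list(samples = samples, summary = summ,
                 accept_rates = c(stats::setNames(acc / pmax(num, 1), tnames),
                                  latent = if (num_lat > 0) acc_lat / num_lat else NA),
                 iterations = iterations, burnin = burn, seed = seed),
            class = "mcmc_oracle")
}

# Initial-positive-sequence ESS estimate and split-R-hat.
ess_estimate <- function(v) {
  n <- length(v)
  if (stats::sd(v) == 0) return(n)
  ac <- stats::acf(v, lag.max = min(n - 1, 1000), plot = FALSE)$acf[-1]
  s <- 0
  for (k in seq(1, length(ac) - 1, by = 2)) {
    pair <- ac[k] + ac[k + 1]
    if (is.na(pair) || pair <= 0) break
    s <- s + pair
  }
  max(1, n / (1 + 2 * s))
}

split_rhat <- function(v) {
  n <- floor(length(v) / 2)
  a <- v[seq_len(n)]; b <- v[n + seq_len(n)]
  W <- (stats::var(a) + stats::var(b)) / 2
  B <- n * (mean(a) - mean(b))^2 / 2
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

mcmc_summary <- function(samples) {
  data.frame(parameter = colnames(samples),
             mean = colMeans(samples),
             sd = apply(samples, 2, stats::sd),
             ess = apply(samples, 2, ess_estimate),
             mcse = apply(samples, 2, function(v) stats::sd(v) / sqrt(ess_estimate(v))),
             rhat = apply(samples, 2, split_rhat),
             row.names = NULL)
}

#' @export
print.mcmc_oracle <- function(x, ...) {
  cat(sprintf("<mcmc_oracle> %d iterations (%d burn-in)\n", x$iterations, x$burnin))
  print(x$summary, digits = 3)
  invisible(x)
}
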