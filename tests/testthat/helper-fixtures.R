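# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

# A small cleaned-and-joined modeling table with mesh, at desk scale:
# 150 sites on a 600 x 400 km domain, 6 states, truth recorded.
small_sim <- function(seed = 11) {
  fixture(paste0("small_sim_", seed), function() {
    dom <- synthetic_domain(600, 400, c(3, 2), res = 10)
    truth <- synthetic_truth(beta = c(intercept = 2, om = 0.4, ph = -0.3),
                             range = 200, sigma = 0.6, sigma_state = 0.15,
                             sigma_obs = 0.3, seed = seed)
    sim <- simulate_survey(dom, n_sites = 150, truth = truth, seed = seed)
    tab <- merge_horizons(drop_not_sampled(substitute_below_lld(sim$table)))
    for (nm in c("om", "ph")) tab[[nm]] <- raster_extract(sim$covariates[[nm]],
                                                          tab$x_km, tab$y_km)
    sc <- standardize_covariates(tab[, c("om", "ph")])
    tab[, c("om", "ph")] <- sc$data
    mesh <- build_mesh(tab, sim$geometry, coarse_mesh_params(tab))
    list(sim = sim, tab = tab, mesh = mesh, scaling = sc$record,
         geometry = sim$geometry, truth = sim$truth)
  })
}

small_fit <- function(seed = 11) {
  fixture(paste0("small_fit_", seed), function() {
    s <- small_sim(seed)
    spec <- model_spec("base", "lognormal", c("om", "ph"))
    fit_spde(spec, s$tab, s$mesh, seed = 1, n_draws = 400)
  })
}

# The reference simulation conditions (400 sites, 1200 x 800 km, 12 states,
# range 300 km) with a fitted model: used for prediction-recovery checks.
medium_case <- function(seed = 42) {
  fixture(paste0("medium_case_", seed), function() {
    dom <- synthetic_domain(1200, 800, c(4, 3), res = 20)
    sim <- simulate_survey(dom, n_sites = 400,
                           truth = synthetic_truth(seed = seed), seed = seed)
    tab <- merge_horizons(drop_not_sampled(substitute_below_lld(sim$table)))
    covs <- c("om", "ph", "clay")
    for (nm in covs) tab[[nm]] <- raster_extract(sim$covariates[[nm]],
                                                 tab$x_km, tab$y_km)
    sc <- standardize_covariates(tab[, covs])
    tab[, covs] <- sc$data
    mesh <- build_mesh(tab, sim$geometry, coarse_mesh_params(tab))
    fit <- fit_spde(model_spec("ref", "lognormal", covs), tab, mesh,
                    seed = 1, n_draws = 400)
    list(sim = sim, tab = tab, mesh = mesh, scaling = sc$record,
         geometry = sim$geometry, truth = sim$truth, fit = fit, covs = covs)
  })
}

# A dense survey (many sites per correlation range, as in a national
# low-density survey whose range spans hundreds of km): the regime in which
# leave-one-out and leave-group-out scores are expected to be consistent.
dense_fit <- function(seed = 9) {
  fixture(paste0("dense_fit_", seed), function() {
    dom <- synthetic_domain(400, 300, c(2, 2), res = 10)
    truth <- synthetic_truth(beta = c(intercept = 2, om = 0.4, ph = -0.3),
                             range = 250, sigma = 0.5, sigma_state = 0.1,
                             sigma_obs = 0.3, seed = seed)
    sim <- simulate_survey(dom, n_sites = 300, truth = truth, seed = seed)
    tab <- merge_horizons(drop_not_sampled(substitute_below_lld(sim$table)))
    for (nm in c("om", "ph")) tab[[nm]] <- raster_extract(sim$covariates[[nm]],
                                                          tab$x_km, tab$y_km)
    sc <- standardize_covariates(tab[, c("om", "ph")])
    tab[, c("om", "ph")] <- sc$data
    mesh <- build_mesh(tab, sim$geometry, coarse_mesh_params(tab))
    fit_spde(model_spec("dense", "lognormal", c("om", "ph")), tab, mesh,
             seed = 1, n_draws = 300)
  })
}

# Simulate a non-spatial iid lognormal table (fast fits, closed-form checks).
iid_table <- function(n, beta0 = 1, sigma_obs = 0.4, seed = 1) {
  set.seed(seed)
  data.frame(conc = exp(beta0 + rnorm(n, sd = sigma_obs)),
             x_km = runif(n, 0, 100), y_km = runif(n, 0, 100),
             state_id = "S01")
}
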