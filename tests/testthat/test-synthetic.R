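test_that("a zero-variance field is exactly zero and inputs are validated", {
  pts <- cbind(runif(5, 0, 100), runif(5, 0, 100))
  expect_equal(simulate_matern_field(pts, 100, 0, seed = 1), rep(0, 5))
  expect_error(simulate_matern_field(pts[0, , drop = FALSE], 100, 1), "one node")
  expect_error(simulate_matern_field(pts, -1, 1), "range > 0")
})

test_that("dense Matern draws match the closed-form pair correlation", {
  pts <- rbind(c(0, 0), c(300, 0))
  f <- simulate_matern_field(pts, range = 300, sigma = 1, seed = 5, n = 2000,
                             method = "dense")
  target <- matern_correlation(300, 300)          # = 0.1397 for nu = 1
  expect_equal(target, 0.1397, tolerance = 1e-3)
  expect_lt(abs(cor(f[1, ], f[2, ]) - target), 0.03)
  expect_lt(abs(sd(f[1, ]) - 1), 0.04)
})

test_that("SPDE-sampled fields agree with the dense oracle statistically", {
  pts <- rbind(c(0, 0), c(300, 0))
  f <- simulate_matern_field(pts, range = 300, sigma = 0.8, seed = 5, n = 2000,
                             method = "spde")
  # MC noise plus a small positive discretization bias at mesh spacing range/5
  expect_lt(abs(cor(f[1, ], f[2, ]) - matern_correlation(300, 300)), 0.06)
  expect_lt(abs(sd(f[1, ]) - 0.8), 0.05)
  expect_lt(abs(sd(f[2, ]) - 0.8), 0.05)
  # determinism
  g1 <- simulate_matern_field(pts, 300, 0.8, seed = 9, n = 3)
  g2 <- simulate_matern_field(pts, 300, 0.8, seed = 9, n = 3)
  expect_identical(g1[seq_along(g1)], g2[seq_along(g2)])
})

test_that("the field variogram flattens near sigma^2 beyond the range", {
  set.seed(2)
  pts <- cbind(runif(120, 0, 500), runif(120, 0, 500))
  f <- simulate_matern_field(pts, range = 80, sigma = 0.7, seed = 3, n = 400,
                             method = "dense")
  d <- as.matrix(dist(pts))
  far <- which(d > 3 * 80 & upper.tri(d), arr.ind = TRUE)
  semivar <- mean(vapply(seq_len(nrow(far)), function(k)
    mean((f[far[k, 1], ] - f[far[k, 2], ])^2) / 2, numeric(1)))
  expect_lt(abs(semivar - 0.7^2), 0.1)
})

test_that("covariate rasters have the declared shape and are seed-stable", {
  dom <- synthetic_domain(1200, 800, c(4, 3), res = 2.5)
  rs <- simulate_covariate_rasters(dom, seed = 4)
  expect_length(rs, 8)
  for (r in rs) expect_equal(c(r$nrow, r$ncol), c(320, 480))
  rs2 <- simulate_covariate_rasters(dom, seed = 4)
  expect_identical(rs$om$values, rs2$om$values)     # bit-identical by seed
  expect_false(identical(rs$om$values,
                         simulate_covariate_rasters(dom, seed = 5)$om$values))
  expect_true(all(rs$crops$values >= 0 & rs$crops$values <= 1))
})

test_that("the constructed covariate pair hits its target correlation", {
  dom <- synthetic_domain(400, 300, c(1, 1), res = 10)
  rs <- simulate_covariate_rasters(dom, seed = 6, pair_r = 0.9)
  r_hat <- cor(as.vector(rs$precip$values), as.vector(rs$ph$values))
  expect_lt(abs(abs(r_hat) - 0.9), 0.02)
  rs2 <- simulate_covariate_rasters(dom, seed = 6, pair_r = 0.75)
  expect_lt(abs(cor(as.vector(rs2$precip$values), as.vector(rs2$ph$values)) - 0.75),
            0.02)
})

test_that("a degenerate survey collapses to the intercept", {
  dom <- synthetic_domain(200, 200, c(2, 2), res = 10)
  truth <- synthetic_truth(beta = c(intercept = 1.5, om = 0), range = 100,
                           sigma = 0, sigma_state = 0, sigma_obs = 1e-8)
  sim <- simulate_survey(dom, n_sites = 30, truth = truth, seed = 3,
                         p_not_sampled = 0)
  expect_equal(mean(sim$table$conc_top5), exp(1.5), tolerance = 0.05)
  expect_equal(sim$eta, rep(1.5, 30))
})

test_that("survey tables have the declared structure and reproduce by seed", {
  dom <- synthetic_domain(600, 400, c(3, 2), res = 10)
  sim <- simulate_survey(dom, n_sites = 400, truth = synthetic_truth(seed = 21))
  tab <- sim$table
  expect_equal(nrow(tab), 400)
  expect_true(all(c("conc_top5", "conc_ahorizon", "below_lld_top5",
                    "lab_id_top5", "lld", "state_id") %in% names(tab)))
  expect_false(anyNA(tab$state_id))
  expect_false(anyDuplicated(tab$site_id) > 0)
  sim2 <- simulate_survey(dom, n_sites = 400, truth = synthetic_truth(seed = 21))
  expect_identical(sim$table, sim2$table)           # reproducibility
  expect_equal(length(sim$truth$state_effects), 6)
  # flagged values sit below the detection limit, by construction
  expect_true(all(tab$conc_top5[tab$below_lld_top5] < tab$lld[tab$below_lld_top5]))
})

test_that("log-residual spread matches sigma_obs and data are right-skewed", {
  dom <- synthetic_domain(600, 400, c(3, 2), res = 10)
  truth <- synthetic_truth(beta = c(intercept = 2, om = 0.4, ph = -0.3, clay = 0.2),
                           range = 150, sigma = 0.6, sigma_obs = 0.3, seed = 31)
  sim <- simulate_survey(dom, n_sites = 2000, truth = truth, seed = 31)
  # residual of log concentration around the generating linear predictor
  resid <- log(sim$table$conc_top5) - sim$eta
  expect_lt(abs(sd(resid) - sqrt(0.3^2 + 0.05^2)), 0.05)
  y <- sim$table$conc_top5
  skew <- mean((y - mean(y))^3) / sd(y)^3
  expect_gt(skew, 0)
  expect_error(simulate_survey(dom, n_sites = 5, truth = truth), "at least 10")
})

test_that("truth records validate their invariants and serialize", {
  expect_error(synthetic_truth(range = -5), "range")
  expect_error(synthetic_truth(sigma_obs = 0), "sigma_obs")
  expect_error(synthetic_truth(beta = c(0.5)), "names")
  tr <- synthetic_truth(seed = 12)
  path <- withr::local_tempfile(fileext = ".json")
  dom <- synthetic_domain(200, 200, c(1, 1), res = 10)
  sim <- simulate_survey(dom, n_sites = 20, truth = tr, seed = 12)
  write_truth_json(sim$truth, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$range_true, 300)
  expect_equal(back$beta$intercept, 2)
  expect_equal(length(back$field_values), length(sim$truth$field_values))
})
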