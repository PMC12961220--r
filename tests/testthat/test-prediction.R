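test_that("predicted surfaces are positive with ordered credible bounds", {
  mc <- medium_case()
  ps <- suppressWarnings(predict_surface(mc$fit, mc$sim$covariates[mc$covs],
                                         mc$scaling, geometry = mc$geometry,
                                         seed = 2))
  m <- ps$mean$values; lo <- ps$lower$values; hi <- ps$upper$values
  ok <- !is.na(m)
  expect_gt(sum(ok), 2000)
  expect_true(all(lo[ok] <= m[ok] & m[ok] <= hi[ok]))
  expect_true(all(m[ok] > 0))
  # missing-covariate cells stay masked
  covs2 <- mc$sim$covariates[mc$covs]
  covs2$om$values[5, 7] <- NA
  ps2 <- suppressWarnings(predict_surface(mc$fit, covs2, mc$scaling,
                                          geometry = mc$geometry, seed = 2))
  expect_true(is.na(ps2$mean$values[5, 7]))
})

test_that("the predicted mean tracks the generating response surface", {
  mc <- medium_case()
  ps <- suppressWarnings(predict_surface(mc$fit, mc$sim$covariates[mc$covs],
                                         mc$scaling, geometry = mc$geometry,
                                         seed = 2))
  truth <- mc$truth
  tmpl <- mc$sim$covariates$om
  xy <- raster_xy(tmpl)
  cx <- rep(xy$x, each = tmpl$nrow); cy <- rep(xy$y, times = tmpl$ncol)
  Xc <- vapply(mc$covs, function(nm)
    (raster_extract(mc$sim$covariates[[nm]], cx, cy) - truth$scaling$mean[nm]) /
      truth$scaling$sd[nm], numeric(length(cx)))
  At <- suppressWarnings(projection_matrix(truth$field_mesh, cbind(cx, cy)))
  eta_true <- truth$beta[1] + as.vector(Xc %*% truth$beta[-1]) +
    as.vector(At %*% truth$field_values) +
    truth$state_effects[assign_states(cx, cy, mc$geometry)]
  ok <- !is.na(ps$mean$values) & !is.na(eta_true)
  expect_gt(cor(as.vector(ps$mean$values)[ok], exp(eta_true[ok])), 0.8)
})

test_that("prediction is deterministic given fit, grid and seed", {
  mc <- medium_case()
  p1 <- suppressWarnings(predict_surface(mc$fit, mc$sim$covariates[mc$covs],
                                         mc$scaling, geometry = mc$geometry,
                                         n_draws = 2000, seed = 7))
  p2 <- suppressWarnings(predict_surface(mc$fit, mc$sim$covariates[mc$covs],
                                         mc$scaling, geometry = mc$geometry,
                                         n_draws = 2000, seed = 7))
  expect_identical(p1$mean$values, p2$mean$values)
  expect_identical(p1$upper$values, p2$upper$values)
})

test_that("the projected spatial field is softly centred and interpretable", {
  mc <- medium_case()
  pf <- project_field(mc$fit, mc$sim$covariates$om)
  v <- pf$values[!is.na(pf$values)]
  # the field mean is confounded with the intercept; shrinkage keeps the
  # domain average within a fraction of the field SD of zero
  expect_lt(abs(mean(v)), 0.2)
  expect_lt(sd(v), 2 * mc$truth$sigma_true)
  expect_error(project_field(fit_spde(model_spec("ns", "lognormal",
                                                 include_spatial = FALSE,
                                                 include_state = FALSE),
                                      iid_table(30), n_draws = 30),
                             mc$sim$covariates$om), "no spatial field")
})

test_that("prediction reduces to exp(intercept + field) when noise vanishes", {
  geo <- make_synthetic_boundary(synthetic_domain(300, 300, c(1, 1), res = 10))
  set.seed(5)
  n <- 80
  pts <- data.frame(x_km = runif(n, 10, 290), y_km = runif(n, 10, 290),
                    state_id = "S01")
  w <- simulate_matern_field(pts, range = 150, sigma = 0.7, seed = 3)
  pts$conc <- exp(1.5 + as.vector(w))
  mesh <- build_mesh(pts, geo, coarse_mesh_params(pts))
  spec <- model_spec("nn", "lognormal", include_spatial = TRUE,
                     include_state = FALSE)
  fit <- fit_spde(spec, pts, mesh, seed = 1, n_draws = 300,
                  control = list(fixed = list(sigma_obs = 1e-3)))
  b0 <- fit$beta_summary$mean[1]
  # at data locations the posterior is pinned: mean = exp(b0 + w) exactly
  for (i in c(3, 20, 55)) {
    cell <- soil_raster(matrix(NA_real_, 1, 1), pts$x_km[i] - 5, pts$y_km[i] - 5, 10)
    ps <- predict_surface(fit, list(cell = cell), NULL, seed = 2)
    expect_equal(ps$mean$values[1, 1], pts$conc[i], tolerance = 0.02)
    pf <- project_field(fit, cell)
    expect_equal(exp(b0 + pf$values[1, 1]), pts$conc[i], tolerance = 0.02)
  }
  # across the whole domain the plug-in product tracks the posterior mean
  tmpl <- soil_raster(matrix(NA_real_, 15, 15), 0, 0, 20)
  ps <- suppressWarnings(predict_surface(fit, list(cell = tmpl), NULL, seed = 2))
  pf <- project_field(fit, tmpl)
  ok <- !is.na(ps$mean$values) & !is.na(pf$values)
  rel <- abs(ps$mean$values[ok] / exp(b0 + pf$values[ok]) - 1)
  expect_lt(median(rel), 0.05)
})

test_that("rasterized surfaces are masked to the boundary and conserve cells", {
  geo <- make_synthetic_boundary(synthetic_domain(100, 100, c(1, 1), res = 10))
  r <- soil_raster(matrix(runif(15 * 15), 15, 15), -20, -20, 10)
  out <- rasterize_surface(r, r, geo)
  xy <- raster_xy(r)
  cx <- rep(xy$x, each = 15); cy <- rep(xy$y, times = 15)
  inside <- point_in_polygon(cx, cy, geo$boundary)
  expect_equal(sum(!is.na(out$values)), sum(inside))
  expect_identical(out$values[matrix(inside, 15, 15)],
                   r$values[matrix(inside, 15, 15)])
  bad <- soil_raster(matrix(1, 5, 5), 3, 3, 10)
  expect_error(rasterize_surface(bad, r, geo), "not aligned")
})

test_that("decile classification yields ten labelled monotone classes", {
  r <- soil_raster(matrix(1:100, 10, 10), 0, 0, 1)
  pm <- percentile_classify(r)
  expect_length(pm$breaks, 9)
  expect_true(all(diff(pm$breaks) > 0))
  expect_length(pm$labels, 10)
  counts <- table(pm$classes$values)
  expect_equal(length(counts), 10)
  expect_true(all(abs(as.integer(counts) - 10) <= 1))
  # monotone: a larger value never maps to a lower class
  v <- as.vector(r$values); cl <- as.vector(pm$classes$values)
  o <- order(v)
  expect_true(!is.unsorted(cl[o]))
  # values equal to a break go to the lower class
  at_breaks <- percentile_classify(soil_raster(matrix(pm$breaks, 3, 3), 0, 0, 1),
                                   reference = r)
  expect_equal(as.vector(at_breaks$classes$values), 1:9)
  expect_error(percentile_classify(soil_raster(matrix(5, 5, 5), 0, 0, 1)),
               "degenerate")
  expect_error(percentile_classify(soil_raster(matrix(c(1:5, rep(NA, 20)), 5, 5),
                                               0, 0, 1)), "at least 10")
})

test_that("credible-bound rasters reuse the mean's breaks", {
  set.seed(6)
  mean_r <- soil_raster(matrix(rlnorm(400, 1, 0.5), 20, 20), 0, 0, 1)
  upper_r <- soil_raster(mean_r$values * 1.6, 0, 0, 1)
  pm_mean <- percentile_classify(mean_r)
  pm_upper <- percentile_classify(upper_r, reference = mean_r)
  expect_identical(pm_upper$breaks, pm_mean$breaks)
  counts <- table(factor(pm_upper$classes$values, levels = 1:10))
  expect_gt(max(counts), min(counts))    # counts need not be equal
  # upper bound shifted up: classes never decrease
  expect_true(all(pm_upper$classes$values >= pm_mean$classes$values))
})

test_that("percentile maps export an integer band with a label sidecar", {
  r <- soil_raster(matrix(1:100, 10, 10), 0, 0, 2)
  pm <- percentile_classify(r)
  path <- withr::local_tempfile(fileext = ".asc")
  write_percentile_map(pm, path, meters = TRUE)
  back <- read_ascii_grid(path, from_meters = TRUE)
  expect_identical(back$values, matrix(as.numeric(pm$classes$values), 10, 10))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_length(side$labels, 10)
  expect_equal(side$breaks, unname(pm$breaks))
})
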