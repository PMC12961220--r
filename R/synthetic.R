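# Synthetic survey generator. Produces point surveys, covariate rasters and
# boundary/state geometry with exactly the structure the model assumes --
# log-scale linear predictor, Matern spatial field, iid state effects,
# positively skewed concentrations, detection-limit censoring and paired
# near-replicate depth horizons -- with the generating truth recorded for
# recovery tests.

#' Record the generating truth of a synthetic survey
#'
#' Defaults are the package's reference simulation conditions: a 400-site
#' survey over a 1200 x 800 km domain with three active covariates, spatial
#' range 300 km, field SD 0.8, state-effect SD 0.2 and log-scale
#' observation SD 0.3.
#'
#' @param beta Named coefficient vector on the log-concentration scale; the
#'   first element must be named `intercept`, the rest name covariates.
#' @param range Spatial correlation range of the Matern field, km (> 0).
#' @param sigma Marginal SD of the spatial field (>= 0).
#' @param sigma_state SD of the iid state effects (>= 0).
#' @param sigma_obs Log-scale observation SD (lognormal family) or the
#'   gamma shape parameter (gamma family); > 0.
#' @param seed Integer seed that fully determines all sampled quantities.
#' @return A `synthetic_truth`.
#' @export
synthetic_truth <- function(beta = c(intercept = 2, om = 0.4, ph = -0.3, clay = 0.2),
                            range = 300, sigma = 0.8, sigma_state = 0.2,
                            sigma_obs = 0.3, seed = 1L) {
  stopifnot(!is.null(names(beta)), names(beta)[1] == "intercept")
  if (range <= 0 || sigma < 0 || sigma_obs <= 0 || sigma_state < 0)
    stop("require range > 0, sigma >= 0, sigma_state >= 0, sigma_obs > 0",
         call. = FALSE)
  structure(list(beta = beta, range_true = range, sigma_true = sigma,
                 sigma_state = sigma_state, sigma_obs = sigma_obs,
                 field_values = NULL, field_mesh = NULL, state_effects = NULL,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' Draw a zero-mean Matern (nu = 1) field at point locations
#'
#' The default `"spde"` method samples the field on an internal
#' triangulation through the sparse SPDE precision and projects to the
#' requested locations (scalable, and identical in structure to what the
#' model assumes); `"dense"` factorizes the exact Matern covariance and is
#' the small-n oracle. `sigma = 0` returns exact zeros.
#'
#' @param nodes Point coordinates (matrix or data frame), at least 1.
#' @param range Practical correlation range, km (> 0).
#' @param sigma Marginal SD (>= 0).
#' @param seed Integer seed.
#' @param n Number of independent draws.
#' @param method `"spde"` or `"dense"` (dense requires <= 2000 points).
#' @return Matrix (locations x n); for `n = 1` a vector. SPDE draws carry
#'   the simulation mesh and node values in attributes `field_mesh` /
#'   `node_values`.
#' @export
simulate_matern_field <- function(nodes, range, sigma, seed = 1L, n = 1L,
                                  method = c("spde", "dense")) {
  method <- match.arg(method)
  xy <- as_points(nodes)
  if (nrow(xy) < 1) stop("need at least one node", call. = FALSE)
  if (range <= 0 || sigma < 0) stop("require range > 0 and sigma >= 0", call. = FALSE)
  if (sigma == 0) {
    out <- matrix(0, nrow(xy), n)
    return(if (n == 1) out[, 1] else out)
  }
  if (method == "dense") {
    if (nrow(xy) > 2000) stop("dense method limited to 2000 points", call. = FALSE)
    S <- matern_covariance(xy, range, sigma)
    L <- chol(S + diag(1e-10 * sigma^2, nrow(S)))
    vals <- with_seed(seed, crossprod(L, matrix(stats::rnorm(nrow(xy) * n), nrow(xy), n)))
    return(if (n == 1) as.vector(vals) else as.matrix(vals))
  }
  bb <- ring_bbox(cbind(xy[, 1], xy[, 2]))
  pad <- max(range / 10, 1e-3)
  boundary <- cbind(x = c(bb["xmin"] - pad, bb["xmax"] + pad, bb["xmax"] + pad, bb["xmin"] - pad),
                    y = c(bb["ymin"] - pad, bb["ymin"] - pad, bb["ymax"] + pad, bb["ymax"] + pad))
  area_outer <- (bb["xmax"] - bb["xmin"] + 2 * range) * (bb["ymax"] - bb["ymin"] + 2 * range)
  s <- max(range / 5, sqrt(area_outer / (0.866 * 2200)))
  params <- mesh_params(max_edge_inner = s, max_edge_outer = 3 * s,
                        offset_outer = range, cutoff = s / 20)
  mesh <- build_mesh(xy, boundary, params)
  op <- assemble_fem(mesh)
  Q <- spde_precision(op, range, sigma)
  w_nodes <- with_seed(seed, sample_gmrf(Q, n))
  A <- projection_matrix(mesh, xy)
  vals <- as.matrix(A %*% w_nodes)
  out <- if (n == 1) as.vector(vals) else vals
  attr(out, "field_mesh") <- mesh
  attr(out, "node_values") <- if (n == 1) w_nodes[, 1] else w_nodes
  out
}

# Smooth random surface on a grid: a low-order random Fourier series.
smooth_surface <- function(xs, ys, n_waves = 6) {
  W <- diff(range(xs)) + mean(diff(xs))
  H <- diff(range(ys)) + mean(diff(ys))
  f <- matrix(0, length(ys), length(xs))
  for (k in seq_len(n_waves)) {
    a <- stats::rnorm(1); wx <- sample(1:3, 1); wy <- sample(1:3, 1)
    ph <- stats::runif(2, 0, 2 * pi); sgn <- sample(c(-1, 1), 1)
    f <- f + a * outer(sin(2 * pi * wy * ys / H + ph[2]),
                       sin(2 * pi * wx * xs / W + ph[1]) * sgn)
  }
  f
}

#' Simulate the environmental covariate raster set
#'
#' Eight covariates (organic matter, pH, saturated hydraulic conductivity,
#' percent clay, temperature, elevation, slope, cultivated-crop proportion)
#' on the domain's raster grid, each a smooth random surface plus cell
#' noise, shifted/scaled to plausible field ranges. With `pair_r` set, an
#' extra `precip` layer is constructed by exact Gram-Schmidt mixing to have
#' sample correlation `pair_r` with `ph` across cells, for collinearity
#' screening tests.
#'
#' @param domain A `soil_domain`.
#' @param seed Integer seed (same seed gives bit-identical grids).
#' @param pair_r Optional target correlation of the constructed
#'   (`precip`, `ph`) pair.
#' @return Named list of `soil_raster`.
#' @export
simulate_covariate_rasters <- function(domain, seed = 1L, pair_r = NULL) {
  stopifnot(inherits(domain, "soil_domain"))
  res <- domain$res
  nx <- round(domain$width / res); ny <- round(domain$height / res)
  xs <- domain$origin[1] + (seq_len(nx) - 0.5) * res
  ys <- domain$origin[2] + (seq_len(ny) - 0.5) * res
  spec <- list(om = c(5, 2), ph = c(6.5, 0.8), ksat = c(20, 10), clay = c(20, 8),
               temp = c(12, 6), elev = c(500, 300), slope = c(3, 2),
               crops = c(0, 1))
  out <- list()
  with_seed(seed, {
    for (nm in names(spec)) {
      f <- smooth_surface(xs, ys)
      f <- f + stats::rnorm(length(f), sd = 0.15 * stats::sd(f))
      z <- (f - mean(f)) / stats::sd(f)
      v <- if (nm == "crops") stats::plogis(1.5 * z - 1) else spec[[nm]][1] + spec[[nm]][2] * z
      out[[nm]] <- soil_raster(v, domain$origin[1], domain$origin[2], res, name = nm)
    }
    if (!is.null(pair_r)) {
      stopifnot(abs(pair_r) <= 1)
      ph <- as.vector(out$ph$values)
      z <- as.vector(smooth_surface(xs, ys)) + stats::rnorm(nx * ny, sd = 0.3)
      phs <- (ph - mean(ph)) / stats::sd(ph)
      z <- z - mean(z); z <- z - phs * sum(z * phs) / sum(phs^2)   # exact orthogonalization
      zs <- z / stats::sd(z)
      mix <- pair_r * phs + sqrt(1 - pair_r^2) * zs
      out$precip <- soil_raster(matrix(900 + 300 * mix, ny, nx),
                                domain$origin[1], domain$origin[2], res,
                                name = "precip")
    }
  })
  out
}

#' Simulate a two-horizon point survey with known generating truth
#'
#' Sites are placed uniformly in the boundary; the log-scale linear
#' predictor is `intercept + X beta + w(s) + u_state` with `w` a Matern
#' SPDE field and `u_state` iid per state. Lognormal responses are
#' `exp(eta + N(0, sigma_obs^2))`; gamma responses have mean `exp(eta)` and
#' shape `sigma_obs`. Each site carries two horizon measurements (the
#' response times independent `exp(N(0, 0.05^2))` perturbations, emulating
#' near-replicate 0-5 cm and A-horizon assays). Values below the detection
#' limit keep their simulated value and are flagged, so the substitution
#' rule is testable; a small fraction of horizon assays is marked "N.S."
#' (not sampled).
#'
#' @param domain A `soil_domain` (or `soil_geometry`).
#' @param n_sites Number of survey sites (>= 10).
#' @param truth A `synthetic_truth`.
#' @param covariates Optional covariate raster list; simulated when `NULL`.
#' @param family `"lognormal"` or `"gamma"`.
#' @param lld Lower limit of detection (mg/kg). Default: the 2nd percentile
#'   of the simulated concentrations rounded to 2 significant digits,
#'   emulating an assay that censors about 2 percent of measurements.
#' @param p_not_sampled Per-horizon probability of an "N.S." lab record.
#' @param seed Integer seed; overrides `truth$seed` when given.
#' @return List: `table` (survey table), `truth` (with `field_values`,
#'   `state_effects` filled in), `geometry`, `covariates`, `eta`.
#' @export
simulate_survey <- function(domain, n_sites = 400, truth = synthetic_truth(),
                            covariates = NULL,
                            family = c("lognormal", "gamma"),
                            lld = NULL, p_not_sampled = 0.01, seed = NULL) {
  family <- match.arg(family)
  stopifnot(inherits(truth, "synthetic_truth"))
  if (n_sites < 10) stop("n_sites must be at least 10", call. = FALSE)
  seed <- if (is.null(seed)) truth$seed else as.integer(seed)
  geometry <- if (inherits(domain, "soil_geometry")) domain else make_synthetic_boundary(domain)
  dom <- geometry$domain
  if (is.null(covariates))
    covariates <- simulate_covariate_rasters(dom, seed = child_seed(seed, 1L))
  bb <- ring_bbox(geometry$boundary)
  xy <- with_seed(child_seed(seed, 2L), cbind(
    x = stats::runif(n_sites, bb["xmin"], bb["xmax"]),
    y = stats::runif(n_sites, bb["ymin"], bb["ymax"])))
  state_id <- assign_states(xy[, 1], xy[, 2], geometry)
  covs <- names(truth$beta)[-1]
  missing_cov <- setdiff(covs, names(covariates))
  if (length(missing_cov) > 0)
    stop("covariates not available: ", paste(missing_cov, collapse = ", "), call. = FALSE)
  X <- vapply(covs, function(nm) raster_extract(covariates[[nm]], xy[, 1], xy[, 2]),
              numeric(n_sites))
  X <- matrix(X, nrow = n_sites, dimnames = list(NULL, covs))
  Xs <- scale(X)   # generator works on standardized covariates, like the model
  w <- simulate_matern_field(xy, truth$range_true, truth$sigma_true,
                             seed = child_seed(seed, 3L))
  u_all <- with_seed(child_seed(seed, 4L),
                     stats::rnorm(length(geometry$state_ids), sd = truth$sigma_state))
  names(u_all) <- geometry$state_ids
  eta <- unname(truth$beta[1] + as.vector(Xs %*% truth$beta[-1]) + as.vector(w) +
                  u_all[state_id])
  y <- with_seed(child_seed(seed, 5L), switch(
    family,
    lognormal = exp(eta + stats::rnorm(n_sites, sd = truth$sigma_obs)),
    gamma = stats::rgamma(n_sites, shape = truth$sigma_obs,
                          rate = truth$sigma_obs / exp(eta))))
  hz <- with_seed(child_seed(seed, 6L), list(
    top5 = y * exp(stats::rnorm(n_sites, sd = 0.05)),
    ahorizon = y * exp(stats::rnorm(n_sites, sd = 0.05)),
    ns1 = stats::runif(n_sites) < p_not_sampled,
    ns2 = stats::runif(n_sites) < p_not_sampled))
  if (is.null(lld)) lld <- signif(stats::quantile(c(hz$top5, hz$ahorizon), 0.02,
                                                  names = FALSE), 2)
  tab <- data.frame(
    site_id = sprintf("SITE%04d", seq_len(n_sites)),
    x_km = xy[, 1], y_km = xy[, 2], state_id = state_id,
    lab_id_top5 = ifelse(hz$ns1, "N.S.", sprintf("L%05d", seq_len(n_sites))),
    lab_id_ahorizon = ifelse(hz$ns2, "N.S.", sprintf("L%05d", n_sites + seq_len(n_sites))),
    conc_top5 = hz$top5, conc_ahorizon = hz$ahorizon,
    below_lld_top5 = hz$top5 < lld, below_lld_ahorizon = hz$ahorizon < lld,
    lld = lld, stringsAsFactors = FALSE)
  truth$field_values <- attr(w, "node_values")
  truth$field_mesh <- attr(w, "field_mesh")
  truth$field_at_sites <- as.vector(w)
  truth$state_effects <- u_all
  truth$seed <- seed
  truth$scaling <- list(mean = attr(Xs, "scaled:center"), sd = attr(Xs, "scaled:scale"))
  list(table = tab, truth = truth, geometry = geometry, covariates = covariates,
       eta = eta, family = family)
}

#' Write the generating-truth record as JSON
#'
#' @param truth A `synthetic_truth`.
#' @param path Output path.
#' @export
write_truth_json <- function(truth, path) {
  obj <- list(beta = as.list(truth$beta), range_true = truth$range_true,
              sigma_true = truth$sigma_true, sigma_state = truth$sigma_state,
              sigma_obs = truth$sigma_obs, seed = truth$seed,
              field_values = truth$field_values,
              state_effects = as.list(truth$state_effects))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
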