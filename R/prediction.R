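# Projection of a fitted model onto the covariate grid: response-scale
# posterior mean and 95% credible bounds per cell, spatial-field surfaces,
# boundary-masked raster export and decile percentile maps.

#' Predict the concentration surface on the covariate grid
#'
#' Covariates are standardized with the *training* scaling record (the
#' regression coefficients are defined on that scale), the linear predictor
#' is evaluated per joint posterior draw (fixed effects + barycentric
#' projection of the spatial field + the containing state's effect), and
#' the response-scale per-draw expectation -- `exp(eta + sigma_obs^2/2)`
#' for the lognormal family, `exp(eta)` for gamma -- is summarized by its
#' mean and 2.5%/97.5% quantiles. Cells with missing covariates stay
#' masked; cells outside the mesh are masked with a warning count; cells in
#' states unseen during fitting get the state-effect prior mean of zero.
#'
#' @param fit An `spde_fit`.
#' @param covariates Named list of aligned `soil_raster` covering the
#'   model's covariates.
#' @param scaling A `scaling_record` from the training data (may be `NULL`
#'   for a covariate-free model).
#' @param geometry Optional `soil_geometry` for state assignment (required
#'   when the fit includes a state effect).
#' @param n_draws Number of posterior draws (uses the fit's stored draws
#'   when they suffice).
#' @param seed Seed for fresh draws if needed.
#' @return A `prediction_surface`: `mean`, `lower`, `upper` (`soil_raster`),
#'   plus `n_masked_outside_mesh`.
#' @export
predict_surface <- function(fit, covariates, scaling = NULL, geometry = NULL,
                            n_draws = NULL, seed = 1L) {
  stopifnot(inherits(fit, "spde_fit"))
  covs <- fit$spec$covariates
  if (length(covs) > 0 && !inherits(scaling, "scaling_record"))
    stop("a training scaling_record is required for covariate prediction",
         call. = FALSE)
  missing_cov <- setdiff(covs, names(covariates))
  if (length(missing_cov) > 0)
    stop("missing covariate rasters: ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  template <- covariates[[if (length(covs) > 0) covs[1] else 1]]
  xy <- raster_xy(template)
  cx <- rep(xy$x, each = template$nrow)
  cy <- rep(xy$y, times = template$ncol)
  cell_df <- data.frame(x_km = cx, y_km = cy)
  for (nm in covs) cell_df[[nm]] <- as.vector(covariates[[nm]]$values)
  defined <- if (length(covs) > 0)
    stats::complete.cases(cell_df[, covs, drop = FALSE]) else rep(TRUE, nrow(cell_df))
  if (length(covs) > 0)
    cell_df[covs] <- apply_scaling(cell_df[, covs, drop = FALSE], scaling)

  if (is.null(n_draws) || n_draws <= ncol(fit$x_draws)) {
    x_draws <- fit$x_draws
    theta_draws <- fit$theta_draws
    if (!is.null(n_draws)) {
      x_draws <- x_draws[, seq_len(n_draws), drop = FALSE]
      theta_draws <- theta_draws[seq_len(n_draws), , drop = FALSE]
    }
  } else {
    dr <- sample_posterior(fit, n_draws, seed)
    x_draws <- dr$x; theta_draws <- dr$theta
  }
  S <- ncol(x_draws)
  md <- fit$md
  idx <- which(defined)
  Xp <- cbind(intercept = 1, as.matrix(cell_df[idx, covs, drop = FALSE]))
  eta <- Xp %*% x_draws[md$beta_idx, , drop = FALSE]
  n_outside <- 0L
  if (md$m > 0) {
    Ap <- suppressWarnings(projection_matrix(fit$mesh, cell_df[idx, c("x_km", "y_km")]))
    rs <- Matrix::rowSums(Ap)
    in_mesh <- abs(rs - 1) < 1e-6
    n_outside <- sum(!in_mesh)
    eta <- eta + as.matrix(Ap %*% x_draws[md$w_idx, , drop = FALSE])
    eta[!in_mesh, ] <- NA_real_
  }
  if (md$k > 0) {
    if (is.null(geometry))
      stop("geometry required for state-effect prediction", call. = FALSE)
    st <- assign_states(cell_df$x_km[idx], cell_df$y_km[idx], geometry)
    mi <- match(st, md$state_levels)
    known <- !is.na(mi)
    if (any(known))
      eta[known, ] <- eta[known, ] +
        x_draws[md$u_idx[mi[known]], , drop = FALSE]
  }
  resp <- switch(fit$family,
                 gaussian = eta,
                 lognormal = exp(sweep(eta, 2, theta_draws[, "sigma_obs"]^2 / 2, `+`)),
                 gamma = exp(eta))
  mk <- function(v) {
    full <- rep(NA_real_, nrow(cell_df)); full[idx] <- v
    soil_raster(matrix(full, template$nrow, template$ncol),
                template$xmin, template$ymin, template$res)
  }
  if (n_outside > 0)
    warning(sprintf("%d grid cell(s) outside the mesh were masked", n_outside))
  m <- rowMeans(resp)
  lo <- apply(resp, 1, stats::quantile, 0.025, names = FALSE, na.rm = FALSE)
  hi <- apply(resp, 1, stats::quantile, 0.975, names = FALSE, na.rm = FALSE)
  out <- list(mean = mk(m), lower = mk(lo), upper = mk(hi),
              n_masked_outside_mesh = n_outside, family = fit$family)
  out$mean$name <- "posterior_mean"; out$lower$name <- "lower95"; out$upper$name <- "upper95"
  structure(out, class = "prediction_surface")
}

#' @export
print.prediction_surface <- function(x, ...) {
  cat(sprintf("<prediction_surface> %d x %d cells, %d defined\n",
              x$mean$nrow, x$mean$ncol, sum(!is.na(x$mean$values))))
  invisible(x)
}

#' Posterior mean of the spatial random field on a grid
#'
#' Projects the posterior mean of the latent field onto the template grid's
#' cell centres. On the log link the field acts multiplicatively: a cell
#' value v scales the expected concentration by exp(v), and values near
#' zero mean little residual spatial structure.
#'
#' @param fit An `spde_fit` with a spatial effect.
#' @param template A `soil_raster` (or `sampling_grid`) defining the grid.
#' @return A `soil_raster` of posterior-mean field values (NA off-mesh).
#' @export
project_field <- function(fit, template) {
  stopifnot(inherits(fit, "spde_fit"))
  if (fit$md$m == 0) stop("fit has no spatial field", call. = FALSE)
  if (inherits(template, "sampling_grid")) template <- grid_template_raster(template)
  xy <- raster_xy(template)
  cx <- rep(xy$x, each = template$nrow)
  cy <- rep(xy$y, times = template$ncol)
  A <- suppressWarnings(projection_matrix(fit$mesh, cbind(cx, cy)))
  v <- as.vector(A %*% fit$latent_mean[fit$md$w_idx])
  v[abs(Matrix::rowSums(A) - 1) > 1e-6] <- NA_real_
  soil_raster(matrix(v, template$nrow, template$ncol),
              template$xmin, template$ymin, template$res, name = "spatial_field")
}

#' Mask a surface to the study boundary on a template grid
#'
#' Cells whose centres fall outside the boundary polygon become missing;
#' everything else is carried through unchanged. Export with
#' [write_ascii_grid()] (`meters = TRUE`) converts the georeferencing from
#' km to m.
#'
#' @param surface A `soil_raster` aligned to `template`.
#' @param template A `soil_raster` or `sampling_grid` (georeferencing must
#'   match exactly).
#' @param boundary Polygon ring or `soil_geometry`.
#' @return The masked `soil_raster`.
#' @export
rasterize_surface <- function(surface, template, boundary) {
  if (inherits(template, "sampling_grid")) template <- grid_template_raster(template)
  if (inherits(boundary, "soil_geometry")) boundary <- boundary$boundary
  same <- isTRUE(all.equal(c(surface$xmin, surface$ymin, surface$res),
                           c(template$xmin, template$ymin, template$res))) &&
    surface$nrow == template$nrow && surface$ncol == template$ncol
  if (!same) stop("surface is not aligned to the template grid", call. = FALSE)
  xy <- raster_xy(surface)
  cx <- rep(xy$x, each = surface$nrow)
  cy <- rep(xy$y, times = surface$ncol)
  inside <- point_in_polygon(cx, cy, boundary)
  V <- surface$values
  V[!matrix(inside, surface$nrow, surface$ncol)] <- NA_real_
  soil_raster(V, surface$xmin, surface$ymin, surface$res, name = surface$name)
}

#' Decile classification of a surface
#'
#' Bins a raster into ten percentile classes (10-100%) using the decile
#' breaks of the `reference` raster (default: the raster itself), labelling
#' each class with its raw value range so absolute and relative
#' concentrations read together. Credible-bound rasters are classified with
#' the posterior mean's breaks for comparability; class counts then need
#' not be equal. Values equal to a break go to the lower class.
#'
#' @param raster A `soil_raster` with at least 10 defined values.
#' @param reference Optional `soil_raster` supplying the breaks.
#' @return A `percentile_map`: `classes` (integer raster 1..10), `breaks`
#'   (9 internal break values), `labels` (value-range strings).
#' @export
percentile_classify <- function(raster, reference = NULL) {
  ref <- if (is.null(reference)) raster else reference
  rv <- ref$values[!is.na(ref$values)]
  if (length(rv) < 10) stop("need at least 10 defined values", call. = FALSE)
  breaks <- stats::quantile(rv, probs = seq(0.1, 0.9, by = 0.1), names = FALSE)
  if (any(diff(breaks) <= 0))
    stop("degenerate percentile breaks (too many tied values)", call. = FALSE)
  v <- as.vector(raster$values)
  cls <- rep(NA_integer_, length(v))
  ok <- !is.na(v)
  cls[ok] <- findInterval(v[ok], breaks, left.open = TRUE) + 1L
  edges <- c(min(rv), breaks, max(rv))
  labels <- sprintf("%d%%: %.3g-%.3g", seq(10, 100, by = 10),
                    edges[1:10], edges[2:11])
  classes <- soil_raster(matrix(cls, raster$nrow, raster$ncol),
                         raster$xmin, raster$ymin, raster$res,
                         name = paste0(raster$name, "_decile"))
  structure(list(classes = classes, breaks = breaks, labels = labels),
            class = "percentile_map")
}

#' @export
print.percentile_map <- function(x, ...) {
  cat("<percentile_map>\n")
  cat(paste0("  ", x$labels, collapse = "\n"), "\n")
  invisible(x)
}

#' Write a percentile map (integer class band + JSON label sidecar)
#'
#' @param pm A `percentile_map`.
#' @param path Output `.asc` path; labels go to `paste0(path, ".json")`.
#' @param meters Export georeferencing in metres.
#' @export
write_percentile_map <- function(pm, path, meters = TRUE) {
  write_ascii_grid(pm$classes, path, meters = meters)
  jsonlite::write_json(list(breaks = pm$breaks, labels = pm$labels),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
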