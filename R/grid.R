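# Sampling grid: the square tessellation over the study boundary onto which
# covariates are aggregated and through which samples are linked to
# environmental values.

#' Build the square sampling grid over a study boundary
#'
#' Cells have edge `sqrt(cell_area_km2)` (the default 6 km^2 gives a
#' 2.449 x 2.449 km cell) and cover the boundary's bounding box; counts are
#' rounded up so the box is fully covered. Cells intersecting the boundary
#' polygon (any corner or the centre inside) are flagged in-domain. The grid
#' origin is anchored at the bounding box lower-left corner.
#'
#' @param boundary Polygon ring matrix (n x 2, km) or a `soil_geometry`.
#' @param cell_area_km2 Cell area, km^2 (> 0).
#' @return A `sampling_grid`: origin, `edge`, `n_cols`, `n_rows`,
#'   `in_domain` (logical matrix, rows = y from bottom).
#' @export
build_sampling_grid <- function(boundary, cell_area_km2 = 6) {
  if (inherits(boundary, "soil_geometry")) boundary <- boundary$boundary
  stopifnot(is.matrix(boundary), ncol(boundary) == 2)
  if (cell_area_km2 <= 0) stop("cell_area_km2 must be > 0", call. = FALSE)
  bb <- ring_bbox(boundary)
  if (bb["xmax"] - bb["xmin"] <= 0 || bb["ymax"] - bb["ymin"] <= 0)
    stop("degenerate boundary", call. = FALSE)
  edge <- sqrt(cell_area_km2)
  n_cols <- ceiling((bb["xmax"] - bb["xmin"]) / edge - 1e-9)
  n_rows <- ceiling((bb["ymax"] - bb["ymin"]) / edge - 1e-9)
  xs <- bb[["xmin"]] + (seq_len(n_cols) - 0.5) * edge
  ys <- bb[["ymin"]] + (seq_len(n_rows) - 0.5) * edge
  cx <- rep(xs, each = length(ys)); cy <- rep(ys, times = length(xs))
  h <- edge / 2
  ind <- point_in_polygon(cx, cy, boundary)
  for (dx in c(-h, h)) for (dy in c(-h, h))
    ind <- ind | point_in_polygon(cx + dx, cy + dy, boundary)
  in_domain <- matrix(ind, nrow = n_rows, ncol = n_cols)
  structure(list(xmin = bb[["xmin"]], ymin = bb[["ymin"]], edge = edge,
                 n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
                 in_domain = in_domain, boundary = boundary),
            class = "sampling_grid")
}

#' @export
print.sampling_grid <- function(x, ...) {
  cat(sprintf("<sampling_grid> %d x %d cells of %.3f km (%.3g km^2), %d in-domain\n",
              x$n_cols, x$n_rows, x$edge, x$edge^2, sum(x$in_domain)))
  invisible(x)
}

# Empty raster sharing the grid's georeferencing.
grid_template_raster <- function(grid) {
  soil_raster(matrix(NA_real_, grid$n_rows, grid$n_cols),
              grid$xmin, grid$ymin, grid$edge, name = "template")
}

#' Area-weighted zonal means of a raster over the sampling grid
#'
#' Each grid cell receives the mean of the raster cells it intersects,
#' weighted by overlap fraction; missing raster cells are excluded from the
#' weights and a cell with no valid overlap stays missing.
#'
#' @param raster A `soil_raster`.
#' @param grid A `sampling_grid`.
#' @return A `soil_raster` of per-cell means on the grid.
#' @export
zonal_mean_extract <- function(raster, grid) {
  resample_area_mean(raster, grid_template_raster(grid))
}

# Cell index of points; points on an interior vertical/horizontal cell edge
# are reported with all touching cells (candidates for the seeded tie-break).
cell_candidates <- function(grid, x, y, tol = 1e-9) {
  fx <- (x - grid$xmin) / grid$edge
  fy <- (y - grid$ymin) / grid$edge
  jx <- floor(fx + tol); iy <- floor(fy + tol)
  on_vx <- abs(fx - round(fx)) <= tol & round(fx) >= 1 & round(fx) <= grid$n_cols - 1
  on_hy <- abs(fy - round(fy)) <= tol & round(fy) >= 1 & round(fy) <= grid$n_rows - 1
  list(col = jx + 1L, row = iy + 1L, on_vx = on_vx, on_hy = on_hy)
}

#' Link soil samples to sampling-grid cells and their covariates
#'
#' Each sample is joined to the covariate values of its containing cell. A
#' sample lying exactly on a shared cell edge intersects two (or four)
#' cells; exactly one containing cell is retained by a seeded random draw,
#' mirroring duplicate-record removal after a spatial join. Samples whose
#' cell has any missing covariate are dropped and counted, as are samples
#' outside the grid.
#'
#' @param samples Data frame with `x_km`, `y_km` columns (plus anything else).
#' @param grid A `sampling_grid`.
#' @param covariates Named list of `soil_raster` aligned to `grid`.
#' @param seed Integer seed for the duplicate tie-break.
#' @return The modeling table: `samples` plus one column per covariate, with
#'   attributes `n_dropped_missing`, `n_dropped_outside`, `n_edge_ties`.
#' @export
join_samples_to_grid <- function(samples, grid, covariates, seed = 1L) {
  stopifnot(all(c("x_km", "y_km") %in% names(samples)))
  for (nm in names(covariates)) {
    r <- covariates[[nm]]
    if (r$nrow != grid$n_rows || r$ncol != grid$n_cols)
      stop(sprintf("covariate '%s' is not aligned to the grid", nm), call. = FALSE)
  }
  cc <- cell_candidates(grid, samples$x_km, samples$y_km)
  n <- nrow(samples)
  row_i <- cc$row; col_j <- cc$col
  n_ties <- 0L
  with_seed(seed, {
    for (k in seq_len(n)) {
      rows <- unique(c(cc$row[k], if (cc$on_hy[k]) cc$row[k] + c(-1L, 0L)))
      cols <- unique(c(cc$col[k], if (cc$on_vx[k]) cc$col[k] + c(-1L, 0L)))
      if (length(rows) > 1L || length(cols) > 1L) {
        cand <- expand.grid(row = rows, col = cols)
        pick <- cand[sample.int(nrow(cand), 1L), ]
        row_i[k] <- pick$row; col_j[k] <- pick$col
        n_ties <- n_ties + 1L
      }
    }
  })
  inside <- row_i >= 1 & row_i <= grid$n_rows & col_j >= 1 & col_j <= grid$n_cols
  out <- samples[inside, , drop = FALSE]
  ri <- row_i[inside]; cj <- col_j[inside]
  for (nm in names(covariates))
    out[[nm]] <- covariates[[nm]]$values[cbind(ri, cj)]
  cov_ok <- stats::complete.cases(out[, names(covariates), drop = FALSE])
  res <- out[cov_ok, , drop = FALSE]
  res$cell_row <- ri[cov_ok]; res$cell_col <- cj[cov_ok]
  attr(res, "n_dropped_outside") <- sum(!inside)
  attr(res, "n_dropped_missing") <- sum(!cov_ok)
  attr(res, "n_edge_ties") <- n_ties
  res
}

#' Drop samples outside the study boundary
#'
#' Boundaries are closed: a point exactly on the boundary is retained.
#'
#' @param samples Data frame with `x_km`, `y_km`.
#' @param boundary Polygon ring matrix or `soil_geometry`.
#' @return Filtered data frame with attribute `n_removed`.
#' @export
filter_within_boundary <- function(samples, boundary) {
  if (inherits(boundary, "soil_geometry")) boundary <- boundary$boundary
  keep <- point_in_polygon(samples$x_km, samples$y_km, boundary)
  out <- samples[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}
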