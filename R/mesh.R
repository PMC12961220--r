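# Triangulation of the study domain for the SPDE field: a fine inner mesh
# over the boundary polygon plus a coarser outer buffer that pushes the
# artificial Neumann boundary away from the data.

#' Heuristic mesh parameters derived from the data's spatial extent
#'
#' All four parameters come from the x-direction spatial extent of the point
#' set: inner maximum edge = extent/12, outer offset = extent/3, outer
#' maximum edge = 5 x inner edge, cutoff = inner edge / 5. The extent/12
#' inner resolution is a conventional starting point for continental-scale
#' meshes.
#'
#' @param points Matrix or data frame of point coordinates (`x_km`, `y_km`
#'   columns or two unnamed columns), at least 2 points with distinct x.
#' @return A `mesh_params` object: `max_edge_inner`, `max_edge_outer`,
#'   `offset_outer`, `cutoff` (km).
#' @export
coarse_mesh_params <- function(points) {
  xy <- as_points(points)
  if (nrow(xy) < 2) stop("need at least 2 points", call. = FALSE)
  extent_x <- max(xy[, 1]) - min(xy[, 1])
  if (extent_x <= 0) stop("zero x-extent", call. = FALSE)
  mesh_params(max_edge_inner = extent_x / 12,
              max_edge_outer = 5 * (extent_x / 12),
              offset_outer = extent_x / 3,
              cutoff = (extent_x / 12) / 5)
}

#' Mesh parameters for the fine (final-inference) mesh
#'
#' The inner maximum edge is set to `fraction` of the estimated spatial
#' range (default one-tenth, with one-fifth and one-fifteenth as the
#' standard sensitivity variants); the remaining parameters are inherited
#' from the coarse mesh unless overridden. An inherited cutoff that is no
#' longer strictly below the new inner edge (possible for the finest
#' fractions) is reduced to a fifth of the new edge so the mesh cannot
#' degenerate.
#'
#' @param range_estimate Posterior-mean spatial range from the coarse-mesh
#'   fit, km (> 0).
#' @param coarse `mesh_params` from [coarse_mesh_params()].
#' @param fraction Fraction of the range used as inner maximum edge.
#' @param cutoff Optional cutoff override, km (the 0.5 km variant is the
#'   usual sensitivity setting).
#' @return A `mesh_params` object.
#' @export
fine_mesh_params <- function(range_estimate, coarse, fraction = 1 / 10,
                             cutoff = NULL) {
  stopifnot(inherits(coarse, "mesh_params"))
  if (!is.numeric(range_estimate) || range_estimate <= 0)
    stop("range_estimate must be positive", call. = FALSE)
  mei <- fraction * range_estimate
  co <- if (!is.null(cutoff)) cutoff else coarse$cutoff
  if (co >= mei) co <- mei / 5
  mesh_params(max_edge_inner = mei,
              max_edge_outer = coarse$max_edge_outer,
              offset_outer = coarse$offset_outer,
              cutoff = co)
}

mesh_params <- function(max_edge_inner, max_edge_outer, offset_outer, cutoff) {
  vals <- c(max_edge_inner, max_edge_outer, offset_outer, cutoff)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("mesh parameters must be strictly positive", call. = FALSE)
  if (max_edge_outer < max_edge_inner)
    stop("max_edge_outer must be >= max_edge_inner", call. = FALSE)
  structure(list(max_edge_inner = max_edge_inner, max_edge_outer = max_edge_outer,
                 offset_outer = offset_outer, cutoff = cutoff),
            class = "mesh_params")
}

#' @export
print.mesh_params <- function(x, ...) {
  cat(sprintf(paste0("<mesh_params> inner max edge %.3g km, outer max edge %.3g km, ",
                     "offset %.3g km, cutoff %.3g km\n"),
              x$max_edge_inner, x$max_edge_outer, x$offset_outer, x$cutoff))
  invisible(x)
}

as_points <- function(points) {
  if (is.data.frame(points)) {
    if (all(c("x_km", "y_km") %in% names(points)))
      return(cbind(points$x_km, points$y_km))
    return(as.matrix(points[, 1:2]))
  }
  as.matrix(points)[, 1:2, drop = FALSE]
}

# Hexagonal lattice with spacing s covering a bbox; a tiny deterministic
# jitter breaks co-circular degeneracies without affecting edge lengths.
hex_lattice <- function(bb, s) {
  ys <- seq(bb["ymin"] - s, bb["ymax"] + s, by = s * sqrt(3) / 2)
  pts <- lapply(seq_along(ys), function(i) {
    off <- if (i %% 2 == 0) s / 2 else 0
    xs <- seq(bb["xmin"] - s + off, bb["xmax"] + s, by = s)
    cbind(xs, ys[i])
  })
  p <- do.call(rbind, pts)
  jit <- 1e-4 * s
  k <- seq_len(nrow(p))
  p[, 1] <- p[, 1] + jit * (((k * 7L) %% 13L) / 13 - 0.5)
  p[, 2] <- p[, 2] + jit * (((k * 11L) %% 17L) / 17 - 0.5)
  p
}

# Greedy cutoff thinning in input order using spatial hashing: keep a point
# only if no already-kept point lies within `cutoff`.
thin_points <- function(pts, cutoff) {
  n <- nrow(pts)
  if (n == 0) return(pts)
  cell <- cutoff
  key <- function(ix, iy) paste(ix, iy)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  keep <- logical(n)
  kx <- floor(pts[, 1] / cell); ky <- floor(pts[, 2] / cell)
  for (i in seq_len(n)) {
    ok <- TRUE
    for (dx in -1:1) {
      for (dy in -1:1) {
        ids <- seen[[key(kx[i] + dx, ky[i] + dy)]]
        if (!is.null(ids)) {
          d2 <- (pts[ids, 1] - pts[i, 1])^2 + (pts[ids, 2] - pts[i, 2])^2
          if (any(d2 < cutoff^2)) { ok <- FALSE; break }
        }
      }
      if (!ok) break
    }
    if (ok) {
      keep[i] <- TRUE
      k <- key(kx[i], ky[i])
      seen[[k]] <- c(seen[[k]], i)
    }
  }
  pts[keep, , drop = FALSE]
}

# Points along the boundary ring at roughly `s` spacing.
densify_ring <- function(ring, s) {
  n <- nrow(ring)
  nxt <- c(seq_len(n)[-1], 1)
  out <- list()
  for (i in seq_len(n)) {
    p <- ring[i, ]; q <- ring[nxt[i], ]
    len <- sqrt(sum((q - p)^2))
    k <- max(1L, ceiling(len / s))
    t <- (seq_len(k) - 1) / k
    out[[i]] <- cbind(p[1] + t * (q[1] - p[1]), p[2] + t * (q[2] - p[2]))
  }
  do.call(rbind, out)
}

#' Build the inner/outer triangulation
#'
#' Mesh seed nodes are the data points (thinned so no two are closer than
#' `params$cutoff`), the boundary ring, a fine hexagonal lattice filling the
#' (slightly dilated) boundary, and a coarse lattice filling the outer
#' buffer of width `params$offset_outer`; the combined set is thinned at the
#' cutoff and Delaunay-triangulated. Triangles are flagged inner when their
#' centroid lies inside the boundary polygon. The construction honours the
#' parameter contracts (inner edges below `max_edge_inner`, buffer width at
#' least `offset_outer`) rather than replicating any particular mesher's
#' node placement.
#'
#' @param points Data locations (matrix or data frame with `x_km`, `y_km`);
#'   must lie inside the boundary.
#' @param boundary Polygon ring matrix or `soil_geometry`.
#' @param params A `mesh_params`.
#' @return A `soil_mesh`: `nodes` (m x 2), `triangles` (t x 3, CCW),
#'   `inner` (logical per triangle), `boundary`, `params`.
#' @export
build_mesh <- function(points, boundary, params) {
  stopifnot(inherits(params, "mesh_params"))
  if (inherits(boundary, "soil_geometry")) boundary <- boundary$boundary
  xy <- as_points(points)
  if (params$cutoff >= params$max_edge_inner)
    stop("cutoff must be strictly below max_edge_inner (mesh would degenerate)",
         call. = FALSE)
  if (!all(point_in_polygon(xy[, 1], xy[, 2], boundary)))
    stop("all data points must lie inside the boundary", call. = FALSE)
  # cutoff thinning near data points can open lattice holes wider than the
  # edge limit; the refinement passes below repair those locally, so the
  # base lattice keeps its efficient spacing
  s_in <- 0.76 * params$max_edge_inner
  s_out <- 0.76 * params$max_edge_outer
  inner_halo <- offset_convex_polygon(boundary, s_in)
  outer_poly <- offset_convex_polygon(boundary, params$offset_outer + s_in + s_out)
  fine <- hex_lattice(ring_bbox(inner_halo), s_in)
  fine <- fine[point_in_polygon(fine[, 1], fine[, 2], inner_halo), , drop = FALSE]
  coarse <- hex_lattice(ring_bbox(outer_poly), s_out)
  in_outer <- point_in_polygon(coarse[, 1], coarse[, 2], outer_poly)
  in_halo <- point_in_polygon(coarse[, 1], coarse[, 2],
                              offset_convex_polygon(boundary, 1.2 * s_in))
  coarse <- coarse[in_outer & !in_halo, , drop = FALSE]
  ring_pts <- densify_ring(boundary, s_in)
  outer_ring <- densify_ring(offset_convex_polygon(boundary, params$offset_outer + s_in),
                             s_out)
  seeds <- rbind(thin_points(xy, params$cutoff), ring_pts, fine, coarse, outer_ring)
  nodes <- thin_points(seeds, params$cutoff)
  n_data <- nrow(thin_points(xy, params$cutoff))
  for (pass in 1:4) {
    tri <- delaunay_triangulate(nodes)
    cx <- (nodes[tri[, 1], 1] + nodes[tri[, 2], 1] + nodes[tri[, 3], 1]) / 3
    cy <- (nodes[tri[, 1], 2] + nodes[tri[, 2], 2] + nodes[tri[, 3], 2]) / 3
    keep <- point_in_polygon(cx, cy, outer_poly, tol = 1e-6)
    tri <- tri[keep, , drop = FALSE]
    inner <- point_in_polygon(cx[keep], cy[keep], boundary)
    # refinement: split inner-domain edges that exceed the maximum length
    it <- tri[inner, , drop = FALSE]
    ea <- c(it[, 1], it[, 2], it[, 3]); eb <- c(it[, 2], it[, 3], it[, 1])
    el <- sqrt(rowSums((nodes[ea, , drop = FALSE] - nodes[eb, , drop = FALSE])^2))
    long <- el > params$max_edge_inner
    if (!any(long) || pass == 4) break
    mids <- unique(round((nodes[ea[long], , drop = FALSE] +
                            nodes[eb[long], , drop = FALSE]) / 2, 9))
    nodes <- rbind(nodes, mids)
  }
  used <- sort(unique(as.vector(tri)))
  remap <- integer(nrow(nodes)); remap[used] <- seq_along(used)
  tri <- matrix(remap[tri], ncol = 3)
  nodes <- nodes[used, , drop = FALSE]
  cx <- (nodes[tri[, 1], 1] + nodes[tri[, 2], 1] + nodes[tri[, 3], 1]) / 3
  cy <- (nodes[tri[, 1], 2] + nodes[tri[, 2], 2] + nodes[tri[, 3], 2]) / 3
  inner <- point_in_polygon(cx, cy, boundary)
  colnames(nodes) <- c("x", "y")
  structure(list(nodes = nodes, triangles = tri, inner = inner,
                 boundary = boundary, params = params, n_data_seeds = n_data),
            class = "soil_mesh")
}

#' @export
print.soil_mesh <- function(x, ...) {
  cat(sprintf("<soil_mesh> %d nodes, %d triangles (%d inner)\n",
              nrow(x$nodes), nrow(x$triangles), sum(x$inner)))
  invisible(x)
}

tri_edge_lengths <- function(mesh, which_tri = seq_len(nrow(mesh$triangles))) {
  tr <- mesh$triangles[which_tri, , drop = FALSE]
  p1 <- mesh$nodes[tr[, 1], , drop = FALSE]
  p2 <- mesh$nodes[tr[, 2], , drop = FALSE]
  p3 <- mesh$nodes[tr[, 3], , drop = FALSE]
  cbind(sqrt(rowSums((p2 - p1)^2)),
        sqrt(rowSums((p3 - p2)^2)),
        sqrt(rowSums((p1 - p3)^2)))
}

#' Quality metrics of a mesh
#'
#' @param mesh A `soil_mesh`.
#' @return List: `n_nodes`, `n_triangles`, `min_angle_deg` (over inner
#'   triangles), `inner_max_edge`, `edge_lengths` (inner-edge vector for
#'   histograms).
#' @export
mesh_quality <- function(mesh) {
  stopifnot(inherits(mesh, "soil_mesh"))
  inner_idx <- which(mesh$inner)
  if (length(inner_idx) == 0) inner_idx <- seq_len(nrow(mesh$triangles))
  el <- tri_edge_lengths(mesh, inner_idx)
  a <- el[, 1]; b <- el[, 2]; c2 <- el[, 3]
  ang <- function(op, s1, s2) acos(pmin(1, pmax(-1, (s1^2 + s2^2 - op^2) / (2 * s1 * s2))))
  angles <- cbind(ang(a, b, c2), ang(b, c2, a), ang(c2, a, b)) * 180 / pi
  list(n_nodes = nrow(mesh$nodes),
       n_triangles = nrow(mesh$triangles),
       min_angle_deg = min(angles),
       inner_max_edge = max(el),
       edge_lengths = as.vector(el))
}

#' Barycentric projection matrix from mesh nodes to point locations
#'
#' Row `i` holds the barycentric weights of location `i` within its
#' containing triangle (at most 3 nonzeros summing to 1); locations outside
#' the mesh get an all-zero row and a warning.
#'
#' @param mesh A `soil_mesh`.
#' @param locations Matrix or data frame of point coordinates.
#' @return Sparse `dgCMatrix`, rows = locations, cols = mesh nodes.
#' @export
projection_matrix <- function(mesh, locations) {
  xy <- as_points(locations)
  if (nrow(xy) == 0) stop("locations list is empty", call. = FALSE)
  nodes <- mesh$nodes; tri <- mesh$triangles
  x1 <- nodes[tri[, 1], 1]; y1 <- nodes[tri[, 1], 2]
  x2 <- nodes[tri[, 2], 1]; y2 <- nodes[tri[, 2], 2]
  x3 <- nodes[tri[, 3], 1]; y3 <- nodes[tri[, 3], 2]
  det <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  # spatial binning of triangles for point location
  h <- max(tri_edge_lengths(mesh)) + 1e-9
  txmin <- pmin(x1, x2, x3); txmax <- pmax(x1, x2, x3)
  tymin <- pmin(y1, y2, y3); tymax <- pmax(y1, y2, y3)
  bx0 <- floor(txmin / h); bx1 <- floor(txmax / h)
  by0 <- floor(tymin / h); by1 <- floor(tymax / h)
  bins <- new.env(hash = TRUE, parent = emptyenv())
  for (t in seq_len(nrow(tri))) {
    for (ix in bx0[t]:bx1[t]) for (iy in by0[t]:by1[t]) {
      k <- paste(ix, iy)
      bins[[k]] <- c(bins[[k]], t)
    }
  }
  n <- nrow(xy)
  ri <- integer(0); ci <- integer(0); wi <- numeric(0)
  n_outside <- 0L
  tol <- 1e-9
  for (i in seq_len(n)) {
    px <- xy[i, 1]; py <- xy[i, 2]
    cand <- bins[[paste(floor(px / h), floor(py / h))]]
    found <- FALSE
    if (!is.null(cand)) {
      l2 <- ((px - x1[cand]) * (y3[cand] - y1[cand]) -
               (py - y1[cand]) * (x3[cand] - x1[cand])) / det[cand]
      l3 <- ((x2[cand] - x1[cand]) * (py - y1[cand]) -
               (y2[cand] - y1[cand]) * (px - x1[cand])) / det[cand]
      l1 <- 1 - l2 - l3
      ok <- which(l1 >= -tol & l2 >= -tol & l3 >= -tol)
      if (length(ok) > 0) {
        t <- cand[ok[1]]
        w <- c(l1[ok[1]], l2[ok[1]], l3[ok[1]])
        w <- pmax(w, 0); w <- w / sum(w)
        ri <- c(ri, rep.int(i, 3L)); ci <- c(ci, tri[t, ]); wi <- c(wi, w)
        found <- TRUE
      }
    }
    if (!found) n_outside <- n_outside + 1L
  }
  if (n_outside > 0)
    warning(sprintf("%d location(s) outside the mesh: all-zero projection rows",
                    n_outside))
  A <- Matrix::sparseMatrix(i = ri, j = ci, x = wi,
                            dims = c(n, nrow(nodes)))
  A
}

#' Serialize / deserialize a mesh as JSON
#'
#' Documented plain-text schema: `nodes` (array of [x, y] km), `triangles`
#' (1-based vertex triples), `inner` flags, `boundary` ring and the
#' generating parameters.
#'
#' @param mesh A `soil_mesh`.
#' @param path Output path.
#' @rdname mesh_json
#' @export
write_mesh_json <- function(mesh, path) {
  obj <- list(nodes = unname(mesh$nodes), triangles = mesh$triangles,
              inner = mesh$inner, boundary = unname(mesh$boundary),
              params = unclass(mesh$params))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname mesh_json
#' @export
read_mesh_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- as.matrix(obj$nodes); colnames(nodes) <- c("x", "y")
  structure(list(nodes = nodes,
                 triangles = matrix(as.integer(as.matrix(obj$triangles)), ncol = 3),
                 inner = as.logical(obj$inner),
                 boundary = as.matrix(obj$boundary),
                 params = do.call(mesh_params, obj$params)),
            class = "soil_mesh")
}
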