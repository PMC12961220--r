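# Synthetic study domain: a rectangular boundary tiled into "state" units.
# Stands in for a national boundary subdivided into administrative polygons;
# the modeling code only ever sees the generic polygon interface.

#' Define a rectangular synthetic study domain
#'
#' @param width,height Extent of the study rectangle, km (> 0).
#' @param n_states Integer vector `c(nx, ny)`: number of state tiles in x/y.
#' @param res Covariate raster resolution, km; must divide both extents.
#' @param origin Lower-left corner, km. Default `c(0, 0)`.
#' @return An object of class `soil_domain`.
#' @export
synthetic_domain <- function(width = 1200, height = 800, n_states = c(4, 3),
                             res = 10, origin = c(0, 0)) {
  if (!is.numeric(width) || !is.numeric(height) || width <= 0 || height <= 0)
    stop("invalid domain: extents must be positive", call. = FALSE)
  n_states <- as.integer(n_states)
  if (length(n_states) != 2 || any(n_states < 1))
    stop("invalid domain: n_states must be two integers >= 1", call. = FALSE)
  if (res <= 0) stop("invalid domain: res must be positive", call. = FALSE)
  if (abs(width / res - round(width / res)) > 1e-8 ||
      abs(height / res - round(height / res)) > 1e-8)
    stop("res must divide both extents", call. = FALSE)
  structure(list(width = width, height = height, n_states = n_states,
                 res = res, origin = origin),
            class = "soil_domain")
}

#' Build the boundary polygon and state tiling of a synthetic domain
#'
#' The boundary is the domain rectangle; states are an `nx` by `ny` tiling of
#' equal rectangles whose union is exactly the boundary (non-overlapping by
#' construction).
#'
#' @param domain A `soil_domain`.
#' @return A `soil_geometry`: list with `boundary` (ring matrix), `states`
#'   (named list of ring matrices), `state_ids`.
#' @export
make_synthetic_boundary <- function(domain) {
  stopifnot(inherits(domain, "soil_domain"))
  x0 <- domain$origin[1]; y0 <- domain$origin[2]
  w <- domain$width; h <- domain$height
  boundary <- cbind(x = c(x0, x0 + w, x0 + w, x0),
                    y = c(y0, y0, y0 + h, y0 + h))
  nx <- domain$n_states[1]; ny <- domain$n_states[2]
  sw <- w / nx; sh <- h / ny
  states <- list()
  ids <- character(0)
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      sx <- x0 + (i - 1) * sw; sy <- y0 + (j - 1) * sh
      id <- sprintf("S%02d", (j - 1) * nx + i)
      states[[id]] <- cbind(x = c(sx, sx + sw, sx + sw, sx),
                            y = c(sy, sy, sy + sh, sy + sh))
      ids <- c(ids, id)
    }
  }
  structure(list(boundary = boundary, states = states, state_ids = ids,
                 domain = domain),
            class = "soil_geometry")
}

#' Assign points to state polygons
#'
#' Each point receives the id of the first state polygon containing it
#' (closed boundaries; ties on shared internal edges resolve to the
#' lower-indexed state, deterministically).
#'
#' @param x,y Point coordinates, km.
#' @param geometry A `soil_geometry`.
#' @return Character vector of state ids; `NA` outside all states.
#' @export
assign_states <- function(x, y, geometry) {
  stopifnot(inherits(geometry, "soil_geometry"))
  out <- rep(NA_character_, length(x))
  for (id in geometry$state_ids) {
    left <- is.na(out)
    if (!any(left)) break
    hit <- point_in_polygon(x[left], y[left], geometry$states[[id]])
    out[left][hit] <- id
  }
  out
}

ring_to_geojson_coords <- function(ring) {
  closed <- rbind(ring, ring[1, ])
  lapply(seq_len(nrow(closed)), function(i) c(closed[i, 1], closed[i, 2]))
}

#' Write boundary and state polygons as GeoJSON
#'
#' Coordinates are written in the working km frame (no CRS member is
#' emitted; the file documents a local projected frame).
#'
#' @param geometry A `soil_geometry`.
#' @param path Output file path.
#' @export
write_domain_geojson <- function(geometry, path) {
  stopifnot(inherits(geometry, "soil_geometry"))
  feats <- list(list(
    type = "Feature",
    properties = list(role = "boundary"),
    geometry = list(type = "Polygon",
                    coordinates = list(ring_to_geojson_coords(geometry$boundary)))
  ))
  for (id in geometry$state_ids) {
    feats[[length(feats) + 1]] <- list(
      type = "Feature",
      properties = list(role = "state", state_id = id),
      geometry = list(type = "Polygon",
                      coordinates = list(ring_to_geojson_coords(geometry$states[[id]])))
    )
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a boundary + states GeoJSON written by [write_domain_geojson()]
#'
#' @param path GeoJSON file path.
#' @return A `soil_geometry` (without the generating `soil_domain`).
#' @export
read_domain_geojson <- function(path) {
  g <- jsonlite::read_json(path)
  boundary <- NULL; states <- list(); ids <- character(0)
  for (f in g$features) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) c(p[[1]], p[[2]])))
    ring <- ring[-nrow(ring), , drop = FALSE]   # drop closing vertex
    colnames(ring) <- c("x", "y")
    if (identical(f$properties$role, "boundary")) {
      boundary <- ring
    } else {
      id <- f$properties$state_id
      states[[id]] <- ring
      ids <- c(ids, id)
    }
  }
  structure(list(boundary = boundary, states = states, state_ids = ids,
                 domain = NULL),
            class = "soil_geometry")
}
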