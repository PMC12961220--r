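# Lightweight planar polygon utilities. All coordinates are in a projected
# frame with km units; rings are n x 2 matrices, open (first vertex not
# repeated), vertices ordered counter-clockwise.

#' Signed area of a polygon ring
#'
#' @param ring Numeric matrix (n x 2) of vertices, open ring.
#' @return Signed area (positive for counter-clockwise rings), km^2.
#' @keywords internal
polygon_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Test whether points lie inside (or on the edge of) a polygon
#'
#' Ray-casting with an explicit on-edge test; boundaries are closed, so a
#' point on an edge or vertex counts as inside. This is the containment rule
#' used throughout the pipeline (a survey site on the study boundary is kept).
#'
#' @param x,y Numeric vectors of point coordinates (km).
#' @param ring Polygon ring matrix (n x 2).
#' @param tol Absolute tolerance for the on-edge test, km.
#' @return Logical vector.
#' @export
point_in_polygon <- function(x, y, ring, tol = 1e-9) {
  stopifnot(length(x) == length(y), is.matrix(ring), ncol(ring) == 2)
  n <- nrow(ring)
  px <- ring[, 1]; py <- ring[, 2]
  qx <- c(px[-1], px[1]); qy <- c(py[-1], py[1])
  inside <- logical(length(x))
  onedge <- logical(length(x))
  for (e in seq_len(n)) {
    x1 <- px[e]; y1 <- py[e]; x2 <- qx[e]; y2 <- qy[e]
    # crossing test (half-open in y to avoid double counting vertices)
    crosses <- ((y1 > y) != (y2 > y))
    if (any(crosses)) {
      xint <- x1 + (y[crosses] - y1) / (y2 - y1) * (x2 - x1)
      inside[crosses] <- xor(inside[crosses], x[crosses] < xint)
    }
    # on-edge test: distance from segment within tol
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    if (len2 > 0) {
      t <- ((x - x1) * dx + (y - y1) * dy) / len2
      t <- pmin(1, pmax(0, t))
      d2 <- (x - (x1 + t * dx))^2 + (y - (y1 + t * dy))^2
      onedge <- onedge | (d2 <= tol^2)
    }
  }
  inside | onedge
}

#' Outward offset (dilation) of a convex polygon
#'
#' Moves every edge outward by `dist` along its normal and intersects the
#' resulting half-planes, yielding the Minkowski-style buffer used for the
#' outer mesh extension. The input is replaced by its convex hull first, so
#' mildly non-convex boundaries are buffered through their hull.
#'
#' @param ring Polygon ring matrix (n x 2).
#' @param dist Offset distance, km (> 0).
#' @return Offset ring matrix (counter-clockwise).
#' @keywords internal
offset_convex_polygon <- function(ring, dist) {
  stopifnot(dist > 0)
  h <- grDevices::chull(ring[, 1], ring[, 2])
  ring <- ring[rev(h), , drop = FALSE]            # chull returns clockwise
  if (polygon_area(ring) < 0) ring <- ring[rev(seq_len(nrow(ring))), , drop = FALSE]
  n <- nrow(ring)
  nxt <- c(seq_len(n)[-1], 1)
  ex <- ring[nxt, 1] - ring[, 1]
  ey <- ring[nxt, 2] - ring[, 2]
  len <- sqrt(ex^2 + ey^2)
  keep <- len > 1e-12
  ring <- ring[keep, , drop = FALSE]
  n <- nrow(ring); nxt <- c(seq_len(n)[-1], 1); prv <- c(n, seq_len(n)[-n])
  ex <- ring[nxt, 1] - ring[, 1]; ey <- ring[nxt, 2] - ring[, 2]
  len <- sqrt(ex^2 + ey^2)
  # outward normal of a CCW edge is (ey, -ex)/len
  nx <- ey / len; ny <- -ex / len
  # each offset edge: point p_i + dist*normal_i, direction (ex, ey)
  px <- ring[, 1] + dist * nx; py <- ring[, 2] + dist * ny
  out <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    j <- prv[i]
    # intersect offset edge j with offset edge i
    d <- ex[j] * ey[i] - ey[j] * ex[i]
    if (abs(d) < 1e-12) {       # nearly collinear edges: take the offset vertex
      out[i, ] <- c(ring[i, 1] + dist * nx[i], ring[i, 2] + dist * ny[i])
    } else {
      t <- ((px[i] - px[j]) * ey[i] - (py[i] - py[j]) * ex[i]) / d
      out[i, ] <- c(px[j] + t * ex[j], py[j] + t * ey[j])
    }
  }
  out
}

#' Bounding box of a ring
#' @keywords internal
ring_bbox <- function(ring) {
  c(xmin = min(ring[, 1]), xmax = max(ring[, 1]),
    ymin = min(ring[, 2]), ymax = max(ring[, 2]))
}
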