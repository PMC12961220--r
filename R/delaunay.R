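# Incremental Bowyer-Watson Delaunay triangulation, written against the
# package's meshing needs: a few thousand nodes, deterministic output for a
# given input order. Points are expected to be free of duplicates (the mesh
# builder's cutoff thinning guarantees a minimum separation).

circumcircle <- function(x1, y1, x2, y2, x3, y3) {
  ax <- x2 - x1; ay <- y2 - y1
  bx <- x3 - x1; by <- y3 - y1
  d <- 2 * (ax * by - ay * bx)
  if (abs(d) < 1e-14 * (abs(ax * by) + abs(ay * bx) + 1e-300)) {
    return(c(NA_real_, NA_real_, Inf))
  }
  a2 <- ax * ax + ay * ay
  b2 <- bx * bx + by * by
  ux <- (by * a2 - ay * b2) / d
  uy <- (ax * b2 - bx * a2) / d
  c(x1 + ux, y1 + uy, ux * ux + uy * uy)
}

#' Delaunay triangulation of a planar point set
#'
#' @param pts Numeric matrix (n x 2), n >= 3, no duplicate points.
#' @return Integer matrix (m x 3) of triangle vertex indices into `pts`,
#'   counter-clockwise.
#' @keywords internal
delaunay_triangulate <- function(pts) {
  n <- nrow(pts)
  stopifnot(n >= 3)
  xr <- range(pts[, 1]); yr <- range(pts[, 2])
  cx <- mean(xr); cy <- mean(yr)
  d <- max(xr[2] - xr[1], yr[2] - yr[1], 1)
  # super-triangle comfortably containing everything
  sx <- c(cx - 30 * d, cx + 30 * d, cx)
  sy <- c(cy - 20 * d, cy - 20 * d, cy + 30 * d)
  vx <- c(sx, pts[, 1]); vy <- c(sy, pts[, 2])
  cap <- max(64L, 6L * n)
  t1 <- integer(cap); t2 <- integer(cap); t3 <- integer(cap)
  ccx <- numeric(cap); ccy <- numeric(cap); cr2 <- numeric(cap)
  alive <- logical(cap)
  ntri <- 0L
  add_tri <- function(a, b, c) {
    ntri <<- ntri + 1L
    if (ntri > length(t1)) {     # grow storage
      grow <- function(v) c(v, vector(mode(v), length(v)))
      t1 <<- grow(t1); t2 <<- grow(t2); t3 <<- grow(t3)
      ccx <<- grow(ccx); ccy <<- grow(ccy); cr2 <<- grow(cr2)
      alive <<- c(alive, logical(length(alive)))
    }
    cc <- circumcircle(vx[a], vy[a], vx[b], vy[b], vx[c], vy[c])
    t1[ntri] <<- a; t2[ntri] <<- b; t3[ntri] <<- c
    ccx[ntri] <<- cc[1]; ccy[ntri] <<- cc[2]; cr2[ntri] <<- cc[3]
    alive[ntri] <<- TRUE
  }
  add_tri(1L, 2L, 3L)
  nv <- n + 3L
  for (p in 4:nv) {
    px <- vx[p]; py <- vy[p]
    idx <- seq_len(ntri)
    live <- idx[alive[idx]]
    dx <- ccx[live] - px; dy <- ccy[live] - py
    bad <- live[dx * dx + dy * dy <= cr2[live] * (1 + 1e-12) + 1e-12]
    if (length(bad) == 0L) next   # degenerate; should not happen inside super-tri
    ea <- c(t1[bad], t2[bad], t3[bad])
    eb <- c(t2[bad], t3[bad], t1[bad])
    lo <- pmin(ea, eb); hi <- pmax(ea, eb)
    key <- lo * (nv + 1) + hi
    once <- !(key %in% key[duplicated(key)])
    alive[bad] <- FALSE
    for (e in which(once)) add_tri(ea[e], eb[e], p)
    # periodic compaction keeps the scan short
    if (ntri > 4L * n + 64L && sum(alive[seq_len(ntri)]) < ntri / 2L) {
      keep <- which(alive[seq_len(ntri)])
      m <- length(keep)
      t1[seq_len(m)] <- t1[keep]; t2[seq_len(m)] <- t2[keep]; t3[seq_len(m)] <- t3[keep]
      ccx[seq_len(m)] <- ccx[keep]; ccy[seq_len(m)] <- ccy[keep]; cr2[seq_len(m)] <- cr2[keep]
      alive[seq_len(ntri)] <- FALSE
      alive[seq_len(m)] <- TRUE
      ntri <- m
    }
  }
  keep <- which(alive[seq_len(ntri)])
  tri <- cbind(t1[keep], t2[keep], t3[keep])
  tri <- tri[tri[, 1] > 3L & tri[, 2] > 3L & tri[, 3] > 3L, , drop = FALSE] - 3L
  # enforce counter-clockwise orientation
  ax <- pts[tri[, 2], 1] - pts[tri[, 1], 1]
  ay <- pts[tri[, 2], 2] - pts[tri[, 1], 2]
  bx <- pts[tri[, 3], 1] - pts[tri[, 1], 1]
  by <- pts[tri[, 3], 2] - pts[tri[, 1], 2]
  cwise <- (ax * by - ay * bx) < 0
  if (any(cwise)) tri[cwise, 2:3] <- tri[cwise, 3:2]
  tri
}
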