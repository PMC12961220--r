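# Minimal in-memory raster container for the covariate grids. Values are a
# matrix with rows indexing y from the bottom (row 1 = southernmost row) and
# columns indexing x from the left, so values[i, j] is the cell centred at
# (xmin + (j - 1/2) res, ymin + (i - 1/2) res). Georeferencing is a km frame.

#' Construct a raster
#'
#' @param values Numeric matrix, rows = y from the bottom, cols = x from left.
#' @param xmin,ymin Lower-left corner of the grid, km.
#' @param res Cell edge length, km.
#' @param name Optional layer name.
#' @return A `soil_raster`.
#' @export
soil_raster <- function(values, xmin, ymin, res, name = "layer") {
  stopifnot(is.matrix(values), res > 0)
  structure(list(values = values, xmin = xmin, ymin = ymin, res = res,
                 nrow = nrow(values), ncol = ncol(values), name = name),
            class = "soil_raster")
}

#' @export
print.soil_raster <- function(x, ...) {
  cat(sprintf("<soil_raster> '%s': %d x %d cells, res %.4g km, origin (%.4g, %.4g)\n",
              x$name, x$nrow, x$ncol, x$res, x$xmin, x$ymin))
  invisible(x)
}

#' Cell-centre coordinates of a raster
#' @param r A `soil_raster`.
#' @return List with vectors `x` (length ncol) and `y` (length nrow).
#' @export
raster_xy <- function(r) {
  list(x = r$xmin + (seq_len(r$ncol) - 0.5) * r$res,
       y = r$ymin + (seq_len(r$nrow) - 0.5) * r$res)
}

#' Look up raster values at point locations (containing-cell rule)
#'
#' @param r A `soil_raster`.
#' @param x,y Point coordinates, km.
#' @return Numeric vector; `NA` outside the raster extent.
#' @export
raster_extract <- function(r, x, y) {
  j <- floor((x - r$xmin) / r$res) + 1
  i <- floor((y - r$ymin) / r$res) + 1
  # points exactly on the top/right edge belong to the last cell
  j[x == r$xmin + r$ncol * r$res] <- r$ncol
  i[y == r$ymin + r$nrow * r$res] <- r$nrow
  ok <- i >= 1 & i <= r$nrow & j >= 1 & j <= r$ncol & !is.na(i) & !is.na(j)
  out <- rep(NA_real_, length(x))
  out[ok] <- r$values[cbind(i[ok], j[ok])]
  out
}

# 1-D overlap-length matrix between source cells and destination cells:
# W[d, s] = length of the intersection of destination interval d with source
# interval s. Area overlaps of axis-aligned grids factor into x and y parts.
overlap_weights_1d <- function(src_min, src_res, src_n, dst_min, dst_res, dst_n) {
  s_lo <- src_min + (seq_len(src_n) - 1) * src_res
  s_hi <- s_lo + src_res
  d_lo <- dst_min + (seq_len(dst_n) - 1) * dst_res
  d_hi <- d_lo + dst_res
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  for (d in seq_len(dst_n)) {
    s_first <- max(1L, floor((d_lo[d] - src_min) / src_res) + 1L)
    s_last <- min(src_n, ceiling((d_hi[d] - src_min) / src_res))
    if (s_first > s_last) next
    s <- s_first:s_last
    w <- pmin(d_hi[d], s_hi[s]) - pmax(d_lo[d], s_lo[s])
    keep <- w > 1e-12
    ii <- c(ii, rep.int(d, sum(keep))); jj <- c(jj, s[keep]); ww <- c(ww, w[keep])
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(dst_n, src_n))
}

# Area-weighted mean resampling onto a template grid, NA-aware: weights of
# missing source cells are dropped and the remainder renormalized; a
# destination cell with no valid overlap becomes NA.
resample_area_mean <- function(r, template) {
  Wx <- overlap_weights_1d(r$xmin, r$res, r$ncol,
                           template$xmin, template$res, template$ncol)
  Wy <- overlap_weights_1d(r$ymin, r$res, r$nrow,
                           template$ymin, template$res, template$nrow)
  V <- r$values
  M <- !is.na(V)
  V0 <- V; V0[!M] <- 0
  num <- as.matrix(Wy %*% V0 %*% Matrix::t(Wx))
  den <- as.matrix(Wy %*% (M * 1) %*% Matrix::t(Wx))
  out <- num / den
  out[den <= 1e-12] <- NA_real_
  soil_raster(out, template$xmin, template$ymin, template$res, name = r$name)
}

# Bilinear resampling at template cell centres (used when the source is
# coarser than or equal to the template). Outside the source cell-centre
# hull, nearest valid value is used; outside the source extent -> NA.
resample_bilinear <- function(r, template) {
  sxy <- raster_xy(r)
  txy <- raster_xy(template)
  fx <- (txy$x - sxy$x[1]) / r$res
  fy <- (txy$y - sxy$y[1]) / r$res
  j0 <- pmin(pmax(floor(fx), 0), r$ncol - 2); tx <- fx - j0
  i0 <- pmin(pmax(floor(fy), 0), r$nrow - 2); ty <- fy - i0
  tx <- pmin(pmax(tx, 0), 1); ty <- pmin(pmax(ty, 0), 1)
  out <- matrix(NA_real_, template$nrow, template$ncol)
  inx <- txy$x >= r$xmin & txy$x <= r$xmin + r$ncol * r$res
  iny <- txy$y >= r$ymin & txy$y <= r$ymin + r$nrow * r$res
  V <- r$values
  for (i in which(iny)) {
    a <- V[i0[i] + 1, j0 + 1]; b <- V[i0[i] + 1, j0 + 2]
    c2 <- V[i0[i] + 2, j0 + 1]; d <- V[i0[i] + 2, j0 + 2]
    v <- (1 - ty[i]) * ((1 - tx) * a + tx * b) + ty[i] * ((1 - tx) * c2 + tx * d)
    v[!inx] <- NA_real_
    out[i, ] <- v
  }
  soil_raster(out, template$xmin, template$ymin, template$res, name = r$name)
}

#' Align covariate rasters to a template grid
#'
#' Each raster is cropped/resampled onto the template: finer-than-template
#' sources by area-weighted mean aggregation (e.g. a binary cropland layer
#' becomes a per-cell crop proportion), coarser or equal sources by bilinear
#' interpolation. Alignment is verified by shape equality.
#'
#' @param rasters Named list of `soil_raster`.
#' @param template A `soil_raster` (values ignored) or `sampling_grid`
#'   defining the target georeferencing.
#' @return Named list of aligned `soil_raster` (a covariate raster set).
#' @export
align_rasters <- function(rasters, template) {
  if (inherits(template, "sampling_grid")) template <- grid_template_raster(template)
  out <- vector("list", length(rasters))
  names(out) <- names(rasters)
  for (nm in names(rasters)) {
    r <- rasters[[nm]]
    overlap_x <- min(r$xmin + r$ncol * r$res, template$xmin + template$ncol * template$res) -
      max(r$xmin, template$xmin)
    overlap_y <- min(r$ymin + r$nrow * r$res, template$ymin + template$nrow * template$res) -
      max(r$ymin, template$ymin)
    if (overlap_x <= 0 || overlap_y <= 0)
      stop(sprintf("raster '%s' does not overlap the template extent", nm), call. = FALSE)
    already <- isTRUE(all.equal(c(r$xmin, r$ymin, r$res), c(template$xmin, template$ymin, template$res))) &&
      r$nrow == template$nrow && r$ncol == template$ncol
    out[[nm]] <- if (already) {
      r
    } else if (r$res < template$res - 1e-12) {
      resample_area_mean(r, template)
    } else {
      resample_bilinear(r, template)
    }
    stopifnot(out[[nm]]$nrow == template$nrow, out[[nm]]$ncol == template$ncol)
  }
  out
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text georeferenced export. With `meters = TRUE` the georeferencing
#' (origin and cell size) is scaled from km to m (a pure metadata scale by
#' 1000); cell values are unchanged.
#'
#' @param r A `soil_raster`.
#' @param path Output path (conventionally `.asc`).
#' @param meters Scale georeferencing from km to m on export.
#' @param nodata NODATA sentinel written for missing cells.
#' @export
write_ascii_grid <- function(r, path, meters = FALSE, nodata = -9999) {
  s <- if (meters) 1000 else 1
  hdr <- c(sprintf("ncols %d", r$ncol),
           sprintf("nrows %d", r$nrow),
           sprintf("xllcorner %.10g", r$xmin * s),
           sprintf("yllcorner %.10g", r$ymin * s),
           sprintf("cellsize %.10g", r$res * s),
           sprintf("NODATA_value %g", nodata))
  V <- r$values[rev(seq_len(r$nrow)), , drop = FALSE]  # .asc rows run north->south
  V[is.na(V)] <- nodata
  lines <- apply(V, 1, function(row) paste(formatC(row, digits = 17, format = "g"),
                                           collapse = " "))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path File path.
#' @param from_meters Divide georeferencing by 1000 back into the km frame.
#' @param name Layer name for the result.
#' @return A `soil_raster`.
#' @export
read_ascii_grid <- function(path, from_meters = FALSE, name = "layer") {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key, "\\b"), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  ncols <- val("ncols"); nrows <- val("nrows")
  xll <- val("xllcorner"); yll <- val("yllcorner")
  cs <- val("cellsize"); nodata <- val("NODATA_value")
  body <- lines[-(1:6)]
  V <- do.call(rbind, lapply(body, function(ln) as.numeric(strsplit(trimws(ln), "\\s+")[[1]])))
  V[V == nodata] <- NA_real_
  V <- V[rev(seq_len(nrow(V))), , drop = FALSE]
  s <- if (from_meters) 1 / 1000 else 1
  stopifnot(nrow(V) == nrows, ncol(V) == ncols)
  soil_raster(V, xll * s, yll * s, cs * s, name = name)
}
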