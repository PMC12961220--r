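# Finite-element representation of a Matern (smoothness nu = 1) Gaussian
# random field: P1 elements on the mesh give the mass matrix C (lumped) and
# stiffness matrix G, and the SPDE precision
#   Q(range, sigma) = tau^2 (kappa^4 C + 2 kappa^2 G + G C^-1 G)
# with kappa = sqrt(8)/range and tau^2 = 1 / (4 pi kappa^2 sigma^2), so that
# the field has marginal SD sigma and correlation ~0.14 at distance = range
# (the conventional "practical range" where correlation has dropped to
# roughly 0.1).

#' Assemble finite-element operators of a mesh
#'
#' @param mesh A `soil_mesh`.
#' @return An `spde_operator`: `c_diag` (lumped mass diagonal), `G`
#'   (sparse stiffness), `gcg` (precomputed `G C^-1 G`), `n` nodes,
#'   `total_area` of the triangulation.
#' @export
assemble_fem <- function(mesh) {
  stopifnot(inherits(mesh, "soil_mesh"))
  nodes <- mesh$nodes; tri <- mesh$triangles
  # memoize per mesh: repeated fits on one mesh skip re-assembly
  cache_key <- paste(nrow(nodes), nrow(tri),
                     format(sum(nodes), digits = 16), sum(tri))
  cached <- .fem_cache[[cache_key]]
  if (!is.null(cached)) return(cached)
  n <- nrow(nodes)
  x1 <- nodes[tri[, 1], 1]; y1 <- nodes[tri[, 1], 2]
  x2 <- nodes[tri[, 2], 1]; y2 <- nodes[tri[, 2], 2]
  x3 <- nodes[tri[, 3], 1]; y3 <- nodes[tri[, 3], 2]
  area2 <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  if (any(area2 <= 1e-12)) {
    bad <- which(area2 <= 1e-12)[1]
    stop(sprintf("degenerate triangle %d (non-positive area)", bad), call. = FALSE)
  }
  area <- area2 / 2
  # P1 basis gradients: for vertex k, grad = (b_k, c_k) / (2 area)
  b <- cbind(y2 - y3, y3 - y1, y1 - y2)
  cc <- cbind(x3 - x2, x1 - x3, x2 - x1)
  ii <- integer(0); jj <- integer(0); gg <- numeric(0)
  for (a in 1:3) {
    for (bidx in 1:3) {
      ii <- c(ii, tri[, a]); jj <- c(jj, tri[, bidx])
      gg <- c(gg, (b[, a] * b[, bidx] + cc[, a] * cc[, bidx]) / (4 * area))
    }
  }
  G <- Matrix::sparseMatrix(i = ii, j = jj, x = gg, dims = c(n, n))
  G <- Matrix::forceSymmetric((G + Matrix::t(G)) / 2)
  c_diag <- numeric(n)
  for (a in 1:3) {
    inc <- tapply(area / 3, tri[, a], sum)
    c_diag[as.integer(names(inc))] <- c_diag[as.integer(names(inc))] + inc
  }
  gcg <- Matrix::forceSymmetric(G %*% Matrix::Diagonal(n, 1 / c_diag) %*% G)
  # union sparsity pattern; components aligned to it so Q(range, sigma) is
  # assembled by pure x-slot arithmetic in the inference hot loop
  pat <- Matrix::forceSymmetric(Matrix::Diagonal(n, 1) + G + gcg)
  pat <- methods::as(pat, "CsparseMatrix")
  zero <- pat; zero@x <- numeric(length(pat@x))
  align <- function(Mx) (methods::as(Matrix::forceSymmetric(Mx), "CsparseMatrix") + zero)@x
  cx <- align(Matrix::Diagonal(n, c_diag))
  gx <- align(G)
  gcgx <- align(gcg)
  out <- structure(list(c_diag = c_diag, G = G, gcg = gcg,
                        pattern = pat, cx = cx, gx = gx, gcgx = gcgx,
                        spectrum_env = new.env(parent = emptyenv()),
                        n = n, total_area = sum(area)),
                   class = "spde_operator")
  if (length(.fem_cache) > 20) rm(list = ls(.fem_cache), envir = .fem_cache)
  .fem_cache[[cache_key]] <- out
  out
}

.fem_cache <- new.env(parent = emptyenv())

#' @export
print.spde_operator <- function(x, ...) {
  cat(sprintf("<spde_operator> %d nodes, total area %.5g km^2\n", x$n, x$total_area))
  invisible(x)
}

#' SPDE Matern precision matrix for given range and marginal SD
#'
#' @param op An `spde_operator` from [assemble_fem()].
#' @param range Spatial correlation range, km (> 0).
#' @param sigma Marginal standard deviation of the field (> 0).
#' @return Sparse symmetric positive-definite precision matrix.
#' @export
spde_precision <- function(op, range, sigma) {
  stopifnot(inherits(op, "spde_operator"), range > 0, sigma > 0)
  kappa <- sqrt(8) / range
  tau2 <- 1 / (4 * pi * kappa^2 * sigma^2)
  Q <- op$pattern
  Q@x <- tau2 * (kappa^4 * op$cx + 2 * kappa^2 * op$gx + op$gcgx)
  Q
}

# Generalized spectrum of B = C^-1/2 G C^-1/2, computed lazily and cached:
# only inference needs it (for O(n) prior log-determinants), and only for
# meshes small enough that one dense eigendecomposition amortizes.
spde_spectrum <- function(op) {
  env <- op$spectrum_env
  if (is.null(env$done)) {
    env$ev <- if (op$n <= 1200) {
      s <- 1 / sqrt(op$c_diag)
      B <- Matrix::Diagonal(op$n, s) %*% op$G %*% Matrix::Diagonal(op$n, s)
      eigen(as.matrix(Matrix::forceSymmetric(B)), symmetric = TRUE,
            only.values = TRUE)$values
    }
    env$done <- TRUE
  }
  env$ev
}

# log-determinant of spde_precision(op, range, sigma), via the generalized
# spectrum when available (identity Q = tau^2 C^1/2 (kappa^2 I + B)^2 C^1/2).
spde_logdet <- function(op, range, sigma) {
  kappa <- sqrt(8) / range
  tau2 <- 1 / (4 * pi * kappa^2 * sigma^2)
  ev <- spde_spectrum(op)
  if (!is.null(ev)) {
    op$n * log(tau2) + sum(log(op$c_diag)) +
      2 * sum(log(kappa^2 + pmax(ev, 0)))
  } else {
    ch <- Matrix::Cholesky(spde_precision(op, range, sigma), LDL = FALSE, perm = TRUE)
    2 * as.numeric(Matrix::determinant(ch, logarithm = TRUE, sqrt = TRUE)$modulus)
  }
}

#' Matern (nu = 1) correlation function under the practical-range convention
#'
#' `matern_correlation(d, range)` returns `kappa d K1(kappa d)` with
#' `kappa = sqrt(8)/range`; at `d = range` this is about 0.14.
#'
#' @param d Distances, km (>= 0).
#' @param range Practical range, km.
#' @return Correlation values in (0, 1].
#' @export
matern_correlation <- function(d, range) {
  kappa <- sqrt(8) / range
  out <- rep(1, length(d))
  pos <- d > 0
  out[pos] <- (kappa * d[pos]) * besselK(kappa * d[pos], 1)
  out
}

#' Penalized-complexity prior for the range or marginal SD
#'
#' The PC prior shrinks toward the simple base model (infinite range / zero
#' variance) with an exponential penalty, calibrated by one tail statement:
#' for the marginal SD, `P(sigma > u) = alpha` (exponential with rate
#' `-log(alpha)/u`); for the 2-D range, `P(range < u) = alpha` (density
#' `lambda p^-2 exp(-lambda/p)` with `lambda = -u log(alpha)`, an
#' inverse-exponential form).
#'
#' @param kind `"range"` or `"sigma"`.
#' @param u Threshold (> 0), in km for the range.
#' @param alpha Tail probability in (0, 1).
#' @return A `pc_prior` with functions `d` (density), `p` (CDF), `q`
#'   (quantile), `r` (sampler) and `log_d`.
#' @export
pc_prior <- function(kind = c("range", "sigma"), u, alpha) {
  kind <- match.arg(kind)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (u <= 0) stop("threshold u must be positive", call. = FALSE)
  if (kind == "sigma") {
    lambda <- -log(alpha) / u
    obj <- list(
      kind = kind, u = u, alpha = alpha, lambda = lambda,
      d = function(x) stats::dexp(x, rate = lambda),
      log_d = function(x) stats::dexp(x, rate = lambda, log = TRUE),
      p = function(x) stats::pexp(x, rate = lambda),
      q = function(p) stats::qexp(p, rate = lambda),
      r = function(n) stats::rexp(n, rate = lambda))
  } else {
    lambda <- -u * log(alpha)
    obj <- list(
      kind = kind, u = u, alpha = alpha, lambda = lambda,
      d = function(x) ifelse(x > 0, lambda * x^-2 * exp(-lambda / x), 0),
      log_d = function(x) ifelse(x > 0, log(lambda) - 2 * log(x) - lambda / x, -Inf),
      p = function(x) ifelse(x > 0, exp(-lambda / x), 0),
      q = function(p) -lambda / log(p),
      r = function(n) -lambda / log(stats::runif(n)))
  }
  structure(obj, class = "pc_prior")
}

#' @export
print.pc_prior <- function(x, ...) {
  rel <- if (x$kind == "sigma") ">" else "<"
  cat(sprintf("<pc_prior> P(%s %s %g) = %g (lambda = %g)\n",
              x$kind, rel, x$u, x$alpha, x$lambda))
  invisible(x)
}

#' Default range-prior threshold from the observed point pattern
#'
#' Half the x-direction spatial extent of the data locations: the weakly
#' informative threshold for the range PC prior when no model-based range
#' estimate is available yet.
#'
#' @param points Point coordinates (matrix or data frame).
#' @return `range_ob`, km.
#' @export
default_range_threshold <- function(points) {
  xy <- as_points(points)
  if (nrow(xy) < 2) stop("need at least 2 points", call. = FALSE)
  extent_x <- max(xy[, 1]) - min(xy[, 1])
  if (extent_x <= 0) stop("zero x-extent", call. = FALSE)
  extent_x / 2
}

# Draw n independent samples of a zero-mean GMRF with sparse precision Q,
# via the permuted Cholesky factor: x = P' L^-T z.
sample_gmrf <- function(Q, n = 1) {
  ch <- Matrix::Cholesky(Q, LDL = FALSE, perm = TRUE)
  m <- nrow(Q)
  z <- matrix(stats::rnorm(m * n), m, n)
  y <- Matrix::solve(ch, z, system = "Lt")
  as.matrix(Matrix::solve(ch, y, system = "Pt"))
}

# Dense Matern (nu = 1) covariance between point sets, marginal SD sigma.
matern_covariance <- function(pts, range, sigma) {
  d <- as.matrix(stats::dist(pts))
  n <- nrow(pts)
  sigma^2 * matrix(matern_correlation(as.vector(d), range), n, n)
}
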