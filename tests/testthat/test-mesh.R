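test_that("coarse-mesh heuristics reproduce the extent divisors exactly", {
  pts <- cbind(c(0, 1200, 600, 300), c(0, 800, 400, 100))
  p <- coarse_mesh_params(pts)
  expect_equal(p$max_edge_inner, 100)
  expect_equal(p$max_edge_outer, 500)
  expect_equal(p$offset_outer, 400)
  expect_equal(p$cutoff, 20)

  p2 <- coarse_mesh_params(cbind(c(3, 15), c(0, 1)))   # x-extent 12
  expect_equal(p2$max_edge_inner, 1)

  set.seed(1)
  cloud <- cbind(runif(50, -30, 470), runif(50, 0, 200))
  pc <- coarse_mesh_params(cloud)
  ext <- diff(range(cloud[, 1]))
  expect_equal(ext / pc$max_edge_inner, 12)
  expect_equal(ext / pc$offset_outer, 3)
  expect_equal(pc$max_edge_outer / pc$max_edge_inner, 5)
  expect_equal(pc$max_edge_inner / pc$cutoff, 5)
  expect_error(coarse_mesh_params(cbind(c(1, 1), c(0, 5))), "extent")
})

test_that("fine-mesh parameters scale with the range estimate", {
  coarse <- coarse_mesh_params(cbind(c(0, 1200), c(0, 800)))
  f10 <- fine_mesh_params(300, coarse)
  expect_equal(f10$max_edge_inner, 30)
  expect_equal(f10$offset_outer, coarse$offset_outer)
  expect_equal(f10$max_edge_outer, coarse$max_edge_outer)
  f5 <- fine_mesh_params(300, coarse, fraction = 1 / 5)
  expect_equal(f5$max_edge_inner, 60)
  fc <- fine_mesh_params(300, coarse, cutoff = 0.5)
  expect_equal(fc$cutoff, 0.5)
  expect_equal(fc$max_edge_inner, 30)
  expect_error(fine_mesh_params(-10, coarse), "positive")
})

test_that("built meshes honour the edge, containment and cutoff contracts", {
  geo <- make_synthetic_boundary(synthetic_domain(600, 400, c(1, 1), res = 10))
  set.seed(20)
  pts <- cbind(runif(100, 10, 590), runif(100, 10, 390))
  counts <- c()
  for (frac in c(1 / 5, 1 / 10, 1 / 15)) {
    params <- fine_mesh_params(200, coarse_mesh_params(pts), fraction = frac)
    mesh <- build_mesh(pts, geo, params)
    q <- mesh_quality(mesh)
    expect_lte(q$inner_max_edge, params$max_edge_inner * 1.01)
    counts <- c(counts, q$n_nodes)
    A <- projection_matrix(mesh, pts)
    expect_true(all(abs(Matrix::rowSums(A) - 1) < 1e-12))  # all data in-mesh
    # triangle areas all positive
    tr <- mesh$triangles; nd <- mesh$nodes
    ar <- (nd[tr[, 2], 1] - nd[tr[, 1], 1]) * (nd[tr[, 3], 2] - nd[tr[, 1], 2]) -
      (nd[tr[, 3], 1] - nd[tr[, 1], 1]) * (nd[tr[, 2], 2] - nd[tr[, 1], 2])
    expect_true(all(ar > 0))
  }
  expect_true(all(diff(counts) > 0))   # finer fraction -> more nodes
  expect_error(build_mesh(pts, geo,
                          soilspde:::mesh_params(10, 50, 100, 10)), "cutoff")
})

test_that("cutoff thinning merges near-duplicate seed points", {
  pts <- rbind(c(100, 100), c(100.7, 100.7))   # ~1 km apart
  kept <- soilspde:::thin_points(pts, cutoff = 20)
  expect_equal(nrow(kept), 1)
  expect_equal(kept[1, ], pts[1, ])            # first-in-order wins
  spread <- rbind(c(0, 0), c(50, 0), c(0, 50))
  expect_equal(nrow(soilspde:::thin_points(spread, 20)), 3)
})

test_that("outer buffer is at least the offset wide", {
  geo <- make_synthetic_boundary(synthetic_domain(300, 200, c(1, 1), res = 10))
  set.seed(3)
  pts <- cbind(runif(40, 10, 290), runif(40, 10, 190))
  params <- coarse_mesh_params(pts)
  mesh <- build_mesh(pts, geo, params)
  bb <- soilspde:::ring_bbox(mesh$nodes)
  expect_lte(bb["xmin"], 0 - params$offset_outer * 0.99)
  expect_gte(bb["xmax"], 300 + params$offset_outer * 0.99)
})

test_that("projection weights are barycentric", {
  geo <- make_synthetic_boundary(synthetic_domain(100, 100, c(1, 1), res = 10))
  set.seed(7)
  pts <- cbind(runif(30, 5, 95), runif(30, 5, 95))
  mesh <- build_mesh(pts, geo, coarse_mesh_params(pts))
  # at a node: single weight of 1
  A1 <- projection_matrix(mesh, mesh$nodes[10, , drop = FALSE])
  expect_equal(sum(A1), 1)
  expect_equal(max(A1), 1)
  # at a centroid: three weights of 1/3
  tr <- mesh$triangles[which(mesh$inner)[1], ]
  centroid <- colMeans(mesh$nodes[tr, ])
  A2 <- projection_matrix(mesh, matrix(centroid, 1))
  expect_equal(sort(as.vector(A2[1, tr])), rep(1 / 3, 3))
  # random interior locations: rows sum to one
  loc <- cbind(runif(50, 10, 90), runif(50, 10, 90))
  A3 <- projection_matrix(mesh, loc)
  expect_true(all(abs(Matrix::rowSums(A3) - 1) < 1e-12))
  expect_true(all(A3@x >= 0 & A3@x <= 1))
  expect_true(all(Matrix::rowSums(A3 != 0) <= 3))
  # P1 elements reproduce linear functions exactly
  f <- function(p) 2 + 0.3 * p[, 1] - 0.7 * p[, 2]
  expect_equal(as.vector(A3 %*% f(mesh$nodes)), f(loc), tolerance = 1e-10)
  # outside the mesh: zero row plus warning
  expect_warning(A4 <- projection_matrix(mesh, cbind(1e4, 1e4)), "outside")
  expect_equal(Matrix::rowSums(A4)[1], 0)
})

test_that("mesh quality reports angles, counts and the equilateral case", {
  tri_mesh <- structure(list(
    nodes = cbind(x = c(0, 1, 0.5), y = c(0, 0, sqrt(3) / 2)),
    triangles = matrix(c(1L, 2L, 3L), 1),
    inner = TRUE,
    boundary = cbind(c(0, 1, 0.5), c(0, 0, sqrt(3) / 2)),
    params = soilspde:::mesh_params(2, 2, 1, 0.1)), class = "soil_mesh")
  q <- mesh_quality(tri_mesh)
  expect_equal(q$min_angle_deg, 60, tolerance = 1e-9)
  expect_equal(q$n_nodes, 3)
  expect_equal(q$n_triangles, 1)
})

test_that("mesh JSON serialization round trips", {
  geo <- make_synthetic_boundary(synthetic_domain(100, 100, c(1, 1), res = 10))
  set.seed(9)
  pts <- cbind(runif(20, 10, 90), runif(20, 10, 90))
  mesh <- build_mesh(pts, geo, coarse_mesh_params(pts))
  path <- withr::local_tempfile(fileext = ".json")
  write_mesh_json(mesh, path)
  back <- read_mesh_json(path)
  expect_equal(back$nodes, mesh$nodes)
  expect_equal(back$triangles, mesh$triangles)
  expect_equal(back$inner, mesh$inner)
  expect_equal(back$params$cutoff, mesh$params$cutoff)
})

test_that("Delaunay triangulation has the empty-circumcircle property", {
  set.seed(13)
  pts <- cbind(runif(60), runif(60))
  tri <- soilspde:::delaunay_triangulate(pts)
  for (t in sample(nrow(tri), 10)) {
    cc <- soilspde:::circumcircle(pts[tri[t, 1], 1], pts[tri[t, 1], 2],
                                  pts[tri[t, 2], 1], pts[tri[t, 2], 2],
                                  pts[tri[t, 3], 1], pts[tri[t, 3], 2])
    d2 <- (pts[, 1] - cc[1])^2 + (pts[, 2] - cc[2])^2
    expect_equal(sum(d2 < cc[3] * (1 - 1e-9)), 0)
  }
})
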