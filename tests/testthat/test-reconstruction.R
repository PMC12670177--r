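test_that("baseline alpha is k x d_avg with the documented default", {
  g <- as.matrix(expand.grid(x = 1:12, y = 1:12, z = 1:12)) * 0.01
  pc <- pointCloud(g)
  expect_equal(baselineAlpha(pc), 0.05, tolerance = 0.05)  # grid d_avg ~ 0.01
  expect_error(baselineAlpha(pc, k = 0), "positive")
  # forced arithmetic: d_avg = 0.02 exactly on collinear pairs
  pairs <- pointCloud(cbind(seq(0, 10, by = 1), 0, 0))
  expect_equal(baselineAlpha(pairs, k = 5), 5 * 1)
})

test_that("mesh volume is exact on analytic solids and origin-independent", {
  expect_identical(meshVolume(cubeMesh()), 1)
  expect_equal(meshVolume(tetraMesh()), 1 / 6)

  # translation far from the origin: the signed-sum contract keeps the
  # volume unchanged (a per-term absolute value would not)
  shifted <- cubeMesh()
  shifted@vertices <- sweep(shifted@vertices, 2, c(10, 10, 10), "+")
  expect_equal(meshVolume(shifted), 1, tolerance = 1e-12)

  sph <- reconstructCanopy(sphereCloud(r = 1, n = 4000, seed = 2))
  v0 <- meshVolume(sph)
  expect_equal(v0, 4 * pi / 3, tolerance = 0.05)
  sph@vertices <- sweep(sph@vertices, 2, c(10, 10, 10), "+")
  expect_equal(meshVolume(sph), v0, tolerance = 1e-9)
})

test_that("an open mesh is rejected with its boundary-edge count", {
  open <- cubeMesh()
  open@triangles <- open@triangles[-1, , drop = FALSE]
  expect_error(meshVolume(open), "not closed")
})

test_that("reconstruction closes a sphere sample within 10% of the analytic volume", {
  mesh <- reconstructCanopy(sphereCloud(r = 0.5, n = 2000, seed = 1))
  expect_false(mesh@hullFallback)
  expect_equal(mesh@volume, 4 / 3 * pi * 0.5^3, tolerance = 0.10)
  expect_equal(meshVolume(mesh), mesh@volume)
  # closed: no defective edges
  expect_identical(canopyEV:::cpp_mesh_bad_edges(mesh@triangles), 0L)
})

test_that("four tetrahedron points reconstruct to the tetrahedron itself", {
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  mesh <- reconstructCanopy(pointCloud(pts), alphaParams(k = 50))
  expect_equal(mesh@volume, 1 / 6, tolerance = 1e-9)
})

test_that("degenerate clouds are rejected and split clouds still close", {
  flat <- pointCloud(cbind(runif(50), runif(50), 0))
  expect_error(reconstructCanopy(flat), "coplanar|degenerate")

  # two parallel disjoint patches: alpha grows until bridged or the hull
  # fallback fires; either way the contract is a closed mesh
  set.seed(14)
  p1 <- cbind(runif(300), runif(300), rnorm(300, 0, 0.01))
  p2 <- cbind(runif(300), runif(300), rnorm(300, 1, 0.01))
  mesh <- suppressWarnings(reconstructCanopy(pointCloud(rbind(p1, p2))))
  expect_identical(canopyEV:::cpp_mesh_bad_edges(mesh@triangles), 0L)
  expect_gt(mesh@volume, 0)
})

test_that("alpha-shape closure is monotone in alpha and bounded by the convex hull", {
  cl <- sphereCloud(r = 0.5, n = 1500, seed = 3)
  mu <- unique(coords(cl))
  del <- canopyEV:::cpp_delaunay3d(mu)
  mesh <- reconstructCanopy(cl)
  hull <- canopyEV:::cpp_alpha_boundary(del$tets, mu,
                                        rep(TRUE, nrow(del$tets)))
  expect_lte(mesh@volume, hull$volume * (1 + 1e-9))
  for (mult in c(1.5, 3)) {
    b <- canopyEV:::cpp_alpha_boundary(del$tets, mu,
                                       del$circumradius <= mesh@alphaUsed * mult)
    expect_true(b$closed)
    expect_lte(b$volume, hull$volume * (1 + 1e-9))
  }
})

test_that("reconstruction is deterministic", {
  cl <- makeSpindleCanopy(seed = 9)@cloud
  m1 <- reconstructCanopy(cl)
  m2 <- reconstructCanopy(cl)
  expect_identical(m1@volume, m2@volume)
  expect_identical(m1@triangles, m2@triangles)
  expect_identical(m1@alphaUsed, m2@alphaUsed)
})

test_that("the 2D Delaunay triangulation agrees with the deldir oracle", {
  skip_if_not_installed("deldir")
  set.seed(15)
  p <- cbind(runif(300), runif(300))
  mine <- canopyEV:::cpp_delaunay2d(p)$triangles
  dd <- deldir::triang.list(deldir::deldir(p[, 1], p[, 2]))
  orac <- t(vapply(dd, function(t) sort(t$ptNum), integer(3)))
  canon <- function(m) {
    m <- t(apply(m, 1, sort))
    m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
  }
  expect_equal(canon(mine), canon(orac))
})

test_that("3D Delaunay tetrahedra all have empty circumspheres", {
  set.seed(16)
  q <- matrix(runif(240), 80, 3)
  d3 <- canopyEV:::cpp_delaunay3d(q)
  for (k in seq_len(nrow(d3$tets))) {
    v <- q[d3$tets[k, ], ]
    A <- 2 * rbind(v[2, ] - v[1, ], v[3, ] - v[1, ], v[4, ] - v[1, ])
    b <- c(sum(v[2, ]^2 - v[1, ]^2), sum(v[3, ]^2 - v[1, ]^2),
           sum(v[4, ]^2 - v[1, ]^2))
    cc <- solve(A, b)
    r2 <- sum((v[1, ] - cc)^2)
    inside <- which(rowSums(sweep(q, 2, cc)^2) < r2 * (1 - 1e-9))
    expect_length(setdiff(inside, d3$tets[k, ]), 0L)
  }
})
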