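test_that("projection drops the right axis and keeps every point", {
  pc <- pointCloud(rbind(c(1, 2, 3), c(4, 5, 6)))
  pr <- projectCloud(pc, "yoz")
  expect_equal(pr$points2d[1, ], c(y = 2, z = 3))
  expect_equal(pr$dropped, c(1, 4))
  expect_equal(nrow(projectCloud(pc, "xoy")$points2d), 2L)
  cube <- makePrimitiveCloud("cube", c(edge = 1), density = 3000, seed = 1)
  for (pl in c("xoy", "xoz", "yoz")) {
    p <- projectCloud(cube@cloud, pl)$points2d
    expect_equal(unname(apply(p, 2, min)), c(0, 0), tolerance = 0.05)
    expect_equal(unname(apply(p, 2, max)), c(1, 1), tolerance = 0.05)
  }
})

test_that("voxelization follows the hand binning and the brute-force oracle", {
  g <- voxelizeProjection(rbind(c(0.25, 0.25), c(0.75, 0.25)), VS = 0.5)
  expect_true(g@occupancy[1, 1])
  expect_true(g@occupancy[2, 1])
  expect_equal(sum(g@occupancy), 2L)

  expect_equal(sum(voxelizeProjection(matrix(c(3, 7), 1, 2), VS = 0.5)@occupancy), 1L)
  expect_error(voxelizeProjection(matrix(1, 1, 2), VS = 0), "positive")

  set.seed(17)
  p <- matrix(runif(2000), 1000, 2)
  g2 <- voxelizeProjection(p, VS = 0.07)
  occ <- which(g2@occupancy, arr.ind = TRUE) - 1L
  brute <- bruteBinCells(p, 0.07)
  expect_equal(nrow(occ), nrow(brute))
  expect_setequal(paste(occ[, 1], occ[, 2]), paste(brute[, 1], brute[, 2]))
})

test_that("the 2D boundary contour covers the points and preserves concavity", {
  set.seed(18)
  sq <- matrix(runif(8000), 4000, 2)
  g <- voxelizeProjection(sq, VS = 0.02)
  g <- boundaryContour(g)
  expect_equal(g@contourArea, 1, tolerance = 0.05)
  expect_true(all(g@inContour[g@occupancy]))   # occupied => in contour

  # C shape: alpha contour area clearly below convex hull area
  th <- runif(4000, 0.25 * pi, 1.75 * pi)
  r <- runif(4000, 0.6, 1)
  cs <- cbind(r * cos(th), r * sin(th))
  ac <- canopyEV:::.alphaComplex2D(cs)
  hullArea <- canopyEV:::.hullArea(cs)
  expect_lt(ac$area, 0.9 * hullArea)

  # triangle with a huge alpha is the triangle itself
  tri <- rbind(c(0, 0), c(1, 0), c(0, 1))
  expect_equal(canopyEV:::.alphaComplex2D(tri, k2 = 1000)$area, 0.5)
  # collinear points are rejected
  expect_error(canopyEV:::.alphaComplex2D(cbind(1:5, 1:5)), "degenerate|collinear")
})

test_that("enclosed windows of the projection count as in-contour, notches do not", {
  set.seed(19)
  # annulus: the central hole is enclosed by the outer boundary
  th <- runif(6000, 0, 2 * pi)
  r <- runif(6000, 0.6, 1)
  ring <- cbind(r * cos(th), r * sin(th))
  g <- boundaryContour(voxelizeProjection(ring, VS = 0.04))
  nx <- g@dims[1]; ny <- g@dims[2]
  centerCell <- c(ceiling(nx / 2), ceiling(ny / 2))
  expect_false(g@occupancy[centerCell[1], centerCell[2]])
  expect_true(g@inContour[centerCell[1], centerCell[2]])
  # corner far outside the disk stays out of contour
  expect_false(g@inContour[1, 1])
})

test_that("partition weights implement the thickness rule with interpolated gaps", {
  # 10 x 10 voxels -> 2 x 2 partitions of 5 x 5; one partition has points
  # with dropped-axis values spanning 0.35 m
  pts <- rbind(c(0.01, 0.01), c(0.12, 0.14), c(0.31, 0.02), c(0.44, 0.21),
               c(0.02, 0.31), c(0.21, 0.44), c(0.33, 0.33), c(0.48, 0.48))
  dropped <- c(0.10, 0.45, 0.2, 0.2, 0.3, 0.3, 0.25, 0.25)
  g <- voxelizeProjection(pts, VS = 0.05, dropped = dropped)
  g <- boundaryContour(g)
  pg <- partitionWeights(g, 5)
  expect_equal(pg@W[1, 1], 0.35)           # max - min = 0.45 - 0.10
  expect_true(all(pg@nev <= pg@nav))

  # points whose dropped-axis values coincide give a degenerate zero
  # weight (single-point case), left for interpolation
  tri3 <- rbind(c(0.01, 0.01), c(0.03, 0.02), c(0.02, 0.04))
  g1 <- boundaryContour(voxelizeProjection(tri3, VS = 0.05,
                                           dropped = c(0.2, 0.2, 0.2)))
  expect_equal(partitionWeights(g1, 5)@W[1, 1], 0)
})

test_that("zero-weight interpolation follows the Jacobi hand traces", {
  mk <- function(W, nav) new("PartitionGrid", partitionMultiplier = 5L,
                             W = W, nev = array(0L, dim(W)),
                             nav = nav, interpolationRounds = 0L)
  # 3x3, center missing, neighbours all 0.4 -> one round, center 0.4
  W <- matrix(0.4, 3, 3); W[2, 2] <- 0
  out <- interpolateZeroWeights(mk(W, matrix(1L, 3, 3)))
  expect_equal(out@W[2, 2], 0.4)
  expect_equal(out@interpolationRounds, 1L)

  # line 0.2, 0, 0, 0.6: round one fills from the available non-zero sides
  W2 <- matrix(c(0.2, 0, 0, 0.6), 1, 4)
  out2 <- interpolateZeroWeights(mk(W2, matrix(1L, 1, 4)))
  expect_equal(as.vector(out2@W), c(0.2, 0.2, 0.6, 0.6))
  expect_equal(out2@interpolationRounds, 1L)

  # nothing to do: identity, zero rounds
  out3 <- interpolateZeroWeights(mk(matrix(0.5, 2, 2), matrix(1L, 2, 2)))
  expect_equal(out3@interpolationRounds, 0L)

  # a zero-weight partition with no non-zero weight anywhere: error
  expect_error(interpolateZeroWeights(mk(matrix(0, 2, 2), matrix(1L, 2, 2))),
               "interpolated")
})

test_that("the plane effective coefficient is the weighted occupancy ratio", {
  mk <- function(W, nev, nav) new("PartitionGrid", partitionMultiplier = 5L,
                                  W = W, nev = nev, nav = nav,
                                  interpolationRounds = 0L)
  W <- matrix(c(1, 1), 1); nev <- matrix(c(10L, 20L), 1); nav <- matrix(c(20L, 20L), 1)
  expect_equal(planeEffectiveCoefficient(mk(W, nev, nav)), 0.75)
  W2 <- matrix(c(1, 3), 1)
  expect_equal(planeEffectiveCoefficient(mk(W2, nev, nav)), 0.875)
  # saturation: every in-contour voxel occupied -> EC = 1
  expect_equal(planeEffectiveCoefficient(mk(W, nav, nav)), 1)
  expect_error(planeEffectiveCoefficient(mk(matrix(0, 1, 1), matrix(0L, 1, 1),
                                            matrix(0L, 1, 1))), "empty")
})

test_that("a dense solid cube saturates every plane coefficient", {
  cube <- makePrimitiveCloud("cube", c(edge = 1), density = 27000, seed = 3)
  mesh <- reconstructCanopy(cube@cloud)
  ev <- effectiveVolume(cube@cloud, mesh)
  expect_true(all(ev@EC >= 0.95))
  expect_equal(ev@Ve, 1, tolerance = 0.1)
  expect_equal(ev@EVC, prod(ev@EC))
  expect_lte(ev@Ve, ev@Vm)
})

test_that("carving porosity out of the same point stream lowers every affected EC", {
  # nested clouds: the porous cloud is a subset of the solid one
  solid <- makeSpindleCanopy(seed = 20)
  porous <- makeSpindleCanopy(porosity = spindlePorosity(0.3), seed = 20)
  expect_lt(nPoints(porous), nPoints(solid))
  evS <- effectiveVolume(solid@cloud, reconstructCanopy(solid@cloud))
  evP <- effectiveVolume(porous@cloud, reconstructCanopy(porous@cloud))
  expect_lt(evP@EVC, evS@EVC)
  expect_lt(evP@Ve, evS@Ve)
  for (ev in list(evS, evP)) {
    expect_true(all(ev@EC > 0 & ev@EC <= 1))
    expect_lte(ev@Ve, ev@Vm)
    expect_lte(ev@EVC, min(ev@EC))
  }
})

test_that("plane coefficients are invariant under rigid translation", {
  can <- makeSpindleCanopy(seed = 21, density = 3000)
  mesh <- reconstructCanopy(can@cloud)
  ev1 <- effectiveVolume(can@cloud, mesh)
  shifted <- pointCloud(sweep(coords(can), 2, c(100, -50, 7), "+"))
  mesh2 <- mesh
  mesh2@vertices <- sweep(mesh2@vertices, 2, c(100, -50, 7), "+")
  ev2 <- effectiveVolume(shifted, mesh2)
  expect_equal(unname(ev2@EC), unname(ev1@EC), tolerance = 1e-6)
  expect_equal(ev2@Ve, ev1@Ve, tolerance = 1e-6)
})

test_that("the identity EVC triple returns the mesh volume unchanged", {
  res <- new("EVResult", Vm = 2.5, EC = c(xoy = 1, xoz = 1, yoz = 1),
             EVC = 1, Ve = 2.5, params = list())
  expect_equal(res@Ve, res@Vm)
  # EVResult validity enforces the EC range and Ve <= Vm
  expect_error(new("EVResult", Vm = 1, EC = c(xoy = 1.2, xoz = 1, yoz = 1),
                   EVC = 1.2, Ve = 1.2, params = list()), "coefficient")
})
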