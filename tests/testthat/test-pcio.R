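test_that("xyz files read with coordinates intact and errors name the line", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("0 0 0", "1 0 0", "0 1 0"), f)
  pc <- readCloud(f)
  expect_equal(nPoints(pc), 3L)
  expect_equal(coords(pc)[2, ], c(x = 1, y = 0, z = 0))

  bad <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("0 0 0", "a b c"), bad)
  expect_error(readCloud(bad), "line 2")

  empty <- withr::local_tempfile(fileext = ".xyz")
  writeLines(character(0), empty)
  expect_error(readCloud(empty), "empty")

  expect_error(readCloud(file.path(tempdir(), "no-such-file.xyz")), "no such file")
})

test_that("round trips preserve coordinates to 1e-6 m in all four formats", {
  set.seed(42)
  m <- cbind(runif(10000, -50, 50), runif(10000, -50, 50), runif(10000, 0, 30))
  pc <- pointCloud(m)
  for (fmt in c("xyz", "ply", "pcd", "las")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    writeCloud(pc, f)
    back <- readCloud(f)
    expect_lt(max(abs(coords(back) - m)), 1e-6, label = paste(fmt, "round trip"))
  }
  # binary flavours of ply and pcd
  for (fmt in c("ply", "pcd")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    writeCloud(pc, f, binary = TRUE)
    expect_equal(coords(readCloud(f)), coords(pc), tolerance = 1e-12)
  }
})

test_that("writing refuses an empty cloud and single points survive", {
  expect_error(writeCloud(pointCloud(matrix(numeric(0), 0, 3)),
                          tempfile(fileext = ".xyz")), "empty")
  f <- withr::local_tempfile(fileext = ".ply")
  writeCloud(pointCloud(matrix(c(1.5, -2.25, 3), 1, 3)), f)
  expect_equal(unname(coords(readCloud(f))[1, ]), c(1.5, -2.25, 3))
})

test_that("average nearest-neighbour distance matches grids, hand cases and the all-pairs oracle", {
  g <- as.matrix(expand.grid(x = 1:20, y = 1:20, z = 1:20)) * 0.02
  expect_equal(averageNNDistance(pointCloud(g))$d_avg, 0.02, tolerance = 0.05)

  coll <- cbind(c(0, 1, 3), 0, 0)
  expect_equal(averageNNDistance(pointCloud(coll))$d_avg, 4 / 3)

  set.seed(7)
  m <- matrix(runif(1500), 500, 3)
  expect_equal(averageNNDistance(pointCloud(m))$d_avg, bruteMeanNN(m))
  # 2D variant against the same oracle on the first two columns
  expect_equal(averageNNDistance(m[, 1:2], dims = 2)$d_avg,
               bruteMeanNN(m[, 1:2]))

  expect_error(averageNNDistance(pointCloud(matrix(1:3, 1, 3))), "at least 2")
})

test_that("d_avg is rigid-motion invariant, scales linearly, and keeps duplicates", {
  set.seed(8)
  m <- matrix(runif(300), 100, 3)
  d0 <- averageNNDistance(pointCloud(m))$d_avg
  # translation
  expect_equal(averageNNDistance(pointCloud(sweep(m, 2, c(5, -3, 9), "+")))$d_avg, d0)
  # rotation about z by 30 degrees
  th <- pi / 6
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(averageNNDistance(pointCloud(m %*% t(R)))$d_avg, d0)
  # uniform scaling
  expect_equal(averageNNDistance(pointCloud(m * 2.5))$d_avg, 2.5 * d0)
  # an exact duplicate contributes a zero distance and is not removed
  md <- rbind(m, m[1, ])
  dd <- averageNNDistance(pointCloud(md))$d_avg
  expect_lt(dd, d0)
})
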