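test_that("row segmentation splits Gaussian clusters at standard tall-spindle row spacing", {
  set.seed(10)
  mk <- function(centers, n = 2000, sd = 0.4) {
    y <- as.vector(vapply(centers, function(c) rnorm(n, c, sd), numeric(n)))
    pointCloud(cbind(runif(length(y), 0, 5), y, runif(length(y), 0, 3)))
  }
  two <- mk(c(0, 3.5))
  rs <- segmentRows(two)
  expect_length(rs$cut_positions, 1L)
  expect_lt(abs(rs$cut_positions - 1.75), 0.3)
  # membership: first 2000 points generated around y=0 belong to row 1
  y <- coords(two)[, 2]
  grp <- findInterval(y, c(-Inf, rs$cut_positions, Inf))
  expect_gte(mean(grp[1:2000] == 1), 0.99)
  expect_gte(mean(grp[2001:4000] == 2), 0.99)

  one <- mk(0)
  expect_length(segmentRows(one)$cut_positions, 0L)
  expect_length(segmentRows(one)$rows, 1L)

  three <- mk(c(0, 3.5, 7))
  expect_length(segmentRows(three)$cut_positions, 2L)
  expect_length(segmentRows(three)$rows, 3L)
})

test_that("row segmentation is a partition and degenerate Y warns", {
  set.seed(11)
  pc <- pointCloud(cbind(runif(500), rnorm(500, rep(c(0, 3.5), each = 250), 0.3),
                         runif(500)))
  rs <- segmentRows(pc)
  expect_equal(sum(vapply(rs$rows, nPoints, 0L)), 500L)

  flat <- pointCloud(cbind(runif(50), 2, runif(50)))
  expect_warning(rs2 <- segmentRows(flat), "identical")
  expect_length(rs2$rows, 1L)
})

test_that("height profile bins per the hand trace and matches brute-force per-bin maxima", {
  pc <- pointCloud(rbind(c(0.01, 0, 1), c(0.07, 0, 2), c(0.12, 0, 0.5)))
  prof <- heightProfile(pc, bin_width = 0.05)
  expect_equal(prof$max_z, c(1, 2, 0.5))

  slab <- pointCloud(cbind(runif(500), runif(500), 2))
  expect_true(all(heightProfile(slab)$max_z == 2, na.rm = TRUE))

  set.seed(12)
  row <- makeOrchard(n_rows = 1, trees_per_row = 5, ground = "none",
                     noise_rate = 0, seed = 4)
  m <- coords(row)
  prof2 <- heightProfile(row@cloud, bin_width = 0.05)
  idx <- pmin(floor((m[, 1] - min(m[, 1])) / 0.05), length(prof2$max_z) - 1L)
  brute <- tapply(m[, 3], idx, max)
  expect_equal(unname(prof2$max_z[as.integer(names(brute)) + 1L]),
               as.vector(brute))
})

test_that("trough screening follows the three-stage hand traces", {
  p <- troughParams(bin_width = 1, min_depth = 0.3, min_spacing = 1.5,
                    sig_depth = 0.8)
  # deep single trough kept
  expect_equal(detectTroughs(profileFromZ(c(3.0, 2.0, 3.1)), p), 1.5)
  # pseudo-trough (depth 0.1) removed
  expect_length(detectTroughs(profileFromZ(c(3.0, 2.9, 3.0)), p), 0L)
  # spacing rule keeps the lower trough; the removed one is deep against
  # both peaks (1.0 and 0.8 >= sig_depth) and is reinstated
  p2 <- troughParams(bin_width = 1, min_depth = 0.3, min_spacing = 3,
                     sig_depth = 0.8)
  z <- c(3.0, 2.0, 2.8, 1.5, 3.0)
  expect_equal(detectTroughs(profileFromZ(z), p2), c(1.5, 3.5))
  # same profile, sig_depth above the removed trough's weaker depth:
  # only the lower trough survives
  p3 <- troughParams(bin_width = 1, min_depth = 0.3, min_spacing = 3,
                     sig_depth = 0.9)
  expect_equal(detectTroughs(profileFromZ(z), p3), 3.5)
})

test_that("trough detection ignores empty end bins and is monotone in min_depth", {
  p <- troughParams(bin_width = 1, min_depth = 0.3, min_spacing = 1.5,
                    sig_depth = 0.8)
  z <- c(3.0, 2.0, 3.1)
  base <- detectTroughs(profileFromZ(z), p)
  padded <- profileFromZ(c(NA, NA, z, NA))
  # bin centers shift with the padding; compare relative to first non-empty
  got <- detectTroughs(padded, p)
  expect_equal(got - 2, base)

  set.seed(13)
  for (rep in 1:20) {
    z <- cumsum(rnorm(40)) + 5 * sin(seq(0, 6 * pi, length.out = 40))
    prof <- profileFromZ(z)
    prev <- Inf
    for (md in c(0.5, 1, 2, 4)) {
      ns <- length(detectTroughs(prof,
        troughParams(bin_width = 1, min_depth = md, min_spacing = 1.5,
                     sig_depth = Inf)))
      expect_lte(ns, prev)
      prev <- ns
    }
  }
})

test_that("column segmentation splits a five-tree wall and leaves fused pairs alone", {
  row <- makeOrchard(n_rows = 1, trees_per_row = 5, ground = "none",
                     noise_rate = 0, seed = 5)
  cs <- segmentColumns(row@cloud)
  expect_length(cs$columns, 5L)
  expect_length(cs$split_x, 4L)
  # each generated tree's points land >= 95% in a single column
  colAssign <- findInterval(coords(row)[, 1], c(-Inf, cs$split_x, Inf))
  for (t in 1:5) {
    sel <- row@treeId == t
    expect_gte(max(table(colAssign[sel])) / sum(sel), 0.95)
  }
  # partition: every point in exactly one column
  expect_equal(sum(vapply(cs$columns, nPoints, 0L)), nPoints(row))

  single <- makeSpindleCanopy(seed = 6)
  expect_length(segmentColumns(single@cloud)$columns, 1L)

  # dip shallower than min_depth: under-segmentation into one column
  fused <- makeOrchard(n_rows = 1, trees_per_row = 2, ground = "none",
                       noise_rate = 0, seed = 7)
  cs2 <- segmentColumns(fused@cloud,
                        troughParams(min_depth = 3.4, sig_depth = 3.4))
  expect_length(cs2$columns, 1L)
})
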