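test_that("radius outlier removal keeps dense clusters and drops isolated points", {
  set.seed(1)
  cluster <- matrix(rnorm(150, sd = 0.012), 50, 3)        # 50 pts within ~0.05 m
  lone <- c(5, 5, 5)
  pc <- pointCloud(rbind(cluster, lone))
  res <- radiusOutlierRemoval(pc, rorParams(radius = 0.2, min_neighbors = 20))
  expect_equal(res$removed_count, 1L)
  expect_equal(nPoints(res$kept), 50L)

  # min_neighbors = 0 is the identity
  res0 <- radiusOutlierRemoval(pc, rorParams(radius = 0.2, min_neighbors = 0))
  expect_equal(res0$removed_count, 0L)
  expect_identical(coords(res0$kept), coords(pc))
})

test_that("radius outlier removal matches the all-pairs oracle and is non-cascading", {
  set.seed(2)
  m <- matrix(runif(600), 200, 3)
  res <- radiusOutlierRemoval(pointCloud(m),
                              rorParams(radius = 0.15, min_neighbors = 5))
  expect_identical(res$kept_indices, bruteRORKeep(m, 0.15, 5))
  expect_equal(coords(res$kept), m[bruteRORKeep(m, 0.15, 5), ],
               ignore_attr = TRUE)

  # chain A-B-C: A has 1 neighbour (removed), B has 2 (kept); a cascading
  # pass would re-examine B after A's removal and drop it too
  chain <- cbind(c(0, 1, 2, 3, 3.5, 3.6), 0, 0)
  res2 <- radiusOutlierRemoval(pointCloud(chain),
                               rorParams(radius = 1.05, min_neighbors = 2))
  expect_true(2L %in% res2$kept_indices)   # B survives: decisions vs original
  expect_false(1L %in% res2$kept_indices)
})

test_that("ground leveling recovers a tilted plane and preserves pairwise distances", {
  set.seed(3)
  # ground tilted 10 degrees about Y + a canopy blob
  g <- cbind(runif(3000, 0, 10), runif(3000, 0, 10), rnorm(3000, sd = 0.01))
  th <- 10 * pi / 180
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  blob <- cbind(rnorm(500, 5, 0.3), rnorm(500, 5, 0.3), rnorm(500, 2, 0.3))
  m <- rbind(g %*% t(R), blob)
  out <- levelToGround(pointCloud(m))
  # recovered pre-rotation normal within 1 degree of the true tilted normal
  trueN <- R %*% c(0, 0, 1)
  ang <- acos(min(1, abs(sum(out$result$ground_normal_before * trueN))))
  expect_lt(ang * 180 / pi, 1)
  # after leveling, ground inliers sit near z = 0
  gz <- coords(out$leveled)[seq_len(3000), 3]
  expect_lt(stats::quantile(abs(gz), 0.95), 0.05)
  # rigid motion: pairwise distances preserved
  i <- sample.int(nrow(m), 50)
  expect_equal(as.vector(dist(coords(out$leveled)[i, ])),
               as.vector(dist(m[i, ])), tolerance = 1e-9)
  # rotation is orthonormal with determinant +1
  Rr <- out$result$rotation
  expect_equal(crossprod(Rr), diag(3), tolerance = 1e-9)
  expect_equal(det(Rr), 1, tolerance = 1e-9)
})

test_that("leveling an already-level cloud is near-identity and no-plane errors", {
  set.seed(4)
  g <- cbind(runif(2000, 0, 5), runif(2000, 0, 5), rnorm(2000, sd = 0.01))
  out <- levelToGround(pointCloud(g))
  expect_lt(max(abs(out$result$rotation - diag(3))), 0.01)  # within ~0.5 deg

  sparse <- matrix(runif(300), 100, 3)  # no planar structure
  expect_error(levelToGround(pointCloud(sparse), min_inlier_fraction = 0.5),
               "no ground plane")
})

test_that("ground filtering separates a flat floor from an elevated blob", {
  set.seed(5)
  floor <- cbind(runif(4000, 0, 5), runif(4000, 0, 5), rnorm(4000, sd = 0.01))
  blob <- cbind(rnorm(800, 2.5, 0.3), rnorm(800, 2.5, 0.3), rnorm(800, 1.5, 0.2))
  res <- removeGround(pointCloud(rbind(floor, blob)))
  expect_gte(nPoints(res$ground), 0.99 * 4000)
  expect_true(all(res$offground_indices > 4000))
  expect_error(removeGround(pointCloud(matrix(numeric(0), 0, 3))), "empty")
  expect_error(removeGround(pointCloud(floor), method = "csf"),
               "cloth-simulation backend")
})

test_that("ground filtering on undulating terrain recovers the generated canopy count", {
  orch <- makeOrchard(n_rows = 1, trees_per_row = 3, ground = "undulating",
                      seed = 2)
  lev <- levelToGround(orch@cloud)
  res <- removeGround(lev$leveled)
  truth <- sum(orch@labels == "canopy")
  expect_lt(abs(nPoints(res$offground) / truth - 1), 0.02)
})

test_that("the preprocessing pipeline keeps canopy, drops ground and flags noise-only input", {
  orch <- makeOrchard(n_rows = 1, trees_per_row = 3, seed = 3)
  pp <- preprocessPipeline(orch@cloud)
  lab <- orch@labels[attr(pp, "kept_indices")]
  expect_gte(sum(lab == "canopy") / sum(orch@labels == "canopy"), 0.95)
  expect_lte(mean(lab == "ground"), 0.01)
  # pipeline output is a subset of the input (up to the leveling motion):
  # point count never grows and all kept indices are valid input rows
  expect_lte(nPoints(pp), nPoints(orch@cloud))
  expect_true(all(attr(pp, "kept_indices") %in% seq_len(nPoints(orch@cloud))))

  set.seed(6)
  noise <- pointCloud(matrix(runif(90, 0, 30), 30, 3))
  expect_warning(out <- preprocessPipeline(noise, level = FALSE),
                 "outlier")
  expect_equal(nPoints(out), 0L)
})
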