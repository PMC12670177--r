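test_that("primitive generators carry exact analytic truths and are seed-deterministic", {
  cube <- makePrimitiveCloud("cube", c(edge = 1), density = 1000, seed = 7)
  expect_identical(cube@truthSolidVolume, 1)
  sph <- makePrimitiveCloud("sphere", c(radius = 0.5), density = 1000, seed = 7)
  expect_equal(sph@truthSolidVolume, 4 / 3 * pi * 0.125)
  fr <- makePrimitiveCloud("frustum", c(r1 = 0.5, r2 = 0.3, height = 1),
                           density = 1000, seed = 7)
  expect_equal(fr@truthSolidVolume, pi * 1 * (0.25 + 0.15 + 0.09) / 3)

  again <- makePrimitiveCloud("cube", c(edge = 1), density = 1000, seed = 7)
  expect_identical(coords(cube), coords(again))
  other <- makePrimitiveCloud("cube", c(edge = 1), density = 1000, seed = 8)
  expect_false(identical(coords(cube), coords(other)))

  expect_error(makePrimitiveCloud("cube", c(edge = -1)), "positive")
})

test_that("surface-only sampling stays on the boundary", {
  sph <- makePrimitiveCloud("sphere", c(radius = 0.5), density = 2000,
                            surface_only = TRUE, seed = 1)
  r <- sqrt(rowSums(coords(sph)^2))
  expect_equal(range(r), c(0.5, 0.5), tolerance = 1e-9)
})

test_that("spindle porosity accounting is analytic and voids are validated", {
  solid <- makeSpindleCanopy(seed = 1)
  expect_identical(solid@porosityFraction, 0)
  expect_equal(solid@truthSolidVolume, solid@truthEnvelopeVolume)

  # explicit spherical voids: porosity = sum of sphere volumes / envelope
  holes <- rbind(c(0, 0, 1.0, 0.1), c(0, 0, 1.6, 0.1))
  withHoles <- makeSpindleCanopy(porosity = list(holes = holes), seed = 1)
  expect_equal(withHoles@truthEnvelopeVolume - withHoles@truthSolidVolume,
               2 * 4 / 3 * pi * 0.1^3)

  # overlapping voids are rejected, keeping truth analytic
  bad <- rbind(c(0, 0, 1.0, 0.15), c(0, 0, 1.1, 0.15))
  expect_error(makeSpindleCanopy(porosity = list(holes = bad), seed = 1),
               "overlapping")
  # a void poking out of the envelope is rejected
  expect_error(makeSpindleCanopy(porosity = list(holes = rbind(c(0.5, 0, 3.3, 0.3))),
                                 seed = 1), "outside")

  # the porosity preset hits its target fraction analytically
  for (f in c(0.2, 0.4)) {
    can <- makeSpindleCanopy(porosity = spindlePorosity(f), seed = 2)
    expect_equal(can@porosityFraction, f, tolerance = 1e-6)
  }
})

test_that("sector-void volume agrees with a Monte Carlo integration oracle", {
  can <- makeSpindleCanopy(porosity = list(sectors = list(c(1.0, 1.5, 1))),
                           seed = 3)
  voidVol <- can@truthEnvelopeVolume - can@truthSolidVolume
  # MC oracle: fraction of a bounding box inside the sector void region
  set.seed(30)
  g <- can@geometry
  rmax <- g$base_radius * (1 + g$lobe_amp + g$dent_amp)
  n <- 400000
  x <- runif(n, -rmax, rmax); y <- runif(n, -rmax, rmax); z <- runif(n, 1.0, 1.5)
  th <- atan2(y, x)
  rl <- canopyEV:::.lobedRadius(z, th, g$height, g$base_radius, g$lobe_amp,
                                g$lobe_n, g$dent_amp, g$dent_n)
  inside <- sqrt(x^2 + y^2) <= rl & y > 0
  mc <- mean(inside) * (2 * rmax)^2 * 0.5
  expect_equal(voidVol, mc, tolerance = 0.02)
})

test_that("points never fall inside declared voids (before sensor noise)", {
  can <- makeSpindleCanopy(porosity = spindlePorosity(0.4), jitter_sd = 0,
                           seed = 4)
  m <- coords(can)
  expect_false(any(canopyEV:::.insideVoid(m, can@geometry$voids)))
})

test_that("the orchard generator labels every point and respects its knobs", {
  orch <- makeOrchard(seed = 1)
  expect_length(orch@labels, nPoints(orch))
  expect_equal(length(unique(stats::na.omit(orch@treeId))), 15L)
  expect_equal(length(unique(stats::na.omit(orch@rowId))), 3L)
  expect_gt(sum(orch@labels == "ground"), 0)
  expect_gt(sum(orch@labels == "noise"), 0)
  # bit-identical under the same seed
  expect_identical(coords(makeOrchard(seed = 1)), coords(orch))

  quiet <- makeOrchard(n_rows = 1, trees_per_row = 2, noise_rate = 0, seed = 2)
  expect_equal(sum(quiet@labels == "noise"), 0L)
  bare <- makeOrchard(n_rows = 1, trees_per_row = 2, ground = "none", seed = 2)
  expect_equal(sum(bare@labels == "ground"), 0L)
})

test_that("the virtual projection instrument matches the three-section model", {
  solid <- makeSpindleCanopy(seed = 5, density = 2000)
  ref <- referenceMeasurement(solid)
  g <- solid@geometry
  h3 <- g$height / 3
  r <- c(1, 0.8, 0.55, 0) * g$base_radius
  frustum <- function(r1, r2) pi * h3 * (r1^2 + r1 * r2 + r2^2) / 3
  expect_equal(ref$three_section_volume,
               frustum(r[1], r[2]) + frustum(r[2], r[3]) + frustum(r[3], r[4]))
  # a fully solid canopy shades nearly its whole silhouette in every view
  expect_true(all(ref$coefficients > 0.97))
  expect_lte(ref$effective_volume, ref$three_section_volume * 1.0000001)

  # a sector gap opens the side views but barely touches the top view
  porous <- makeSpindleCanopy(porosity = list(sectors = list(c(0.8, 1.6, 1))),
                              seed = 5, density = 2000)
  ref2 <- referenceMeasurement(porous)
  expect_lt(ref2$coefficients[["yoz"]], 0.93)
  expect_gt(ref2$coefficients[["xoy"]], 0.95)
  expect_lt(ref2$effective_volume, ref$effective_volume)
})
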