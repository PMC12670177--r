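# Brute-force oracles and hand-built fixtures shared across the test files.
# Every oracle here is deliberately O(n^2) / enumeration so it stays
# independent of the KD-tree and geometry code paths it checks.

# exact mean nearest-neighbour distance by all-pairs distances
bruteMeanNN <- function(m) {
  d <- as.matrix(stats::dist(m))
  diag(d) <- Inf
  mean(apply(d, 1, min))
}

# radius-outlier-removal keep set by all-pairs neighbour counting
bruteRORKeep <- function(m, radius, min_neighbors) {
  d <- as.matrix(stats::dist(m))
  diag(d) <- Inf
  unname(which(rowSums(d <= radius) >= min_neighbors))
}

# occupied-cell set under half-open binning from the min corner
bruteBinCells <- function(m, cell) {
  idx <- floor(sweep(m, 2, apply(m, 2, min)) / cell)
  unique(idx)
}

# closed unit cube mesh: 8 vertices, 12 outward-oriented triangles
cubeMesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
             c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  tri <- rbind(c(1, 3, 2), c(1, 4, 3),        # bottom, normal -z
               c(5, 6, 7), c(5, 7, 8),        # top, +z
               c(1, 2, 6), c(1, 6, 5),        # front, -y
               c(3, 4, 8), c(3, 8, 7),        # back, +y
               c(1, 5, 8), c(1, 8, 4),        # left, -x
               c(2, 3, 7), c(2, 7, 6))        # right, +x
  new("CanopyMesh", vertices = v, triangles = tri,
      alphaUsed = Inf, itersUsed = 0L, volume = 1, hullFallback = FALSE)
}

# regular-corner tetrahedron (0,0,0),(1,0,0),(0,1,0),(0,0,1); volume 1/6
tetraMesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  tri <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
  new("CanopyMesh", vertices = v, triangles = tri,
      alphaUsed = Inf, itersUsed = 0L, volume = 1 / 6, hullFallback = FALSE)
}

# seeded sphere cloud with points on and inside the surface, ~n total
sphereCloud <- function(r = 0.5, n = 2000, seed = 1) {
  vol <- 4 / 3 * pi * r^3
  s1 <- makePrimitiveCloud("sphere", c(radius = r), density = n / 2 / vol,
                           surface_only = TRUE, seed = seed)
  s2 <- makePrimitiveCloud("sphere", c(radius = r), density = n / 2 / vol,
                           surface_only = FALSE, seed = seed + 1L)
  pointCloud(rbind(coords(s1), coords(s2)))
}

# height profile built directly from a max-z vector (bin width 1, x0 = 0)
profileFromZ <- function(z, bin_width = 1) {
  list(bin_width = bin_width,
       bin_centers = (seq_along(z) - 0.5) * bin_width,
       max_z = z, x0 = 0)
}
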