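# Synthetic orchard and canopy generator with closed-form ground truth.
#
# The canopy envelope follows the tall-spindle habit: narrower at the top,
# broader at the base, modelled as two stacked frusta plus a cone of equal
# heights (the same three-section model used for manual canopy measurement),
# with an optional lobed cross-section emulating the surface concavity
# between scaffold branches. Porosity enters as non-overlapping interior
# spherical voids and/or full horizontal slab gaps, both with closed-form
# volumes, so every generated cloud carries an analytic solid volume.

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

.frustumVolume <- function(r1, r2, h) pi * h * (r1^2 + r1 * r2 + r2^2) / 3

# radius profile of the three-section spindle at heights z (vector), for a
# base radius r0: r0 at the base, 0.8 r0 and 0.55 r0 at the section joints,
# 0 at the apex.
.spindleRadius <- function(z, height, base_radius) {
  h3 <- height / 3
  r <- c(1, 0.8, 0.55, 0) * base_radius
  out <- numeric(length(z))
  seg <- pmin(pmax(floor(z / h3), 0), 2) + 1
  frac <- (z - (seg - 1) * h3) / h3
  out <- r[seg] * (1 - frac) + r[seg + 1] * frac
  out[z < 0 | z > height] <- 0
  out
}

.spindleEnvelopeVolume <- function(height, base_radius, lobe_amp = 0,
                                   dent_amp = 0) {
  h3 <- height / 3
  r <- c(1, 0.8, 0.55) * base_radius
  v <- .frustumVolume(r[1], r[2], h3) + .frustumVolume(r[2], r[3], h3) +
    .frustumVolume(r[3], 0, h3)                    # cone as a frustum to 0
  # exact for r (1 + a cos m.theta + b cos k.theta), distinct harmonics
  v * (1 + lobe_amp^2 / 2 + dent_amp^2 / 2)
}

# analytic volume of the envelope between z = a and z = b (for slab voids)
.spindleBandVolume <- function(a, b, height, base_radius, lobe_amp = 0,
                               dent_amp = 0) {
  f <- function(z) pi * .spindleRadius(z, height, base_radius)^2
  # piecewise quadratic integrand: integrate each linear segment exactly
  h3 <- height / 3
  cuts <- sort(unique(pmin(pmax(c(a, b, h3 * 0:3), a), b)))
  tot <- 0
  for (i in seq_len(length(cuts) - 1)) {
    lo <- cuts[i]; hi <- cuts[i + 1]
    if (hi <= lo) next
    # Simpson is exact for quadratics
    tot <- tot + (hi - lo) / 6 * (f(lo) + 4 * f((lo + hi) / 2) + f(hi))
  }
  tot * (1 + lobe_amp^2 / 2 + dent_amp^2 / 2)
}

# Local envelope radius at (z, theta):
#   r(z) * (1 + a cos(m theta) + b cos(k theta)),
# where the m-harmonic models the broad lobes between scaffold branches and
# the k-harmonic the deep, narrow corrugation between individual branches.
# Harmonic phases are fixed at zero (no twist along z): all cross terms then
# integrate to zero over any half circle, so the volume of a half-space
# sector of the envelope is exactly half the full band volume and sector
# voids stay closed-form.
.lobedRadius <- function(z, theta, height, base_radius, lobe_amp, lobe_n,
                         dent_amp = 0, dent_n = 12) {
  .spindleRadius(z, height, base_radius) *
    (1 + lobe_amp * cos(lobe_n * theta) + dent_amp * cos(dent_n * theta))
}

.insideVoid <- function(pts, voids) {
  inside <- rep(FALSE, nrow(pts))
  for (v in voids$spheres) {
    d2 <- (pts[, 1] - v[1])^2 + (pts[, 2] - v[2])^2 + (pts[, 3] - v[3])^2
    inside <- inside | d2 <= v[4]^2
  }
  for (s in voids$slabs) inside <- inside | (pts[, 3] >= s[1] & pts[, 3] < s[2])
  # sector voids: horizontal band restricted to one y half-space
  for (s in voids$sectors)
    inside <- inside |
      (pts[, 3] >= s[1] & pts[, 3] < s[2] & s[3] * pts[, 2] > 0)
  inside
}

# Sample nEnv material candidate points in the spindle envelope centered at
# (cx, cy), base at z = 0 (surface_frac of them biased into the outer
# shell), then remove candidates falling inside voids and add sensor noise.
# The candidate stream does not depend on the void specification, so under
# one seed the clouds of increasingly porous canopies are nested subsets of
# one another -- porosity comparisons are then driven by the voids, not by
# sampling noise.
.sampleSpindle <- function(nEnv, height, base_radius, lobe_amp, lobe_n, voids,
                           cx = 0, cy = 0, surface_frac = 0.7,
                           shell = 0.12, jitter_sd = 0.02,
                           dent_amp = 0, dent_n = 12) {
  rmax <- base_radius * (1 + lobe_amp + dent_amp)
  nSurf <- round(nEnv * surface_frac)
  nInt <- nEnv - nSurf
  acc <- matrix(numeric(0), 0, 3)
  # interior: uniform rejection inside the envelope
  while (nrow(acc) < nInt) {
    k <- max(256L, 2L * (nInt - nrow(acc)))
    z <- stats::runif(k, 0, height)
    x <- stats::runif(k, -rmax, rmax)
    y <- stats::runif(k, -rmax, rmax)
    th <- atan2(y, x)
    rl <- .lobedRadius(z, th, height, base_radius, lobe_amp, lobe_n,
                       dent_amp, dent_n)
    ok <- sqrt(x^2 + y^2) <= rl
    acc <- rbind(acc, cbind(x, y, z)[ok, , drop = FALSE])
  }
  acc <- acc[seq_len(nInt), , drop = FALSE]
  # shell: z weighted by local radius (surface area density), radius pushed
  # into the outer band of width `shell`
  accS <- matrix(numeric(0), 0, 3)
  while (nrow(accS) < nSurf) {
    k <- max(256L, 2L * (nSurf - nrow(accS)))
    z <- stats::runif(k, 0, height)
    wz <- .spindleRadius(z, height, base_radius) / base_radius
    keepZ <- stats::runif(k) < wz
    z <- z[keepZ]
    if (length(z) == 0) next
    th <- stats::runif(length(z), 0, 2 * pi)
    rl <- .lobedRadius(z, th, height, base_radius, lobe_amp, lobe_n,
                       dent_amp, dent_n)
    rr <- pmax(rl - shell * stats::runif(length(z)), 0)
    accS <- rbind(accS, cbind(rr * cos(th), rr * sin(th), z))
  }
  accS <- accS[seq_len(nSurf), , drop = FALSE]
  pts <- rbind(acc, accS)
  pts <- pts[!.insideVoid(pts, voids), , drop = FALSE]
  if (jitter_sd > 0)
    pts <- pts + matrix(stats::rnorm(length(pts), 0, jitter_sd), nrow(pts), 3)
  pts[, 1] <- pts[, 1] + cx
  pts[, 2] <- pts[, 2] + cy
  pts
}

#' Generate a primitive point cloud with analytic volume
#'
#' Seeded uniform sampling of a cube, sphere, cylinder or frustum, either
#' filling the solid or covering only its surface. Ground-truth volumes are
#' closed-form.
#'
#' @param shape "cube", "sphere", "cylinder" or "frustum"
#' @param dims named numeric: cube \code{edge} (or lx, ly, lz); sphere
#'   \code{radius}; cylinder \code{radius, height}; frustum
#'   \code{r1, r2, height}
#' @param density points per cubic meter of solid volume
#' @param surface_only place points on the boundary surface instead of the
#'   interior (same total count)
#' @param seed RNG seed; identical seed and parameters give a bit-identical
#'   cloud
#' @param jitter_sd per-coordinate Gaussian noise (meters), default none
#' @return a \linkS4class{SyntheticCanopy}
#' @examples
#' cube <- makePrimitiveCloud("cube", c(edge = 1), density = 2000, seed = 7)
#' cube@truthSolidVolume   # 1
#' @export
makePrimitiveCloud <- function(shape = c("cube", "sphere", "cylinder", "frustum"),
                               dims, density = 5000, surface_only = FALSE,
                               seed = 1, jitter_sd = 0) {
  shape <- match.arg(shape)
  dims <- as.list(dims)
  if (any(unlist(dims) <= 0)) stop("all dimensions must be positive")
  if (density <= 0) stop("density must be positive")
  vol <- switch(shape,
    cube = if (!is.null(dims$edge)) dims$edge^3 else dims$lx * dims$ly * dims$lz,
    sphere = 4 / 3 * pi * dims$radius^3,
    cylinder = pi * dims$radius^2 * dims$height,
    frustum = .frustumVolume(dims$r1, dims$r2, dims$height))
  n <- max(64L, as.integer(round(density * vol)))
  pts <- .withSeed(seed, {
    p <- switch(shape,
      cube = {
        e <- if (!is.null(dims$edge)) rep(dims$edge, 3) else
          c(dims$lx, dims$ly, dims$lz)
        if (surface_only) {
          # pick a face proportional to its area, then uniform on it
          areas <- c(e[2] * e[3], e[2] * e[3], e[1] * e[3], e[1] * e[3],
                     e[1] * e[2], e[1] * e[2])
          f <- sample.int(6, n, replace = TRUE, prob = areas)
          u <- stats::runif(n); v <- stats::runif(n)
          out <- matrix(0, n, 3)
          out[f == 1, ] <- cbind(0, u[f == 1] * e[2], v[f == 1] * e[3])
          out[f == 2, ] <- cbind(e[1], u[f == 2] * e[2], v[f == 2] * e[3])
          out[f == 3, ] <- cbind(u[f == 3] * e[1], 0, v[f == 3] * e[3])
          out[f == 4, ] <- cbind(u[f == 4] * e[1], e[2], v[f == 4] * e[3])
          out[f == 5, ] <- cbind(u[f == 5] * e[1], v[f == 5] * e[2], 0)
          out[f == 6, ] <- cbind(u[f == 6] * e[1], v[f == 6] * e[2], e[3])
          out
        } else cbind(stats::runif(n, 0, e[1]), stats::runif(n, 0, e[2]),
                     stats::runif(n, 0, e[3]))
      },
      sphere = {
        r <- dims$radius
        v <- matrix(stats::rnorm(3 * n), n, 3)
        v <- v / sqrt(rowSums(v^2))
        rad <- if (surface_only) rep(r, n) else r * stats::runif(n)^(1 / 3)
        v * rad
      },
      cylinder = {
        r <- dims$radius; h <- dims$height
        th <- stats::runif(n, 0, 2 * pi)
        if (surface_only) {
          sideA <- 2 * pi * r * h; capA <- pi * r^2
          f <- sample.int(3, n, replace = TRUE, prob = c(sideA, capA, capA))
          rad <- ifelse(f == 1, r, r * sqrt(stats::runif(n)))
          z <- ifelse(f == 1, stats::runif(n, 0, h), ifelse(f == 2, 0, h))
          cbind(rad * cos(th), rad * sin(th), z)
        } else {
          rad <- r * sqrt(stats::runif(n))
          cbind(rad * cos(th), rad * sin(th), stats::runif(n, 0, h))
        }
      },
      frustum = {
        r1 <- dims$r1; r2 <- dims$r2; h <- dims$height
        # z density proportional to cross-section area for uniform fill
        acc <- matrix(numeric(0), 0, 3)
        rmax <- max(r1, r2)
        while (nrow(acc) < n) {
          k <- max(256L, 2L * (n - nrow(acc)))
          z <- stats::runif(k, 0, h)
          rz <- r1 + (r2 - r1) * z / h
          if (surface_only) {
            th <- stats::runif(k, 0, 2 * pi)
            acc <- rbind(acc, cbind(rz * cos(th), rz * sin(th), z))
          } else {
            x <- stats::runif(k, -rmax, rmax); y <- stats::runif(k, -rmax, rmax)
            ok <- x^2 + y^2 <= rz^2
            acc <- rbind(acc, cbind(x, y, z)[ok, , drop = FALSE])
          }
        }
        acc[seq_len(n), , drop = FALSE]
      })
    if (jitter_sd > 0)
      p <- p + matrix(stats::rnorm(length(p), 0, jitter_sd), nrow(p), 3)
    p
  })
  new("SyntheticCanopy", cloud = pointCloud(pts),
      labels = rep("canopy", nrow(pts)),
      treeId = rep(1L, nrow(pts)), rowId = rep(1L, nrow(pts)),
      truthSolidVolume = vol, truthEnvelopeVolume = vol,
      porosityFraction = 0,
      geometry = list(shape = shape, dims = dims, density = density,
                      surface_only = surface_only, seed = seed,
                      jitter_sd = jitter_sd))
}

#' Generate a tall-spindle canopy with controlled porosity
#'
#' The envelope is the three-section spindle (two frusta plus a cone of
#' equal heights) with base radius \code{base_radius}, optionally with a
#' lobed cross-section emulating scaffold-branch concavity. Porosity is
#' introduced as non-overlapping interior spherical voids and/or full
#' horizontal slab gaps; both have closed-form volumes, so
#' \code{truthSolidVolume} is analytic. Spheres overlapping each other, a
#' slab, or the envelope surface are rejected with an error rather than
#' union-volume-computed.
#'
#' @param height canopy height in meters
#' @param base_radius envelope radius at the base (m)
#' @param porosity either NULL (solid), or a list with any of
#'   \code{n_holes}, \code{hole_radius} (spherical voids, placed by the
#'   seeded generator), \code{holes} (explicit 4-column matrix x, y, z, r),
#'   \code{slabs} (list of c(z_lo, z_hi) full horizontal gaps), and
#'   \code{sectors} (list of c(z_lo, z_hi, side) horizontal gaps covering
#'   one y half-space; side is +1 or -1)
#' @param density points per cubic meter of solid material
#' @param surface_frac fraction of points biased into the outer shell,
#'   emulating LiDAR's surface bias
#' @param lobe_amp,lobe_n amplitude and count of the broad cross-section
#'   lobes (scaffold branches)
#' @param dent_amp,dent_n amplitude and count of the narrow surface
#'   corrugation between individual branches
#' @param jitter_sd Gaussian sensor noise per coordinate (m); the default
#'   matches a typical terrestrial LiDAR range accuracy of 2 cm
#' @param seed RNG seed
#' @return a \linkS4class{SyntheticCanopy}
#' @export
makeSpindleCanopy <- function(height = 3.5, base_radius = 0.6,
                              porosity = NULL, density = 6000,
                              surface_frac = 0.7, lobe_amp = 0.15,
                              lobe_n = 5, dent_amp = 0.28, dent_n = 14,
                              jitter_sd = 0.02, seed = 1) {
  stopifnot(height > 0, base_radius > 0, density > 0,
            surface_frac >= 0, surface_frac <= 1,
            lobe_amp + dent_amp < 1)
  envVol <- .spindleEnvelopeVolume(height, base_radius, lobe_amp, dent_amp)
  voids <- .withSeed(seed + 1L,
    .resolveVoids(porosity, height, base_radius, lobe_amp + dent_amp))
  voidVol <- 0
  for (v in voids$spheres) voidVol <- voidVol + 4 / 3 * pi * v[4]^3
  for (s in voids$slabs)
    voidVol <- voidVol + .spindleBandVolume(s[1], s[2], height, base_radius,
                                            lobe_amp, dent_amp)
  for (s in voids$sectors)
    voidVol <- voidVol + .spindleBandVolume(s[1], s[2], height, base_radius,
                                            lobe_amp, dent_amp) / 2
  solidVol <- envVol - voidVol
  if (solidVol <= 0) stop("voids exceed the envelope volume")
  nEnv <- max(200L, as.integer(round(density * envVol)))
  pts <- .withSeed(seed,
    .sampleSpindle(nEnv, height, base_radius, lobe_amp, lobe_n, voids,
                   surface_frac = surface_frac, jitter_sd = jitter_sd,
                   dent_amp = dent_amp, dent_n = dent_n))
  new("SyntheticCanopy", cloud = pointCloud(pts),
      labels = rep("canopy", nrow(pts)),
      treeId = rep(1L, nrow(pts)), rowId = rep(1L, nrow(pts)),
      truthSolidVolume = solidVol, truthEnvelopeVolume = envVol,
      porosityFraction = 1 - solidVol / envVol,
      geometry = list(kind = "spindle", height = height,
                      base_radius = base_radius, lobe_amp = lobe_amp,
                      lobe_n = lobe_n, dent_amp = dent_amp, dent_n = dent_n,
                      voids = voids, density = density,
                      surface_frac = surface_frac, jitter_sd = jitter_sd,
                      seed = seed,
                      three_section_volume =
                        .spindleEnvelopeVolume(height, base_radius, 0)))
}

# turn a porosity spec into concrete non-overlapping voids; spheres are
# placed by rejection inside the eroded envelope, away from slabs
.resolveVoids <- function(porosity, height, base_radius, lobe_amp) {
  voids <- list(spheres = list(), slabs = list(), sectors = list())
  if (is.null(porosity)) return(voids)
  if (!is.null(porosity$slabs))
    for (s in porosity$slabs) {
      s <- sort(as.numeric(s[1:2]))
      if (s[1] < 0 || s[2] > height) stop("slab void outside the envelope")
      voids$slabs <- c(voids$slabs, list(s))
    }
  if (!is.null(porosity$sectors))
    for (s in porosity$sectors) {
      if (length(s) != 3 || !s[3] %in% c(-1, 1))
        stop("a sector void is c(z_lo, z_hi, side) with side +1 or -1")
      if (s[1] < 0 || s[2] > height || s[2] <= s[1])
        stop("sector void outside the envelope")
      voids$sectors <- c(voids$sectors, list(as.numeric(s)))
    }
  holes <- list()
  if (!is.null(porosity$holes)) {
    hm <- as.matrix(porosity$holes)
    for (i in seq_len(nrow(hm))) holes <- c(holes, list(hm[i, 1:4]))
  }
  nH <- porosity$n_holes
  if (!is.null(nH) && nH > 0) {
    rh <- porosity$hole_radius
    if (is.null(rh) || rh <= 0) stop("hole_radius must be given with n_holes")
    margin <- 0.05
    tries <- 0L
    while (length(holes) < nH + length(porosity$holes %||% integer(0)) &&
           tries < 20000L) {
      tries <- tries + 1L
      z <- stats::runif(1, rh + margin, height - rh - margin)
      # worst-case envelope radius over the sphere's z-range, lobe troughs
      zr <- c(z - rh, z, z + rh)
      rEnv <- min(.spindleRadius(zr, height, base_radius)) * (1 - lobe_amp)
      rAllow <- rEnv - rh - margin
      if (rAllow <= 0) next
      th <- stats::runif(1, 0, 2 * pi)
      rad <- rAllow * sqrt(stats::runif(1))
      cand <- c(rad * cos(th), rad * sin(th), z, rh)
      ok <- TRUE
      for (h in holes)
        if (sum((cand[1:3] - h[1:3])^2) < (cand[4] + h[4] + 0.02)^2) ok <- FALSE
      for (s in voids$slabs)
        if (cand[3] + rh > s[1] - 0.02 && cand[3] - rh < s[2] + 0.02) ok <- FALSE
      for (s in voids$sectors)
        if (cand[3] + rh > s[1] - 0.02 && cand[3] - rh < s[2] + 0.02 &&
            s[3] * cand[2] + rh > -0.02) ok <- FALSE
      if (ok) holes <- c(holes, list(cand))
    }
    if (length(holes) < nH)
      stop("could not place ", nH, " non-overlapping holes of radius ", rh,
           " inside the envelope; reduce n_holes or hole_radius")
  }
  # validate explicit holes: pairwise disjoint, inside envelope, off slabs
  if (length(holes) > 1) {
    for (i in seq_len(length(holes) - 1)) for (j in (i + 1):length(holes))
      if (sum((holes[[i]][1:3] - holes[[j]][1:3])^2) <
          (holes[[i]][4] + holes[[j]][4])^2)
        stop("overlapping spherical voids: ground truth would not be analytic")
  }
  for (h in holes) {
    zr <- c(h[3] - h[4], h[3], h[3] + h[4])
    rEnv <- min(.spindleRadius(zr, height, base_radius)) * (1 - lobe_amp)
    if (sqrt(h[1]^2 + h[2]^2) + h[4] > rEnv)
      stop("spherical void extends outside the envelope")
    for (s in voids$slabs)
      if (h[3] + h[4] > s[1] && h[3] - h[4] < s[2])
        stop("spherical void intersects a slab void")
    for (s in voids$sectors)
      if (h[3] + h[4] > s[1] && h[3] - h[4] < s[2] && s[3] * h[2] + h[4] > 0)
        stop("spherical void intersects a sector void")
  }
  voids$spheres <- holes
  voids
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Porosity specification targeting a given porosity fraction
#'
#' Convenience helper building a void specification for
#' \code{\link{makeSpindleCanopy}} whose analytic porosity is close to the
#' requested fraction: a fixed set of spherical voids supplies up to about
#' 0.18 of the envelope volume and a mid-height slab gap supplies the rest
#' (its width solved from the closed-form band volume).
#'
#' @param fraction target porosity in [0, 0.55)
#' @param height,base_radius,lobe_amp,dent_amp envelope parameters (must
#'   match the generator call)
#' @return a porosity list for \code{makeSpindleCanopy}, or NULL for 0
#' @export
spindlePorosity <- function(fraction, height = 3.5, base_radius = 0.6,
                            lobe_amp = 0.15, dent_amp = 0.28) {
  stopifnot(fraction >= 0, fraction < 0.55)
  if (fraction == 0) return(NULL)
  envVol <- .spindleEnvelopeVolume(height, base_radius, lobe_amp, dent_amp)
  rest <- fraction * envVol
  spec <- list()
  if (rest > 1e-9) {
    # two sector gaps (one per side) at fixed band centers; widths solved
    # from the closed-form band volume so specs for increasing fractions
    # are nested. The void volume is split between the two bands in
    # proportion to their capacity.
    zc <- c(0.33, 0.62) * height
    side <- c(1, -1)
    wmax <- pmin(2 * (zc - 0.03 * height), 2 * (0.97 * height - zc))
    half <- function(i, w)
      .spindleBandVolume(zc[i] - w / 2, zc[i] + w / 2, height, base_radius,
                         lobe_amp, dent_amp) / 2
    cap <- vapply(1:2, function(i) half(i, wmax[i]), 0)
    if (rest > 0.95 * sum(cap))
      stop("porosity fraction too large for the sector-void construction")
    target <- rest * cap / sum(cap)
    spec$sectors <- list()
    for (i in 1:2) {
      w <- stats::uniroot(function(w) half(i, w) - target[i],
                          c(1e-9, wmax[i]), tol = 1e-12)$root
      spec$sectors[[i]] <- c(zc[i] - w / 2, zc[i] + w / 2, side[i])
    }
  }
  spec
}

#' Generate a synthetic orchard scene
#'
#' Rows of fused spindle canopies (a "tree wall") over a ground surface,
#' with optional uniform noise. Default geometry follows standard
#' tall-spindle planting: 3.5 m row spacing, 1.0 m plant spacing, ~3.5 m
#' tree height. Every point carries a class label and, for canopy points,
#' its generating tree and row, which downstream segmentation is scored
#' against.
#'
#' @param n_rows,trees_per_row orchard layout
#' @param crown_base height of the foliage base above the ground (m); the
#'   trunk below it carries no points
#' @param row_spacing,plant_spacing,tree_height planting geometry (m)
#' @param base_radius canopy base radius (m); the default 0.45 m with the
#'   corrugation crests gives canopy diameters around 1.3 m and fused tree
#'   walls at 1 m plant spacing
#' @param ground "flat", "undulating" (0.1 m amplitude) or "tilted" (5
#'   percent slope), or "none"
#' @param ground_density ground points per square meter
#' @param noise_rate noise points as a fraction of canopy points
#' @param height_jitter relative tree-height variation
#' @param density canopy points per cubic meter of solid material
#' @param seed RNG seed
#' @return a \linkS4class{SyntheticCanopy} (truth volumes are NA: fused
#'   neighbouring canopies overlap, so per-scene volume is not closed-form;
#'   the labels are the ground truth)
#' @export
makeOrchard <- function(n_rows = 3, trees_per_row = 5, row_spacing = 3.5,
                        plant_spacing = 1.0, tree_height = 3.5,
                        base_radius = 0.45, crown_base = 0.6,
                        ground = "flat", ground_density = 400,
                        noise_rate = 0.002, height_jitter = 0.04,
                        density = 4000, seed = 1) {
  stopifnot(n_rows >= 1, trees_per_row >= 1, row_spacing > 0, plant_spacing > 0)
  .withSeed(seed, {
    pts <- list(); tree <- list(); row <- list()
    tid <- 0L
    for (r in seq_len(n_rows)) {
      for (t in seq_len(trees_per_row)) {
        tid <- tid + 1L
        h <- tree_height * (1 + stats::runif(1, -height_jitter, height_jitter))
        hc <- h - crown_base              # foliage spans crown_base..h
        envVol <- .spindleEnvelopeVolume(hc, base_radius, 0.15, 0.28)
        n <- max(200L, as.integer(round(density * envVol)))
        p <- .sampleSpindle(n, hc, base_radius, lobe_amp = 0.15, lobe_n = 5,
                            voids = list(spheres = list(), slabs = list(),
                                         sectors = list()),
                            cx = (t - 1) * plant_spacing,
                            cy = (r - 1) * row_spacing,
                            surface_frac = 0.7, jitter_sd = 0.02,
                            dent_amp = 0.28, dent_n = 14)
        p[, 3] <- p[, 3] + crown_base
        pts[[tid]] <- p
        tree[[tid]] <- rep(tid, nrow(p))
        row[[tid]] <- rep(r, nrow(p))
      }
    }
    canopy <- do.call(rbind, pts)
    treeId <- unlist(tree); rowId <- unlist(row)
    labels <- rep("canopy", nrow(canopy))
    xr <- range(canopy[, 1]) + c(-1, 1)
    yr <- range(canopy[, 2]) + c(-1, 1)
    if (!identical(ground, "none")) {
      ng <- as.integer(ground_density * diff(xr) * diff(yr))
      gx <- stats::runif(ng, xr[1], xr[2])
      gy <- stats::runif(ng, yr[1], yr[2])
      gz <- switch(ground,
        flat = rep(0, ng),
        undulating = 0.1 * sin(2 * pi * gx / 5) * cos(2 * pi * gy / 7),
        tilted = 0.05 * gx,
        stop("unknown ground type '", ground, "'"))
      gz <- gz + stats::rnorm(ng, 0, 0.01)
      canopy <- rbind(canopy, cbind(gx, gy, gz))
      labels <- c(labels, rep("ground", ng))
      treeId <- c(treeId, rep(NA_integer_, ng))
      rowId <- c(rowId, rep(NA_integer_, ng))
    }
    nn <- as.integer(round(noise_rate * sum(labels == "canopy")))
    if (nn > 0) {
      nx <- stats::runif(nn, xr[1], xr[2])
      ny <- stats::runif(nn, yr[1], yr[2])
      nz <- stats::runif(nn, 0, tree_height * 1.4)
      canopy <- rbind(canopy, cbind(nx, ny, nz))
      labels <- c(labels, rep("noise", nn))
      treeId <- c(treeId, rep(NA_integer_, nn))
      rowId <- c(rowId, rep(NA_integer_, nn))
    }
    new("SyntheticCanopy", cloud = pointCloud(canopy), labels = labels,
        treeId = as.integer(treeId), rowId = as.integer(rowId),
        truthSolidVolume = NA_real_, truthEnvelopeVolume = NA_real_,
        porosityFraction = NA_real_,
        geometry = list(kind = "orchard", n_rows = n_rows,
                        trees_per_row = trees_per_row,
                        row_spacing = row_spacing,
                        plant_spacing = plant_spacing,
                        tree_height = tree_height, base_radius = base_radius,
                        crown_base = crown_base, ground = ground,
                        seed = seed))
  })
}

#' Virtual projection-based reference measurement
#'
#' Computational analogue of the laboratory reference procedure for canopy
#' effective volume: the canopy volume is the three-section model (two
#' frusta plus a cone of equal heights), and each orthogonal direction's
#' effective coefficient is the shaded fraction of the silhouette in an
#' orthographic binary rendering of the solid geometry. The product of the
#' three coefficients times the three-section volume is the reference
#' effective volume. Orthographic rays avoid the divergent-light inflation
#' of a physical point-source rig, so this virtual instrument is unbiased.
#'
#' @param canopy a spindle \linkS4class{SyntheticCanopy} (geometry known)
#' @param projection_resolution pixel size of the orthographic rendering (m)
#' @param ray_samples samples along each ray
#' @return list with \code{three_section_volume}, \code{coefficients} (xoy,
#'   xoz, yoz), \code{effective_volume}
#' @export
referenceMeasurement <- function(canopy, projection_resolution = 0.02,
                                 ray_samples = 48) {
  g <- canopy@geometry
  if (is.null(g$kind) || g$kind != "spindle")
    stop("reference measurement needs a single spindle canopy with known geometry")
  h <- g$height; r0 <- g$base_radius
  rmax <- r0 * (1 + g$lobe_amp)
  da <- g$dent_amp %||% 0; dn <- g$dent_n %||% 12
  solidAt <- function(x, y, z) {
    th <- atan2(y, x)
    rl <- .lobedRadius(z, th, h, r0, g$lobe_amp, g$lobe_n, da, dn)
    inside <- sqrt(x^2 + y^2) <= rl & z >= 0 & z <= h
    inside & !.insideVoid(cbind(x, y, z), g$voids)
  }
  envAt <- function(x, y, z) {
    th <- atan2(y, x)
    sqrt(x^2 + y^2) <= .lobedRadius(z, th, h, r0, g$lobe_amp, g$lobe_n, da, dn) &
      z >= 0 & z <= h
  }
  res <- projection_resolution
  coef <- c(xoy = NA_real_, xoz = NA_real_, yoz = NA_real_)
  for (pl in names(coef)) {
    if (pl == "xoy") {
      u <- seq(-rmax, rmax, by = res); v <- seq(-rmax, rmax, by = res)
      w <- seq(0, h, length.out = ray_samples)
    } else {
      u <- seq(-rmax, rmax, by = res); v <- seq(0, h, by = res)
      w <- seq(-rmax, rmax, length.out = ray_samples)
    }
    px <- as.matrix(expand.grid(u = u, v = v))
    shaded <- contour <- rep(FALSE, nrow(px))
    for (wk in w) {
      xyz <- switch(pl,
        xoy = cbind(px[, 1], px[, 2], wk),
        xoz = cbind(px[, 1], wk, px[, 2]),
        yoz = cbind(wk, px[, 1], px[, 2]))
      contour <- contour | envAt(xyz[, 1], xyz[, 2], xyz[, 3])
      shaded <- shaded | solidAt(xyz[, 1], xyz[, 2], xyz[, 3])
    }
    coef[pl] <- sum(shaded) / sum(contour)
  }
  v3 <- .spindleEnvelopeVolume(h, r0, 0)
  list(three_section_volume = v3, coefficients = coef,
       effective_volume = v3 * prod(coef))
}
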