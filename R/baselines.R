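# Reference canopy-volume estimators the effective-volume method is compared
# against: alpha-shape by slices (ASBS), convex hull by slices (CHBS), and
# voxel counting (VB), plus the volume reduction rate.

#' Alpha-shape-by-slices volume
#'
#' Splits the cloud's Z extent (inclusive of endpoints; a point at z_max
#' belongs to the top slice) into \code{n_slices} equal layers. Each layer
#' with at least 3 distinct points contributes its 2D alpha-shape area in
#' the (x, y) projection — using the same dynamic-alpha scheme as the
#' effective-volume module, with the layer's own projected d_avg — times
#' the layer thickness; layers with fewer points contribute zero.
#'
#' @param cloud a \linkS4class{PointCloud}
#' @param n_slices number of equal Z layers (default 10)
#' @return list: \code{method}, \code{volume} (m^3), \code{params}
#' @export
volumeASBS <- function(cloud, n_slices = 10) {
  .sliceVolume(cloud, n_slices, "ASBS")
}

#' Convex-hull-by-slices volume
#'
#' As \code{\link{volumeASBS}} but each layer contributes its 2D convex-hull
#' area; per-layer hull area always dominates the alpha-shape area, so
#' CHBS >= ASBS on any cloud at equal slicing.
#'
#' @inheritParams volumeASBS
#' @return list: \code{method}, \code{volume} (m^3), \code{params}
#' @export
volumeCHBS <- function(cloud, n_slices = 10) {
  .sliceVolume(cloud, n_slices, "CHBS")
}

.sliceVolume <- function(cloud, n_slices, method) {
  m <- coords(cloud)
  if (nrow(m) == 0L) stop("cannot slice an empty cloud")
  n_slices <- as.integer(n_slices)
  stopifnot(n_slices >= 1L)
  z0 <- min(m[, 3]); z1 <- max(m[, 3])
  h <- (z1 - z0) / n_slices
  if (h <= 0) stop("cloud has zero vertical extent; cannot slice")
  lay <- pmin(floor((m[, 3] - z0) / h), n_slices - 1L)
  vol <- 0; used <- 0L
  for (s in 0:(n_slices - 1L)) {
    p <- m[lay == s, 1:2, drop = FALSE]
    u <- unique(p)
    if (nrow(u) < 3L) next
    a <- if (method == "CHBS") .hullArea(u) else {
      ok <- tryCatch(.alphaComplex2D(u)$area, error = function(e) NA_real_)
      if (is.na(ok)) next else ok
    }
    if (a <= 0) next
    vol <- vol + a * h
    used <- used + 1L
  }
  if (used == 0L) stop("all layers degenerate; cannot estimate a volume")
  list(method = method, volume = vol,
       params = list(n_slices = n_slices, slice_height = h, layers_used = used))
}

.hullArea <- function(p) {
  h <- grDevices::chull(p)
  x <- p[h, 1]; y <- p[h, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Voxel-based volume
#'
#' Counts occupied 3D voxels (half-open binning from the minimum corner) and
#' multiplies by the voxel volume. With \code{voxel = "auto"} the voxel side
#' is 1/15 of the canopy diameter, taken as the larger of the x and y
#' bounding-box extents.
#'
#' @param cloud a \linkS4class{PointCloud}
#' @param voxel voxel side length in meters, or "auto"
#' @return list: \code{method}, \code{volume} (m^3), \code{params}
#' @export
volumeVB <- function(cloud, voxel = "auto") {
  m <- coords(cloud)
  if (nrow(m) == 0L) stop("cannot voxelize an empty cloud")
  if (identical(voxel, "auto")) {
    diam <- max(diff(range(m[, 1])), diff(range(m[, 2])))
    if (diam <= 0) stop("cloud has zero horizontal extent; pass voxel explicitly")
    voxel <- diam / 15
  }
  if (!is.numeric(voxel) || voxel <= 0) stop("voxel size must be positive")
  idx <- floor(sweep(m, 2, apply(m, 2, min)) / voxel)
  nOcc <- nrow(unique(idx))
  list(method = "VB", volume = nOcc * voxel^3,
       params = list(voxel = voxel, occupied_voxels = nOcc))
}

#' Volume reduction rate
#'
#' VRR = (V_cm - V_EV) / V_cm: the relative reduction of the effective
#' volume against a comparison method's estimate.
#'
#' @param V_cm comparison-method volume (m^3, > 0)
#' @param V_EV effective volume (m^3)
#' @return list with \code{VRR}, \code{V_cm}, \code{V_EV}
#' @export
reductionRate <- function(V_cm, V_EV) {
  if (!is.numeric(V_cm) || V_cm <= 0) stop("V_cm must be positive")
  list(VRR = (V_cm - V_EV) / V_cm, V_cm = V_cm, V_EV = V_EV)
}
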