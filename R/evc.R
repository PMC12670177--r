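# Effective volume coefficient: each of the three orthogonal projections of
# the canopy cloud is voxelized, bounded by a 2D alpha-shape contour, and
# partitioned into blocks carrying a canopy-thickness weight; the plane
# effective coefficient is the thickness-weighted fraction of in-contour
# voxels that contain projected points. The product of the three plane
# coefficients is the EVC, and Ve = Vm x EVC.

.PLANES <- c("xoy", "xoz", "yoz")

#' Project a cloud onto an orthogonal plane
#'
#' Drops one axis while preserving the in-plane distribution: yoz keeps
#' (y, z) and records x per point; xoz keeps (x, z) and records y; xoy keeps
#' (x, y) and records z.
#'
#' @param cloud a \linkS4class{PointCloud}
#' @param plane "xoy", "xoz" or "yoz"
#' @return list with \code{points2d} (N x 2) and \code{dropped} (N values of
#'   the projection axis)
#' @export
projectCloud <- function(cloud, plane = c("xoy", "xoz", "yoz")) {
  plane <- match.arg(plane)
  m <- coords(cloud)
  if (nrow(m) == 0L) stop("cannot project an empty cloud")
  keep <- switch(plane, xoy = c(1L, 2L), xoz = c(1L, 3L), yoz = c(2L, 3L))
  drop <- switch(plane, xoy = 3L, xoz = 2L, yoz = 1L)
  list(points2d = m[, keep, drop = FALSE], dropped = m[, drop])
}

#' Voxelize a 2D projection
#'
#' Half-open binning from the 2D minimum corner: voxel (i, j) covers
#' [origin + i*VS, origin + (i+1)*VS) on each axis and is occupied when it
#' contains at least one projected point.
#'
#' @param points2d N x 2 matrix of projected points
#' @param VS voxel side length in meters (> 0)
#' @param plane label stored on the grid
#' @param dropped per-point dropped-axis values carried along for the
#'   partition weights
#' @return a \linkS4class{ProjectionGrid} with occupancy only (contour unset)
#' @export
voxelizeProjection <- function(points2d, VS, plane = "yoz",
                               dropped = numeric(0)) {
  if (!is.numeric(VS) || VS <= 0) stop("voxel size VS must be positive")
  p <- as.matrix(points2d)
  if (nrow(p) == 0L) stop("cannot voxelize an empty projection")
  origin <- c(min(p[, 1]), min(p[, 2]))
  i <- as.integer(floor((p[, 1] - origin[1]) / VS))
  j <- as.integer(floor((p[, 2] - origin[2]) / VS))
  nx <- max(i) + 1L; ny <- max(j) + 1L
  occ <- matrix(FALSE, nx, ny)
  occ[cbind(i + 1L, j + 1L)] <- TRUE
  new("ProjectionGrid", plane = plane, origin = origin, voxelSize = VS,
      dims = c(nx, ny), occupancy = occ,
      inContour = matrix(FALSE, nx, ny), points2d = p,
      dropped = as.numeric(dropped), contourArea = NA_real_)
}

#' Compute the 2D boundary contour and in-contour voxels
#'
#' Reconstructs the projected cloud's boundary with the same dynamic
#' alpha-shape scheme as the 3D reconstruction (alpha from 5 x d_avg of the
#' 2D points, grown by 0.5 x d_avg until the complex contains every point).
#' A voxel is in-contour when its center lies inside or on the complex;
#' occupied voxels are in-contour by construction (the contour encloses all
#' points), which is enforced explicitly to make the invariant robust to
#' center-on-edge rounding.
#'
#' @param grid a \linkS4class{ProjectionGrid} from
#'   \code{\link{voxelizeProjection}}
#' @param k2,step2 dynamic-alpha parameters of the 2D scheme
#' @return the grid with \code{inContour} and \code{contourArea} filled
#' @export
boundaryContour <- function(grid, k2 = 5, step2 = 0.5) {
  ac <- .alphaComplex2D(grid@points2d, k2 = k2, step2 = step2)
  cov <- cpp_cover_cells(ac$points, ac$triangles, grid@origin,
                         grid@voxelSize, grid@dims[1], grid@dims[2])
  inc <- matrix(cov, grid@dims[1], grid@dims[2]) | grid@occupancy
  # outer-contour semantics: voxels inside interior windows of the complex
  # (through-gaps in the canopy) are enclosed by the outer boundary polygon
  # and therefore count as in-contour -- they are the porosity signal
  grid@inContour <- inc | !.reachableFromBorder(!inc)
  grid@contourArea <- ac$area
  grid
}

# 4-connected flood fill over `open` cells starting from the matrix border;
# returns a logical matrix marking reachable open cells
.reachableFromBorder <- function(open) {
  nx <- nrow(open); ny <- ncol(open)
  reach <- matrix(FALSE, nx, ny)
  queue <- integer(2 * (nx + ny) + 8)
  qn <- 0L
  pushIf <- function(i, j) {
    if (i >= 1L && i <= nx && j >= 1L && j <= ny &&
        open[i, j] && !reach[i, j]) {
      reach[i, j] <<- TRUE
      qn <<- qn + 1L
      if (qn > length(queue)) queue <<- c(queue, integer(length(queue)))
      queue[qn] <<- (j - 1L) * nx + i
    }
  }
  for (i in seq_len(nx)) { pushIf(i, 1L); pushIf(i, ny) }
  for (j in seq_len(ny)) { pushIf(1L, j); pushIf(nx, j) }
  while (qn > 0L) {
    id <- queue[qn]; qn <- qn - 1L
    i <- (id - 1L) %% nx + 1L; j <- (id - 1L) %/% nx + 1L
    pushIf(i - 1L, j); pushIf(i + 1L, j); pushIf(i, j - 1L); pushIf(i, j + 1L)
  }
  reach
}

#' Partition a projection grid and compute thickness weights
#'
#' Partitions are aligned blocks of \code{partition_multiplier} x
#' \code{partition_multiplier} voxels (integer division of voxel indices, so
#' every voxel belongs to exactly one partition). For each partition holding
#' at least one projected point the weight is W = max - min of the
#' dropped-axis values of its points (the local canopy thickness along the
#' projection direction); nav counts its in-contour voxels, nev its occupied
#' in-contour voxels. Partitions whose points are coincident along the
#' dropped axis get W = 0 and are treated like point-free in-contour
#' partitions by the interpolation.
#'
#' @param grid a \linkS4class{ProjectionGrid} with the contour computed
#' @param partition_multiplier voxels per partition side (default 5)
#' @return a \linkS4class{PartitionGrid}
#' @export
partitionWeights <- function(grid, partition_multiplier = 5) {
  pm <- as.integer(partition_multiplier)
  stopifnot(pm >= 1L)
  nx <- grid@dims[1]; ny <- grid@dims[2]
  px <- (nx + pm - 1L) %/% pm; py <- (ny + pm - 1L) %/% pm
  vi <- (seq_len(nx) - 1L) %/% pm + 1L     # voxel col -> partition col
  vj <- (seq_len(ny) - 1L) %/% pm + 1L
  # per-partition voxel counts by aggregating the logical rasters
  groupSum <- function(mat) {
    t1 <- rowsum(mat + 0, vi, reorder = TRUE)
    t(rowsum(t(t1), vj, reorder = TRUE))
  }
  nav <- groupSum(grid@inContour)
  nev <- groupSum(grid@occupancy & grid@inContour)
  # point membership by partition
  p <- grid@points2d
  i <- pmin(floor((p[, 1] - grid@origin[1]) / grid@voxelSize), nx - 1L) %/% pm + 1L
  j <- pmin(floor((p[, 2] - grid@origin[2]) / grid@voxelSize), ny - 1L) %/% pm + 1L
  W <- matrix(0, px, py)
  if (length(grid@dropped) == nrow(p)) {
    id <- (j - 1L) * px + i
    mx <- tapply(grid@dropped, id, max)
    mn <- tapply(grid@dropped, id, min)
    W[as.integer(names(mx))] <- mx - mn
  } else if (nrow(p) > 0L && length(grid@dropped) > 0L) {
    stop("dropped-axis values do not match the projected points")
  }
  new("PartitionGrid", partitionMultiplier = pm,
      W = W, nev = storage_int(nev), nav = storage_int(nav),
      interpolationRounds = 0L)
}

storage_int <- function(m) { storage.mode(m) <- "integer"; m }

#' Fill zero-weight in-contour partitions by eight-neighbour averaging
#'
#' Every partition that lies (partly) inside the contour but has zero
#' thickness weight receives, simultaneously per round (Jacobi-style, so the
#' result does not depend on partition order), the arithmetic mean of its
#' non-zero eight-neighbours; out-of-contour partitions are excluded both as
#' targets and as sources. Rounds repeat until no zero-weight in-contour
#' partition remains; after as many rounds as there are partitions the
#' remaining zeros are unreachable and an error is raised.
#'
#' @param pgrid a \linkS4class{PartitionGrid}
#' @return the grid with positive weights on all in-contour partitions and
#'   \code{interpolationRounds} set
#' @export
interpolateZeroWeights <- function(pgrid) {
  W <- pgrid@W
  nav <- pgrid@nav
  px <- nrow(W); py <- ncol(W)
  inc <- nav > 0L
  rounds <- 0L
  maxRounds <- px * py
  repeat {
    todo <- which(inc & W == 0, arr.ind = TRUE)
    if (nrow(todo) == 0L) break
    if (rounds >= maxRounds)
      stop("zero-weight partitions cannot be interpolated: no connected ",
           "non-zero weights within the contour")
    newW <- W
    filled <- FALSE
    for (r in seq_len(nrow(todo))) {
      i <- todo[r, 1]; j <- todo[r, 2]
      ii <- max(1L, i - 1L):min(px, i + 1L)
      jj <- max(1L, j - 1L):min(py, j + 1L)
      nb <- W[ii, jj]
      ok <- inc[ii, jj] & nb > 0
      if (any(ok)) { newW[i, j] <- mean(nb[ok]); filled <- TRUE }
    }
    if (!filled)
      stop("zero-weight partitions cannot be interpolated: no path to any ",
           "non-zero weight inside the contour")
    W <- newW
    rounds <- rounds + 1L
  }
  pgrid@W <- W
  pgrid@interpolationRounds <- rounds
  pgrid
}

#' Plane effective coefficient
#'
#' EC = sum_i(W_i * nev_i) / sum_i(W_i * nav_i) over all partitions with
#' nav > 0: the thickness-weighted fraction of in-contour voxels that
#' contain projected points. Out-of-contour partitions contribute zero to
#' both sums.
#'
#' @param pgrid a \linkS4class{PartitionGrid} with interpolated weights
#' @return EC in (0, 1]
#' @export
planeEffectiveCoefficient <- function(pgrid) {
  sel <- pgrid@nav > 0L
  den <- sum(pgrid@W[sel] * pgrid@nav[sel])
  if (!any(sel) || den <= 0)
    stop("empty projection: no in-contour partitions with positive weight")
  sum(pgrid@W[sel] * pgrid@nev[sel]) / den
}

#' Effective volume of a canopy
#'
#' Runs the full effective-volume-coefficient computation over the three
#' orthogonal planes and multiplies the reconstructed mesh volume by the
#' resulting EVC. The voxel size for each plane is
#' \code{vs_multiplier x d_avg}; by default d_avg is the mean 3D
#' nearest-neighbour distance of the cloud (\code{vsSource = "cloud3d"}),
#' under which voxel occupancy saturates on dense solid material and drops
#' where the canopy is porous — mirroring the physical shadow-projection
#' instrument the coefficient emulates. \code{vsSource = "projected2d"} uses
#' each plane's own projected 2D d_avg instead.
#'
#' @param cloud the canopy \linkS4class{PointCloud} the mesh was built from
#' @param mesh the reconstructed \linkS4class{CanopyMesh} (or NULL to
#'   reconstruct internally with default parameters)
#' @param vs_multiplier voxel size multiplier (1.0 = d_avg)
#' @param partition_multiplier partition side in voxels (default 5)
#' @param vsSource "cloud3d" or "projected2d" (see Details)
#' @return an \linkS4class{EVResult}
#' @export
effectiveVolume <- function(cloud, mesh = NULL, vs_multiplier = 1.0,
                            partition_multiplier = 5,
                            vsSource = c("cloud3d", "projected2d")) {
  vsSource <- match.arg(vsSource)
  stopifnot(vs_multiplier > 0)
  if (is.null(mesh)) mesh <- reconstructCanopy(cloud)
  Vm <- mesh@volume
  d3 <- averageNNDistance(cloud, dims = 3)$d_avg
  EC <- stats::setNames(numeric(3), .PLANES)
  for (pl in .PLANES) {
    pr <- projectCloud(cloud, pl)
    VS <- if (vsSource == "cloud3d") vs_multiplier * d3
          else vs_multiplier * averageNNDistance(pr$points2d, dims = 2)$d_avg
    grid <- voxelizeProjection(pr$points2d, VS, plane = pl,
                               dropped = pr$dropped)
    grid <- boundaryContour(grid)
    pg <- partitionWeights(grid, partition_multiplier)
    pg <- interpolateZeroWeights(pg)
    EC[pl] <- planeEffectiveCoefficient(pg)
  }
  EVC <- prod(EC)
  new("EVResult", Vm = Vm, EC = EC, EVC = EVC, Ve = Vm * EVC,
      params = list(vs_multiplier = vs_multiplier,
                    partition_multiplier = partition_multiplier,
                    vsSource = vsSource, d_avg3d = d3,
                    alphaUsed = mesh@alphaUsed))
}
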