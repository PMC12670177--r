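# Four-step preprocessing of raw orchard scans: radius outlier removal,
# RANSAC plane leveling, ground filtering, and a second outlier-removal pass.

#' Radius outlier removal parameters
#'
#' @param radius neighbourhood search radius in meters
#' @param min_neighbors minimum number of *other* points required within
#'   \code{radius} for a point to be kept (the query point itself is not
#'   counted; the two readings of "neighbourhood size" differ by one)
#' @return validated parameter list
#' @export
rorParams <- function(radius = 0.2, min_neighbors = 20) {
  stopifnot(radius > 0, min_neighbors >= 0)
  list(radius = radius, min_neighbors = as.integer(min_neighbors))
}

#' Cloth-simulation ground-filter parameters
#'
#' Parameter container for cloth-simulation ground classification:
#' (bSloopSmooth, class_threshold, cloth_resolution, iterations, rigidity,
#' time_step) with defaults (FALSE, 0.3, 0.1, 500, 3, 0.65). The grid ground
#' filter shipped with this package consumes \code{class_threshold} and
#' \code{cloth_resolution}; the remaining entries parameterize the cloth
#' physics of an external backend.
#'
#' @param bSloopSmooth smooth cloth-node slopes (for terrain steeper than ~30 deg)
#' @param class_threshold max distance (m) from a point to the settled ground
#'   surface for the point to be labelled ground
#' @param cloth_resolution cloth/grid cell size in meters
#' @param iterations maximum settling iterations
#' @param rigidity integer cloth stiffness grade
#' @param time_step simulation time increment
#' @return validated parameter list
#' @export
csfParams <- function(bSloopSmooth = FALSE, class_threshold = 0.3,
                      cloth_resolution = 0.1, iterations = 500,
                      rigidity = 3, time_step = 0.65) {
  stopifnot(class_threshold > 0, cloth_resolution > 0, iterations >= 1)
  list(bSloopSmooth = isTRUE(bSloopSmooth), class_threshold = class_threshold,
       cloth_resolution = cloth_resolution, iterations = as.integer(iterations),
       rigidity = as.integer(rigidity), time_step = time_step)
}

#' Radius outlier removal
#'
#' Keeps a point iff at least \code{min_neighbors} other points lie within
#' Euclidean distance \code{radius}. All decisions are made against the
#' original cloud (single pass, non-cascading), so the result is
#' deterministic and independent of point order.
#'
#' @param cloud a \linkS4class{PointCloud}
#' @param params see \code{\link{rorParams}}
#' @return list with \code{kept} (PointCloud, possibly empty) and
#'   \code{removed_count}
#' @export
radiusOutlierRemoval <- function(cloud, params = rorParams()) {
  m <- coords(cloud)
  if (nrow(m) == 0L) stop("radius outlier removal needs a non-empty cloud")
  if (params$min_neighbors == 0L)
    return(list(kept = cloud, removed_count = 0L,
                kept_indices = seq_len(nrow(m))))
  k <- min(nrow(m), params$min_neighbors + 1L)  # +1: self-match
  nn <- RANN::nn2(m, k = k, searchtype = "radius", radius = params$radius)
  # nn.idx is 0 where no neighbour within radius; count excludes self
  nWithin <- rowSums(nn$nn.idx > 0L) - 1L
  keep <- nWithin >= params$min_neighbors
  list(kept = pointCloud(m[keep, , drop = FALSE], cloud@frameNote),
       removed_count = sum(!keep), kept_indices = which(keep))
}

#' Level a cloud to its ground plane
#'
#' Fits the dominant plane by RANSAC (inlier: |point-to-plane distance| <=
#' \code{ransac_dist}), orients the plane normal to have a positive Z
#' component, rotates the whole cloud by the minimal rotation taking that
#' normal to (0, 0, 1), and shifts the fitted plane to z = 0.
#'
#' @param cloud a \linkS4class{PointCloud} containing a dominant planar subset
#' @param ransac_dist inlier distance threshold in meters
#' @param ransac_iters number of RANSAC hypotheses
#' @param min_inlier_fraction below this inlier fraction the fit is rejected
#' @param seed RNG seed making the fit reproducible (the global RNG state is
#'   restored on exit)
#' @return list with \code{leveled} (PointCloud) and \code{result}: rotation
#'   (3x3), ground_normal_before, inlier_fraction, plane_z_offset
#' @export
levelToGround <- function(cloud, ransac_dist = 0.05, ransac_iters = 1000,
                          min_inlier_fraction = 0.05, seed = 42) {
  m <- coords(cloud)
  n <- nrow(m)
  if (n < 3L) stop("cannot fit a ground plane to fewer than 3 points")
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  best <- list(count = -1L)
  for (i in seq_len(ransac_iters)) {
    tri <- m[sample.int(n, 3L), , drop = FALSE]
    v1 <- tri[2, ] - tri[1, ]; v2 <- tri[3, ] - tri[1, ]
    nrm <- c(v1[2] * v2[3] - v1[3] * v2[2],
             v1[3] * v2[1] - v1[1] * v2[3],
             v1[1] * v2[2] - v1[2] * v2[1])
    len <- sqrt(sum(nrm^2))
    if (len < 1e-12) next
    nrm <- nrm / len
    d <- as.vector(m %*% nrm) - sum(nrm * tri[1, ])
    count <- sum(abs(d) <= ransac_dist)
    if (count > best$count) best <- list(count = count, normal = nrm, p0 = tri[1, ])
  }
  frac <- best$count / n
  if (frac < min_inlier_fraction)
    stop(sprintf("no ground plane found: best inlier fraction %.3f < %.3f",
                 frac, min_inlier_fraction))
  # refine on inliers via least squares (centroid + smallest eigenvector)
  d <- as.vector(m %*% best$normal) - sum(best$normal * best$p0)
  inl <- m[abs(d) <= ransac_dist, , drop = FALSE]
  ctr <- colMeans(inl)
  ev <- eigen(crossprod(sweep(inl, 2, ctr)), symmetric = TRUE)
  nrm <- ev$vectors[, 3]
  if (nrm[3] < 0) nrm <- -nrm
  # minimal rotation taking nrm to (0,0,1)
  R <- .rotationToZ(nrm)
  rot <- m %*% t(R)
  zoff <- sum(R[3, ] * ctr)
  rot[, 3] <- rot[, 3] - zoff
  list(leveled = pointCloud(rot, cloud@frameNote),
       result = list(rotation = R, ground_normal_before = nrm,
                     inlier_fraction = frac, plane_z_offset = zoff))
}

# Rodrigues rotation taking unit vector v to +Z.
.rotationToZ <- function(v) {
  z <- c(0, 0, 1)
  c_ <- sum(v * z)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(diag(c(1, -1, -1)))  # 180 deg about X
  axis <- c(v[2] * z[3] - v[3] * z[2], v[3] * z[1] - v[1] * z[3],
            v[1] * z[2] - v[2] * z[1])
  s <- sqrt(sum(axis^2)); axis <- axis / s
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + s * K + (1 - c_) * (K %*% K)
}

#' Separate ground from canopy points
#'
#' \code{method = "grid"} (the filter shipped with this package) estimates a
#' ground surface on a horizontal grid from low z-quantiles (empty cells are
#' filled from neighbouring cells) and labels as ground every point within
#' \code{class_threshold} of that surface. \code{method = "csf"} requests the
#' published cloth-simulation filter, which requires an external backend;
#' when none is installed an explicit error points at the grid filter.
#'
#' @param cloud a leveled \linkS4class{PointCloud}
#' @param params see \code{\link{csfParams}}
#' @param method "grid" or "csf"
#' @param cell grid cell size in meters for the grid filter
#' @return list with \code{offground} and \code{ground} PointClouds
#' @export
removeGround <- function(cloud, params = csfParams(),
                         method = c("grid", "csf"), cell = 0.5) {
  method <- match.arg(method)
  m <- coords(cloud)
  if (nrow(m) == 0L) stop("cannot filter ground from an empty cloud")
  if (method == "csf")
    stop("no cloth-simulation backend is installed; ",
         "use removeGround(..., method = \"grid\")")
  ix <- floor((m[, 1] - min(m[, 1])) / cell)
  iy <- floor((m[, 2] - min(m[, 2])) / cell)
  nx <- max(ix) + 1L; ny <- max(iy) + 1L
  cellId <- ix + nx * iy
  # ground elevation per cell: low quantile of z, robust to canopy points
  zfloor <- tapply(m[, 3], cellId, stats::quantile, probs = 0.02, names = FALSE)
  grid <- matrix(NA_real_, nx, ny)
  ids <- as.integer(names(zfloor))
  grid[cbind(ids %% nx + 1L, ids %/% nx + 1L)] <- zfloor
  # fill empty cells from available neighbours (expanding rings)
  if (anyNA(grid)) {
    for (pass in seq_len(max(nx, ny))) {
      nas <- which(is.na(grid), arr.ind = TRUE)
      if (nrow(nas) == 0L) break
      for (r in seq_len(nrow(nas))) {
        i <- nas[r, 1]; j <- nas[r, 2]
        ii <- max(1, i - 1):min(nx, i + 1); jj <- max(1, j - 1):min(ny, j + 1)
        v <- grid[ii, jj]
        if (any(!is.na(v))) grid[i, j] <- stats::median(v, na.rm = TRUE)
      }
    }
  }
  zg <- grid[cbind(ix + 1L, iy + 1L)]
  isGround <- (m[, 3] - zg) <= params$class_threshold
  list(offground = pointCloud(m[!isGround, , drop = FALSE], cloud@frameNote),
       ground = pointCloud(m[isGround, , drop = FALSE], cloud@frameNote),
       offground_indices = which(!isGround))
}

#' Full preprocessing pipeline
#'
#' Radius outlier removal, RANSAC ground leveling, ground filtering, and a
#' second outlier-removal pass, returning the canopy cloud. Per-stage removal
#' counts are attached as the "stages" attribute and reported via message().
#'
#' @param cloud raw scene \linkS4class{PointCloud}
#' @param ror see \code{\link{rorParams}}
#' @param csf see \code{\link{csfParams}}
#' @param level run the leveling stage (disable for pre-leveled scenes)
#' @param ground_method passed to \code{\link{removeGround}}
#' @param verbose emit per-stage counts
#' @return the canopy \linkS4class{PointCloud}; the "kept_indices"
#'   attribute maps its rows back to rows of the input cloud
#' @export
preprocessPipeline <- function(cloud, ror = rorParams(), csf = csfParams(),
                               level = TRUE, ground_method = "grid",
                               verbose = FALSE) {
  stages <- list()
  s1 <- radiusOutlierRemoval(cloud, ror)
  stages$ror1 <- s1$removed_count
  cur <- s1$kept
  idx <- s1$kept_indices
  if (nPoints(cur) == 0L) {
    warning("all points removed as outliers; returning empty cloud")
    attr(cur, "stages") <- stages
    return(cur)
  }
  if (level) {
    lv <- levelToGround(cur)
    cur <- lv$leveled
    stages$leveling_inlier_fraction <- lv$result$inlier_fraction
  }
  gr <- removeGround(cur, csf, method = ground_method)
  stages$ground <- nPoints(gr$ground)
  cur <- gr$offground
  idx <- idx[gr$offground_indices]
  if (nPoints(cur) == 0L) {
    warning("no off-ground points remain after ground filtering")
    attr(cur, "stages") <- stages
    return(cur)
  }
  s2 <- radiusOutlierRemoval(cur, ror)
  stages$ror2 <- s2$removed_count
  out <- s2$kept
  idx <- idx[s2$kept_indices]
  attr(out, "kept_indices") <- idx
  if (nPoints(out) == 0L) warning("no points remain after final outlier removal")
  if (verbose) message("preprocess: removed ", stages$ror1, " outliers, ",
                       stages$ground, " ground points, ", stages$ror2,
                       " residual outliers; ", nPoints(out), " canopy points kept")
  attr(out, "stages") <- stages
  out
}
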