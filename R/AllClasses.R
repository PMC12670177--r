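#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib canopyEV, .registration = TRUE
NULL

#' PointCloud: a set of 3D points in meters
#'
#' The universal currency of the pipeline: an N x 3 matrix of (x, y, z)
#' coordinates in meters. The axis convention is Z up, X along the tree row,
#' Y across rows (rows are split on Y, columns within a row on X).
#'
#' @slot coords numeric matrix with columns x, y, z (meters)
#' @slot frameNote character tag recording the axis convention
#' @export
setClass("PointCloud",
  representation(coords = "matrix", frameNote = "character"),
  prototype(coords = matrix(numeric(0), 0, 3,
                            dimnames = list(NULL, c("x", "y", "z"))),
            frameNote = "z-up; x along row; y across rows"))

setValidity("PointCloud", function(object) {
  m <- object@coords
  if (!is.numeric(m) || ncol(m) != 3L)
    return("coords must be a numeric matrix with 3 columns")
  if (nrow(m) > 0L && !all(is.finite(m)))
    return("all coordinates must be finite")
  TRUE
})

#' Construct a PointCloud
#'
#' @param coords numeric N x 3 matrix (or data.frame) of x, y, z in meters
#' @param frameNote text tag recording the axis convention
#' @return a \linkS4class{PointCloud}
#' @examples
#' pc <- pointCloud(matrix(runif(30), 10, 3))
#' nPoints(pc)
#' @export
pointCloud <- function(coords, frameNote = "z-up; x along row; y across rows") {
  m <- as.matrix(coords)
  if (ncol(m) != 3L) stop("coords must have exactly 3 columns (x, y, z)")
  storage.mode(m) <- "double"
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  new("PointCloud", coords = m, frameNote = frameNote)
}

#' CanopyMesh: closed triangle mesh from alpha-shape reconstruction
#'
#' @slot vertices numeric V x 3 matrix of vertex coordinates (meters)
#' @slot triangles integer T x 3 matrix of 1-based vertex indices, oriented
#'   with outward normals
#' @slot alphaUsed final alpha (meters) at which the mesh closed
#' @slot itersUsed number of alpha-growth iterations consumed
#' @slot volume enclosed volume in cubic meters
#' @slot hullFallback TRUE when the convex-hull fallback was taken
#' @export
setClass("CanopyMesh",
  representation(vertices = "matrix", triangles = "matrix",
                 alphaUsed = "numeric", itersUsed = "integer",
                 volume = "numeric", hullFallback = "logical"),
  prototype(hullFallback = FALSE))

setValidity("CanopyMesh", function(object) {
  if (ncol(object@vertices) != 3L) return("vertices must have 3 columns")
  if (ncol(object@triangles) != 3L) return("triangles must have 3 columns")
  if (length(object@volume) == 1L && !is.na(object@volume) &&
      object@volume <= 0) return("mesh volume must be positive")
  TRUE
})

#' ProjectionGrid: voxelized orthogonal projection of a canopy cloud
#'
#' Occupancy raster of one projection plane, its 2D boundary contour
#' (a 2D alpha complex), and the in-contour flags used by the plane
#' effective coefficient.
#'
#' @slot plane one of "xoy", "xoz", "yoz"
#' @slot origin 2D min corner of the grid (meters)
#' @slot voxelSize side length VS of the square voxels (meters)
#' @slot dims integer c(nx, ny): number of voxels per axis
#' @slot occupancy logical nx x ny matrix: voxel holds >= 1 projected point
#' @slot inContour logical nx x ny matrix: voxel center inside the contour
#' @slot points2d the projected 2D points
#' @slot dropped per-point values of the dropped (projection) axis
#' @slot contourArea area enclosed by the 2D boundary contour (m^2)
#' @export
setClass("ProjectionGrid",
  representation(plane = "character", origin = "numeric", voxelSize = "numeric",
                 dims = "integer", occupancy = "matrix", inContour = "matrix",
                 points2d = "matrix", dropped = "numeric", contourArea = "numeric"))

#' PartitionGrid: partition weights over a ProjectionGrid
#'
#' Aligned square blocks of voxels with thickness weights W (meters), counts
#' of in-contour voxels (nav) and of occupied in-contour voxels (nev).
#'
#' @slot partitionMultiplier voxels per partition side (default 5)
#' @slot W numeric matrix of partition weights, meters
#' @slot nev integer matrix: effective (occupied, in-contour) voxel counts
#' @slot nav integer matrix: in-contour voxel counts
#' @slot interpolationRounds rounds of eight-neighbour interpolation applied
#' @export
setClass("PartitionGrid",
  representation(partitionMultiplier = "integer", W = "matrix",
                 nev = "matrix", nav = "matrix",
                 interpolationRounds = "integer"))

#' EVResult: canopy effective-volume estimate
#'
#' @slot Vm reconstructed model volume (m^3)
#' @slot EC named numeric: plane effective coefficients (xoy, xoz, yoz)
#' @slot EVC effective volume coefficient = product of the three ECs
#' @slot Ve effective volume Vm * EVC (m^3)
#' @slot params parameters used (vs multiplier, partition multiplier, VS source)
#' @export
setClass("EVResult",
  representation(Vm = "numeric", EC = "numeric", EVC = "numeric",
                 Ve = "numeric", params = "list"))

setValidity("EVResult", function(object) {
  if (any(object@EC <= 0 | object@EC > 1 + 1e-12))
    return("every plane effective coefficient must lie in (0, 1]")
  if (object@Ve > object@Vm * (1 + 1e-12))
    return("effective volume cannot exceed the reconstructed volume")
  TRUE
})

#' SyntheticCanopy: generated point cloud with analytic ground truth
#'
#' @slot cloud the generated \linkS4class{PointCloud}
#' @slot labels per-point class: "canopy", "ground" or "noise"
#' @slot treeId per-point tree index (NA for non-canopy points)
#' @slot rowId per-point row index (NA for non-canopy points)
#' @slot truthSolidVolume analytic volume of the solid material (m^3)
#' @slot truthEnvelopeVolume analytic volume of the outer envelope (m^3)
#' @slot porosityFraction 1 - truthSolid/truthEnvelope
#' @slot geometry generator parameters (envelope profile, voids, seed)
#' @export
setClass("SyntheticCanopy",
  representation(cloud = "PointCloud", labels = "character",
                 treeId = "integer", rowId = "integer",
                 truthSolidVolume = "numeric", truthEnvelopeVolume = "numeric",
                 porosityFraction = "numeric", geometry = "list"))

setValidity("SyntheticCanopy", function(object) {
  if (length(object@truthSolidVolume) == 1L &&
      length(object@truthEnvelopeVolume) == 1L &&
      is.finite(object@truthSolidVolume) &&
      object@truthSolidVolume > object@truthEnvelopeVolume + 1e-12)
    return("solid volume cannot exceed envelope volume")
  if (length(object@porosityFraction) == 1L && is.finite(object@porosityFraction) &&
      (object@porosityFraction < 0 || object@porosityFraction >= 1))
    return("porosity fraction must be in [0, 1)")
  TRUE
})
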