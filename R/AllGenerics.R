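#' Extract the coordinate matrix of a point cloud
#'
#' @param x a \linkS4class{PointCloud} or \linkS4class{SyntheticCanopy}
#' @return numeric N x 3 matrix with columns x, y, z (meters)
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname coords
#' @export
setMethod("coords", "PointCloud", function(x) x@coords)

#' @rdname coords
#' @export
setMethod("coords", "SyntheticCanopy", function(x) x@cloud@coords)

#' Number of points in a cloud
#'
#' @param x a \linkS4class{PointCloud} or \linkS4class{SyntheticCanopy}
#' @return integer count
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' @rdname nPoints
#' @export
setMethod("nPoints", "PointCloud", function(x) nrow(x@coords))

#' @rdname nPoints
#' @export
setMethod("nPoints", "SyntheticCanopy", function(x) nrow(x@cloud@coords))

#' Volume enclosed by a closed triangle mesh
#'
#' @param mesh a \linkS4class{CanopyMesh}
#' @return volume in cubic meters
#' @export
setGeneric("meshVolume", function(mesh) standardGeneric("meshVolume"))

setMethod("show", "PointCloud", function(object) {
  n <- nrow(object@coords)
  cat(sprintf("PointCloud with %d points", n))
  if (n > 0) {
    r <- apply(object@coords, 2, range)
    cat(sprintf(" | x [%.2f, %.2f] y [%.2f, %.2f] z [%.2f, %.2f] m",
                r[1, 1], r[2, 1], r[1, 2], r[2, 2], r[1, 3], r[2, 3]))
  }
  cat("\n  frame:", object@frameNote, "\n")
})

setMethod("show", "CanopyMesh", function(object) {
  cat(sprintf(
    "CanopyMesh: %d vertices, %d triangles | alpha = %.4f m (%d iterations)%s\n  volume = %.4f m^3\n",
    nrow(object@vertices), nrow(object@triangles), object@alphaUsed,
    object@itersUsed, if (object@hullFallback) " [convex-hull fallback]" else "",
    object@volume))
})

setMethod("show", "EVResult", function(object) {
  cat(sprintf("Canopy effective volume\n  Vm  = %.4f m^3\n", object@Vm))
  cat(sprintf("  EC  = xoy %.4f | xoz %.4f | yoz %.4f\n",
              object@EC[["xoy"]], object@EC[["xoz"]], object@EC[["yoz"]]))
  cat(sprintf("  EVC = %.4f\n  Ve  = %.4f m^3\n", object@EVC, object@Ve))
})

setMethod("show", "SyntheticCanopy", function(object) {
  cat(sprintf("SyntheticCanopy: %d points (%d canopy, %d ground, %d noise)\n",
              length(object@labels), sum(object@labels == "canopy"),
              sum(object@labels == "ground"), sum(object@labels == "noise")))
  if (is.finite(object@truthEnvelopeVolume))
    cat(sprintf("  truth: envelope %.4f m^3, solid %.4f m^3, porosity %.3f\n",
                object@truthEnvelopeVolume, object@truthSolidVolume,
                object@porosityFraction))
})
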