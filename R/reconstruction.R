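# Density-adaptive alpha-shape reconstruction. The alpha-shape at radius
# alpha keeps every Delaunay tetrahedron whose circumradius is <= alpha; its
# boundary is the set of faces incident to exactly one kept tetrahedron.
# alpha starts at k x d_avg and grows by alpha_step x d_avg per iteration
# until that boundary is a closed, edge-manifold surface enclosing positive
# volume. alpha is a circumradius threshold in meters throughout.

#' Alpha-growth parameters
#'
#' @param k unitless scale of the baseline alpha (alpha_base = k x d_avg)
#' @param alpha_step unitless step coefficient: each iteration grows alpha by
#'   alpha_step x d_avg
#' @param max_iters iterations before the convex-hull fallback
#' @return validated parameter list
#' @export
alphaParams <- function(k = 5, alpha_step = 0.5, max_iters = 50) {
  stopifnot(k > 0, alpha_step > 0, max_iters >= 1)
  list(k = k, alpha_step = alpha_step, max_iters = as.integer(max_iters))
}

#' Baseline alpha from cloud density
#'
#' alpha_base = k x d_avg, with d_avg the mean 3D nearest-neighbour distance
#' of the cloud. With the default k = 5 a cloud of d_avg = 0.02 m starts at
#' alpha = 0.10 m.
#'
#' @param cloud a \linkS4class{PointCloud} with >= 2 points
#' @param k empirical scaling factor (> 0)
#' @return alpha in meters
#' @export
baselineAlpha <- function(cloud, k = 5) {
  if (k <= 0) stop("k must be positive")
  k * averageNNDistance(cloud, dims = 3)$d_avg
}

#' Reconstruct a canopy surface by iterative alpha growth
#'
#' Builds the 3D Delaunay tetrahedralization once, then grows alpha from the
#' baseline until the alpha-shape boundary closes. Tiny disconnected surface
#' islands (under 1 percent of total area) are dropped before the closure
#' test so stray fragments cannot block termination. After \code{max_iters}
#' the convex hull (the alpha-shape limit for large alpha) is returned with
#' a warning: it is guaranteed closed and upper-bounds the volume.
#'
#' @param cloud a \linkS4class{PointCloud} with >= 4 non-coplanar points
#' @param params see \code{\link{alphaParams}}
#' @return a \linkS4class{CanopyMesh}
#' @examples
#' \donttest{
#' sph <- makePrimitiveCloud("sphere", dims = c(radius = 0.5),
#'                           density = 4000, seed = 1)
#' mesh <- reconstructCanopy(sph@cloud)
#' meshVolume(mesh)   # close to 4/3 * pi * 0.5^3
#' }
#' @export
reconstructCanopy <- function(cloud, params = alphaParams()) {
  m <- coords(cloud)
  if (nrow(m) < 4L) stop("need at least 4 points to reconstruct a surface")
  davg <- averageNNDistance(cloud, dims = 3)$d_avg
  # exact duplicates break the tetrahedralization; d_avg above still sees them
  mu <- unique(m)
  if (nrow(mu) < 4L) stop("degenerate cloud: fewer than 4 distinct points")
  if (qr(sweep(mu, 2, colMeans(mu)))$rank < 3L)
    stop("degenerate cloud: points are coplanar or collinear")
  del <- tryCatch(cpp_delaunay3d(mu), error = function(e)
    stop("reconstruction failed (degenerate cloud?): ", conditionMessage(e)))
  if (nrow(del$tets) == 0L)
    stop("degenerate cloud: no tetrahedra (coplanar or collinear points)")
  alpha <- params$k * davg
  for (it in seq_len(params$max_iters)) {
    keep <- del$circumradius <= alpha
    if (any(keep)) {
      b <- cpp_alpha_boundary(del$tets, mu, keep)
      if (isTRUE(b$closed)) {
        return(new("CanopyMesh", vertices = mu, triangles = b$faces,
                   alphaUsed = alpha, itersUsed = it,
                   volume = b$volume, hullFallback = FALSE))
      }
    }
    alpha <- alpha + params$alpha_step * davg
  }
  warning("alpha-shape did not close after ", params$max_iters,
          " iterations; falling back to the convex hull")
  b <- cpp_alpha_boundary(del$tets, mu, rep(TRUE, nrow(del$tets)))
  new("CanopyMesh", vertices = mu, triangles = b$faces,
      alphaUsed = Inf, itersUsed = params$max_iters,
      volume = b$volume, hullFallback = TRUE)
}

#' @describeIn meshVolume Volume by the divergence theorem: the absolute
#'   value of the signed sum of per-triangle tetrahedron terms
#'   (V0 . (V1 x V2)) / 6 over consistently outward-oriented triangles. The
#'   signed sum (rather than summing per-term absolute values) is what makes
#'   the result independent of the coordinate origin and correct for
#'   non-convex canopies; for star-shaped meshes about the origin the two
#'   agree term by term.
#' @export
setMethod("meshVolume", "CanopyMesh", function(mesh) {
  tri <- mesh@triangles
  if (nrow(tri) == 0L) stop("mesh has no triangles")
  bad <- cpp_mesh_bad_edges(tri)
  if (bad > 0L)
    stop("mesh is not closed: ", bad, " boundary/non-manifold edges")
  v <- mesh@vertices
  a <- v[tri[, 1], , drop = FALSE]
  b <- v[tri[, 2], , drop = FALSE]
  c_ <- v[tri[, 3], , drop = FALSE]
  s <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
       a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
       a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  abs(sum(s)) / 6
})

# ---- shared 2D alpha-complex helper ---------------------------------------

# Dynamic 2D alpha complex: triangles of the 2D Delaunay triangulation with
# circumradius <= alpha, alpha grown from k2 x d_avg(2D) in steps of
# step2 x d_avg(2D) until every point is a vertex of a kept triangle (the
# "contour contains all points" condition). Returns kept triangles, the
# point matrix actually triangulated (duplicates removed), total area and
# the alpha used.
.alphaComplex2D <- function(pts2d, k2 = 5, step2 = 0.5, max_iters = 60) {
  pts2d <- as.matrix(pts2d)
  if (nrow(pts2d) < 3L) stop("need at least 3 points for a 2D boundary contour")
  u <- unique(pts2d)
  if (nrow(u) < 3L) stop("degenerate 2D point set")
  davg <- averageNNDistance(pts2d, dims = 2)$d_avg
  del <- tryCatch(cpp_delaunay2d(u), error = function(e)
    stop("degenerate 2D contour (collinear points?): ", conditionMessage(e)))
  if (nrow(del$triangles) == 0L) stop("degenerate 2D contour: no triangles")
  alpha <- k2 * davg
  for (it in seq_len(max_iters)) {
    keep <- del$circumradius <= alpha
    if (any(keep)) {
      tri <- del$triangles[keep, , drop = FALSE]
      if (length(unique(as.vector(tri))) == nrow(u)) {
        area <- .triArea(u, tri)
        return(list(points = u, triangles = tri, area = sum(area),
                    alpha = alpha, d_avg = davg))
      }
    }
    alpha <- alpha + step2 * davg
  }
  tri <- del$triangles   # convex-hull limit
  list(points = u, triangles = tri, area = sum(.triArea(u, tri)),
       alpha = Inf, d_avg = davg)
}

.triArea <- function(p, tri) {
  a <- p[tri[, 1], , drop = FALSE]
  b <- p[tri[, 2], , drop = FALSE]
  c_ <- p[tri[, 3], , drop = FALSE]
  abs((b[, 1] - a[, 1]) * (c_[, 2] - a[, 2]) -
      (b[, 2] - a[, 2]) * (c_[, 1] - a[, 1])) / 2
}
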