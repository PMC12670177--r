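# Division of an orchard cloud into 3D-reconstruction areas: rows are split
# on the Y axis by troughs of a Gaussian kernel density estimate, and each
# row ("tree wall") is split into columns at significant troughs of the
# per-bin maximum-height profile along X.

#' Trough-detection parameters for column segmentation
#'
#' The height-profile trough screening runs in three stages: (3) troughs
#' shallower than \code{min_depth} against either adjacent peak are
#' pseudo-troughs and dropped; (4) troughs closer than \code{min_spacing}
#' are thinned, keeping the lower one; (5) troughs removed by the spacing
#' rule are reinstated when their depth against *both* adjacent peaks
#' exceeds \code{sig_depth}.
#'
#' @param bin_width X bin width of the height profile, meters
#' @param min_depth minimum trough depth (m); NA = 0.15 x row height range
#' @param min_spacing minimum horizontal distance between troughs (m)
#' @param sig_depth significant-trough depth (m); NA = 0.30 x row height range
#' @return validated parameter list
#' @export
troughParams <- function(bin_width = 0.05, min_depth = NA_real_,
                         min_spacing = 0.5, sig_depth = NA_real_) {
  stopifnot(bin_width > 0, min_spacing > bin_width)
  if (is.finite(min_depth) && is.finite(sig_depth) && min_depth > sig_depth)
    stop("min_depth must not exceed sig_depth")
  list(bin_width = bin_width, min_depth = min_depth,
       min_spacing = min_spacing, sig_depth = sig_depth)
}

#' Segment an orchard cloud into tree rows
#'
#' Gaussian kernel density estimation of the Y coordinates on a uniform grid
#' (step = bandwidth / 4); local density minima with prominence of at least
#' 10 percent of the density maximum become row cut positions; points are
#' assigned to rows by half-open intervals between consecutive cuts.
#'
#' @param cloud canopy \linkS4class{PointCloud} covering one or more rows
#' @param bandwidth KDE bandwidth in meters, or "auto" for Scott's rule
#' @param prominence_frac minimum trough prominence as a fraction of the
#'   density maximum
#' @return list with \code{cut_positions} (Y, meters, strictly increasing)
#'   and \code{rows} (list of PointCloud)
#' @export
segmentRows <- function(cloud, bandwidth = "auto", prominence_frac = 0.10) {
  m <- coords(cloud)
  if (nrow(m) == 0L) stop("cannot segment an empty cloud")
  y <- m[, 2]
  if (diff(range(y)) < 1e-9) {
    warning("all Y coordinates identical; returning a single row")
    return(list(cut_positions = numeric(0), rows = list(cloud)))
  }
  bw <- if (identical(bandwidth, "auto"))
    1.06 * stats::sd(y) * length(y)^(-1 / 5) else bandwidth
  step <- bw / 4
  grid <- seq(min(y) - 3 * bw, max(y) + 3 * bw, by = step)
  den <- stats::density(y, bw = bw, from = grid[1],
                        to = grid[length(grid)], n = length(grid))
  d <- den$y
  cuts <- numeric(0)
  n <- length(d)
  locmin <- which(d[2:(n - 1)] <= d[1:(n - 2)] & d[2:(n - 1)] <= d[3:n]) + 1L
  locmax <- which(d[2:(n - 1)] >= d[1:(n - 2)] & d[2:(n - 1)] >= d[3:n]) + 1L
  for (i in locmin) {
    left <- locmax[locmax < i]; right <- locmax[locmax > i]
    if (length(left) == 0L || length(right) == 0L) next
    peakL <- max(d[left]); peakR <- max(d[right])
    prom <- min(peakL, peakR) - d[i]
    if (prom >= prominence_frac * max(d)) cuts <- c(cuts, den$x[i])
  }
  cuts <- sort(unique(cuts))
  breaks <- c(-Inf, cuts, Inf)
  grp <- findInterval(y, breaks, left.open = FALSE)
  rows <- lapply(sort(unique(grp)), function(g)
    pointCloud(m[grp == g, , drop = FALSE], cloud@frameNote))
  list(cut_positions = cuts, rows = rows)
}

#' Height profile of a tree row
#'
#' Bins the row cloud along X into half-open bins [x0 + i*w, x0 + (i+1)*w)
#' and records the per-bin maximum Z (the canopy top). Empty bins are NA.
#'
#' @param row a \linkS4class{PointCloud}
#' @param bin_width bin width in meters
#' @return list with \code{bin_width}, \code{bin_centers}, \code{max_z}
#'   (NA marks an empty bin) and \code{x0}
#' @export
heightProfile <- function(row, bin_width = 0.05) {
  m <- coords(row)
  if (nrow(m) == 0L) stop("cannot profile an empty row")
  x0 <- min(m[, 1])
  ext <- diff(range(m[, 1]))
  nb <- max(1L, as.integer(ceiling(ext / bin_width - 1e-12)))
  idx <- pmin(floor((m[, 1] - x0) / bin_width), nb - 1L)  # x == max -> top bin
  mz <- rep(NA_real_, nb)
  agg <- tapply(m[, 3], idx, max)
  mz[as.integer(names(agg)) + 1L] <- agg
  list(bin_width = bin_width,
       bin_centers = x0 + (seq_len(nb) - 0.5) * bin_width,
       max_z = mz, x0 = x0)
}

#' Detect significant height troughs in a row profile
#'
#' Finds all local minima of the per-bin maximum height, then applies the
#' three screening stages of \code{\link{troughParams}}. Empty bins are
#' excluded from trough detection. Ties in the spacing rule are broken by
#' keeping the leftmost (smaller X) trough; troughs reinstated by the
#' significant-depth rule are never removed again.
#'
#' @param profile output of \code{\link{heightProfile}}
#' @param params see \code{\link{troughParams}}
#' @return numeric vector of split X positions (sorted, possibly empty)
#' @export
detectTroughs <- function(profile, params = troughParams()) {
  keep <- !is.na(profile$max_z)
  z <- profile$max_z[keep]
  x <- profile$bin_centers[keep]
  n <- length(z)
  if (n < 3L) return(numeric(0))
  zr <- diff(range(z))
  min_depth <- if (is.finite(params$min_depth)) params$min_depth else 0.15 * zr
  sig_depth <- if (is.finite(params$sig_depth)) params$sig_depth else 0.30 * zr
  # local minima over the non-empty sequence (plateaus: take the first bin)
  isMin <- logical(n)
  for (i in 2:(n - 1))
    isMin[i] <- z[i] <= z[i - 1] && z[i] <= z[i + 1] &&
      (z[i] < z[i - 1] || z[i] < z[i + 1])
  tr <- which(isMin)
  if (length(tr) == 0L) return(numeric(0))
  # adjacent peak heights by the prominence convention: walk outward from
  # the trough until the profile drops below the trough height (or the end
  # of the row); the adjacent peak is the maximum over that stretch. This
  # keeps noisy staircase descents from masking a deep junction trough
  # behind shallow intermediate minima.
  peakL <- peakR <- numeric(length(tr))
  for (k in seq_along(tr)) {
    i <- tr[k]
    lo <- i - 1L
    while (lo > 1L && z[lo] >= z[i]) lo <- lo - 1L
    peakL[k] <- max(z[lo:(i - 1L)])
    hi <- i + 1L
    while (hi < n && z[hi] >= z[i]) hi <- hi + 1L
    peakR[k] <- max(z[(i + 1L):hi])
  }
  depthL <- peakL - z[tr]; depthR <- peakR - z[tr]
  eps <- 1e-9                       # guard threshold ties against rounding
  # stage 3: pseudo-troughs (shallow against either peak) dropped
  valid <- depthL >= min_depth - eps & depthR >= min_depth - eps
  step3 <- tr[valid]
  # stage 4: spacing constraint on the survivors; keep the lower trough
  step4 <- step3
  repeat {
    if (length(step4) < 2L) break
    gaps <- diff(x[step4])
    j <- which(gaps < params$min_spacing)
    if (length(j) == 0L) break
    j <- j[1]
    a <- step4[j]; b <- step4[j + 1]
    drop <- if (z[a] < z[b] || (z[a] == z[b])) b else a  # ties: keep leftmost
    step4 <- setdiff(step4, drop)
  }
  # stage 5: reinstate spacing-removed troughs that are deep against BOTH peaks
  removed <- setdiff(step3, step4)
  k <- match(removed, tr)
  reinstated <- removed[depthL[k] >= sig_depth - eps &
                        depthR[k] >= sig_depth - eps]
  sort(unique(x[sort(c(step4, reinstated))]))
}

#' Segment a tree row into reconstruction columns
#'
#' Height profile, trough screening, then half-open splitting of the row at
#' the final trough positions. When no significant trough survives, the
#' whole row is a single column (documented under-segmentation behaviour for
#' fused canopies).
#'
#' @param row a \linkS4class{PointCloud}
#' @param params see \code{\link{troughParams}}
#' @return list with \code{split_x} and \code{columns} (list of PointCloud)
#' @export
segmentColumns <- function(row, params = troughParams()) {
  m <- coords(row)
  if (nrow(m) == 0L) stop("cannot segment an empty row")
  prof <- heightProfile(row, params$bin_width)
  splits <- detectTroughs(prof, params)
  breaks <- c(-Inf, splits, Inf)
  grp <- findInterval(m[, 1], breaks, left.open = FALSE)
  cols <- lapply(sort(unique(grp)), function(g)
    pointCloud(m[grp == g, , drop = FALSE], row@frameNote))
  list(split_x = splits, columns = cols)
}
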