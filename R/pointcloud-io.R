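# Point-cloud readers and writers for the four interchange formats used in
# terrestrial LiDAR work: whitespace XYZ, PLY (ascii + binary little-endian),
# PCD (ascii + binary) and LAS 1.2 (point record formats 0-3). Only x, y, z
# are consumed; other attributes are skipped on read and dropped on write.

.guessFormat <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("ply", "pcd", "las", "xyz")) return(ext)
  if (ext %in% c("txt", "pts", "csv")) return("xyz")
  stop("cannot infer point-cloud format from extension of '", path,
       "'; pass fmt explicitly", call. = FALSE)
}

#' Read a point cloud from file
#'
#' @param path file path
#' @param fmt one of "ply", "pcd", "las", "xyz", or "auto" to infer from the
#'   file extension
#' @return a \linkS4class{PointCloud} with coordinates in meters (LAS scale
#'   and offset are applied on read)
#' @examples
#' f <- tempfile(fileext = ".xyz")
#' writeLines(c("0 0 0", "1 0 0", "0 1 0"), f)
#' readCloud(f)
#' @export
readCloud <- function(path, fmt = c("auto", "ply", "pcd", "las", "xyz")) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("cannot read point cloud: no such file '", path, "'")
  if (fmt == "auto") fmt <- .guessFormat(path)
  m <- switch(fmt,
    xyz = .readXYZ(path),
    ply = .readPLY(path),
    pcd = .readPCD(path),
    las = .readLAS(path))
  if (nrow(m) == 0L) stop("empty point cloud in '", path, "'")
  pointCloud(m)
}

#' Write a point cloud to file
#'
#' @param cloud a \linkS4class{PointCloud}
#' @param path destination path
#' @param fmt format as in \code{\link{readCloud}}; "auto" infers from the
#'   extension
#' @param binary for ply/pcd: write the binary flavour (default TRUE writes
#'   ascii for portability)
#' @return invisibly, the path
#' @export
writeCloud <- function(cloud, path, fmt = c("auto", "ply", "pcd", "las", "xyz"),
                       binary = FALSE) {
  fmt <- match.arg(fmt)
  if (fmt == "auto") fmt <- .guessFormat(path)
  m <- coords(cloud)
  if (nrow(m) == 0L) stop("refusing to write an empty point cloud")
  switch(fmt,
    xyz = .writeXYZ(m, path),
    ply = .writePLY(m, path, binary),
    pcd = .writePCD(m, path, binary),
    las = .writeLAS(m, path))
  invisible(path)
}

# ---- XYZ ------------------------------------------------------------------

.readXYZ <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(matrix(numeric(0), 0, 3))
  parts <- strsplit(trimws(lines), "[,;[:space:]]+")
  m <- matrix(NA_real_, length(parts), 3)
  for (i in seq_along(parts)) {
    v <- suppressWarnings(as.numeric(parts[[i]][1:3]))
    if (anyNA(v)) stop("parse error in '", path, "' at line ", i,
                       ": '", lines[i], "'")
    m[i, ] <- v
  }
  m
}

.writeXYZ <- function(m, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%.9g %.9g %.9g", m[, 1], m[, 2], m[, 3]), con)
}

# ---- PLY ------------------------------------------------------------------

.readPLY <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  readHeaderLine <- function() {
    chars <- character(0)
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) stop("unexpected end of PLY header in '", path, "'")
      if (ch == "\n") break
      chars <- c(chars, ch)
    }
    sub("\r$", "", paste(chars, collapse = ""))
  }
  if (readHeaderLine() != "ply") stop("'", path, "' is not a PLY file")
  format <- NULL; elements <- list(); current <- NULL
  repeat {
    line <- readHeaderLine()
    tok <- strsplit(trimws(line), "[[:space:]]+")[[1]]
    if (tok[1] == "comment") next
    if (tok[1] == "format") format <- tok[2]
    else if (tok[1] == "element") {
      current <- tok[2]
      elements[[current]] <- list(count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (tok[2] == "list")
        elements[[current]]$props[[length(elements[[current]]$props) + 1L]] <-
          list(name = tok[5], type = "list", count_type = tok[3], item_type = tok[4])
      else
        elements[[current]]$props[[length(elements[[current]]$props) + 1L]] <-
          list(name = tok[3], type = tok[2])
    } else if (tok[1] == "end_header") break
  }
  if (is.null(elements$vertex)) stop("PLY file '", path, "' has no vertex element")
  sizes <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1, short = 2, ushort = 2,
             int16 = 2, uint16 = 2, int = 4, uint = 4, int32 = 4, uint32 = 4,
             float = 4, float32 = 4, double = 8, float64 = 8)
  readScalar <- function(type) {
    sz <- sizes[[type]]
    if (type %in% c("float", "float32", "double", "float64"))
      readBin(con, "double", 1L, size = sz, endian = "little")
    else
      readBin(con, "integer", 1L, size = sz, endian = "little",
              signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
  }
  elemNames <- names(elements)
  out <- NULL
  if (identical(format, "ascii")) {
    rest <- readLines(con, warn = FALSE)
    pos <- 1L
    for (en in elemNames) {
      el <- elements[[en]]
      nrows <- el$count
      if (en == "vertex") {
        pn <- vapply(el$props, function(p) p$name, "")
        ix <- match(c("x", "y", "z"), pn)
        if (anyNA(ix)) stop("PLY vertex element lacks x/y/z in '", path, "'")
        rows <- rest[pos:(pos + nrows - 1L)]
        vals <- strsplit(trimws(rows), "[[:space:]]+")
        out <- t(vapply(vals, function(v) as.numeric(v[ix]), numeric(3)))
        pos <- pos + nrows
      } else pos <- pos + nrows
    }
  } else if (format %in% c("binary_little_endian")) {
    for (en in elemNames) {
      el <- elements[[en]]
      haveList <- any(vapply(el$props, function(p) p$type == "list", TRUE))
      if (en == "vertex") {
        pn <- vapply(el$props, function(p) p$name, "")
        out <- matrix(NA_real_, el$count, 3)
        for (i in seq_len(el$count)) {
          for (p in el$props) {
            v <- readScalar(p$type)
            j <- match(p$name, c("x", "y", "z"))
            if (!is.na(j)) out[i, j] <- v
          }
        }
      } else if (!haveList) {
        rowBytes <- sum(vapply(el$props, function(p) sizes[[p$type]], 0))
        invisible(readBin(con, "raw", el$count * rowBytes))
      } else {
        for (i in seq_len(el$count)) for (p in el$props) {
          if (p$type == "list") {
            k <- readScalar(p$count_type)
            for (q in seq_len(k)) readScalar(p$item_type)
          } else readScalar(p$type)
        }
      }
    }
  } else stop("unsupported PLY format '", format, "' in '", path, "'")
  out
}

.writePLY <- function(m, path, binary) {
  con <- file(path, "wb"); on.exit(close(con))
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
           paste("element vertex", nrow(m)),
           "property double x", "property double y", "property double z",
           "end_header")
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  if (binary) {
    writeBin(as.vector(t(m)), con, size = 8, endian = "little")
  } else {
    writeChar(paste0(sprintf("%.17g %.17g %.17g", m[, 1], m[, 2], m[, 3]),
                     collapse = "\n"), con, eos = NULL)
    writeChar("\n", con, eos = NULL)
  }
}

# ---- PCD ------------------------------------------------------------------

.readPCD <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- list()
  repeat {
    chars <- character(0)
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) stop("unexpected end of PCD header in '", path, "'")
      if (ch == "\n") break
      chars <- c(chars, ch)
    }
    line <- paste(chars, collapse = "")
    if (grepl("^#", line)) next
    tok <- strsplit(trimws(line), "[[:space:]]+")[[1]]
    hdr[[tok[1]]] <- tok[-1]
    if (tok[1] == "DATA") break
  }
  fields <- hdr$FIELDS
  size <- as.integer(hdr$SIZE)
  type <- hdr$TYPE
  count <- if (!is.null(hdr$COUNT)) as.integer(hdr$COUNT) else rep(1L, length(fields))
  npts <- as.integer(hdr$POINTS[1])
  ix <- match(c("x", "y", "z"), fields)
  if (anyNA(ix)) stop("PCD file '", path, "' lacks x/y/z fields")
  mode <- hdr$DATA[1]
  if (mode == "ascii") {
    rows <- readLines(con, warn = FALSE)
    rows <- rows[nzchar(trimws(rows))][seq_len(npts)]
    vals <- strsplit(trimws(rows), "[[:space:]]+")
    cols <- cumsum(count); starts <- cols - count + 1L
    m <- t(vapply(vals, function(v) as.numeric(v[starts[ix]]), numeric(3)))
    m
  } else if (mode == "binary") {
    m <- matrix(NA_real_, npts, 3)
    readOne <- function(ty, sz) {
      if (ty == "F") readBin(con, "double", 1L, size = sz, endian = "little")
      else if (ty == "I") readBin(con, "integer", 1L, size = sz, endian = "little")
      else readBin(con, "integer", 1L, size = sz, endian = "little", signed = sz >= 4)
    }
    for (i in seq_len(npts)) {
      for (f in seq_along(fields)) for (k in seq_len(count[f])) {
        v <- readOne(type[f], size[f])
        j <- match(fields[f], c("x", "y", "z"))
        if (!is.na(j) && k == 1L) m[i, j] <- v
      }
    }
    m
  } else stop("unsupported PCD DATA mode '", mode, "' in '", path, "'")
}

.writePCD <- function(m, path, binary) {
  con <- file(path, "wb"); on.exit(close(con))
  n <- nrow(m)
  hdr <- c("# .PCD v0.7 - Point Cloud Data file format",
           "VERSION 0.7", "FIELDS x y z", "SIZE 8 8 8", "TYPE F F F",
           "COUNT 1 1 1", paste("WIDTH", n), "HEIGHT 1",
           "VIEWPOINT 0 0 0 1 0 0 0", paste("POINTS", n),
           paste("DATA", if (binary) "binary" else "ascii"))
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  if (binary) writeBin(as.vector(t(m)), con, size = 8, endian = "little")
  else {
    writeChar(paste0(sprintf("%.17g %.17g %.17g", m[, 1], m[, 2], m[, 3]),
                     collapse = "\n"), con, eos = NULL)
    writeChar("\n", con, eos = NULL)
  }
}

# ---- LAS 1.2 --------------------------------------------------------------

.readLAS <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  sig <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(sig, "LASF")) stop("'", path, "' is not a LAS file")
  invisible(readBin(con, "raw", 20L))            # source id .. version minor at 24
  seek(con, 24)
  ver <- readBin(con, "integer", 2L, size = 1, signed = FALSE)
  seek(con, 96)
  offsetToPoints <- readBin(con, "integer", 1L, size = 4, endian = "little")
  invisible(readBin(con, "integer", 1L, size = 4, endian = "little")) # n VLRs
  pdrf <- readBin(con, "integer", 1L, size = 1, signed = FALSE)
  recLen <- readBin(con, "integer", 1L, size = 2, endian = "little", signed = FALSE)
  npts <- readBin(con, "integer", 1L, size = 4, endian = "little")
  invisible(readBin(con, "integer", 5L, size = 4, endian = "little"))
  scale <- readBin(con, "double", 3L, size = 8, endian = "little")
  offset <- readBin(con, "double", 3L, size = 8, endian = "little")
  if (pdrf > 3L) stop("LAS point data record format ", pdrf,
                      " not supported (formats 0-3)")
  seek(con, offsetToPoints)
  raw <- readBin(con, "raw", as.numeric(npts) * recLen)
  if (length(raw) < npts * recLen) stop("truncated LAS file '", path, "'")
  dim(raw) <- c(recLen, npts)
  ints <- function(rows) { # little-endian int32 from 4 raw rows
    b <- matrix(as.integer(raw[rows, , drop = FALSE]), 4L)
    v <- b[1, ] + b[2, ] * 256 + b[3, ] * 65536 + b[4, ] * 16777216
    v - ifelse(b[4, ] >= 128L, 4294967296, 0)
  }
  x <- ints(1:4) * scale[1] + offset[1]
  y <- ints(5:8) * scale[2] + offset[2]
  z <- ints(9:12) * scale[3] + offset[3]
  if (ver[1] != 1L) warning("LAS major version ", ver[1], "; read as 1.x")
  cbind(x, y, z)
}

.writeLAS <- function(m, path) {
  con <- file(path, "wb"); on.exit(close(con))
  n <- nrow(m)
  offset <- apply(m, 2, min)
  scale <- rep(1e-6, 3)                          # micro-meter resolution
  ix <- round(sweep(m, 2, offset) / rep(scale, each = n))
  if (any(abs(ix) > 2^31 - 1)) stop("cloud extent too large for LAS int32 at 1e-6 scale")
  writeChar("LASF", con, eos = NULL)
  writeBin(rep(0L, 2), con, size = 2, endian = "little")     # source id, encoding
  writeBin(rep(0L, 16), con, size = 1)                       # project GUID
  writeBin(c(1L, 2L), con, size = 1)                         # version 1.2
  writeBin(rep(0L, 64), con, size = 1)                       # sys id + software
  writeBin(c(1L, 2026L), con, size = 2, endian = "little")   # day, year
  writeBin(227L, con, size = 2, endian = "little")           # header size
  writeBin(227L, con, size = 4, endian = "little")           # offset to points
  writeBin(0L, con, size = 4, endian = "little")             # n VLRs
  writeBin(0L, con, size = 1)                                # PDRF 0
  writeBin(20L, con, size = 2, endian = "little")            # record length
  writeBin(n, con, size = 4, endian = "little")              # n points
  writeBin(c(n, 0L, 0L, 0L, 0L), con, size = 4, endian = "little") # by return
  writeBin(scale, con, size = 8, endian = "little")
  writeBin(offset, con, size = 8, endian = "little")
  writeBin(as.vector(rbind(apply(m, 2, max), apply(m, 2, min))), con,
           size = 8, endian = "little")                      # max/min x,y,z
  body <- raw(n * 20L)
  dim(body) <- c(20L, n)
  enc <- function(v) { # int32 -> 4 raw bytes, little-endian
    v <- ifelse(v < 0, v + 4294967296, v)
    r1 <- v %% 256; v <- v %/% 256
    r2 <- v %% 256; v <- v %/% 256
    r3 <- v %% 256; r4 <- v %/% 256
    rbind(as.raw(r1), as.raw(r2), as.raw(r3), as.raw(r4))
  }
  body[1:4, ] <- enc(ix[, 1]); body[5:8, ] <- enc(ix[, 2]); body[9:12, ] <- enc(ix[, 3])
  writeBin(as.vector(body), con)
}

# ---- density statistic ----------------------------------------------------

#' Mean nearest-neighbour distance of a point cloud
#'
#' The density statistic d_avg on which the adaptive alpha and the projection
#' voxel size depend: the exact mean, over all points, of the Euclidean
#' distance to each point's single nearest other point (KD-tree accelerated,
#' no sampling). Exactly duplicated points contribute a distance of zero and
#' are not removed, so that d_avg keeps carrying the density signal of the
#' raw cloud.
#'
#' @param cloud a \linkS4class{PointCloud} or a numeric matrix with 2 or 3
#'   columns
#' @param dims 2 or 3; with dims = 2 the first two columns of the supplied
#'   matrix are used (pass projected (y,z), (x,z) or (x,y) pairs as needed)
#' @return list with \code{d_avg} (meters) and \code{n_points}
#' @examples
#' g <- as.matrix(expand.grid(x = 1:10, y = 1:10, z = 1:10)) * 0.02
#' averageNNDistance(pointCloud(g))$d_avg    # ~ 0.02
#' @export
averageNNDistance <- function(cloud, dims = 3) {
  m <- if (is(cloud, "PointCloud")) coords(cloud) else as.matrix(cloud)
  if (!dims %in% c(2, 3)) stop("dims must be 2 or 3")
  if (dims == 2 && ncol(m) >= 2) m <- m[, 1:2, drop = FALSE]
  if (nrow(m) < 2L) stop("need at least 2 points to compute a nearest-neighbour distance")
  nn <- RANN::nn2(m, k = 2L)
  # with exact duplicates the self-match may land in either column; the
  # second-smallest distance per row is the true nearest-other distance
  d <- nn$nn.dists[, 2L]
  list(d_avg = mean(d), n_points = nrow(m))
}
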