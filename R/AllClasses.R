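#' @import methods
NULL

#' AggregateMask: a binary aggregate mask with physical pixel size
#'
#' Container for a single-aggregate binary segmentation mask. Pixels are
#' stored x-first (`pixels[i, j]` is the pixel at x = i - 1, y = j - 1, in
#' pixel units); physical coordinates are pixel centers scaled by
#' `pixelSize` (micrometres per pixel).
#'
#' @slot pixels integer/numeric matrix of 0/1 values, x-first indexing.
#' @slot pixelSize positive scalar, micrometres per pixel.
#' @slot time optional scalar, minutes post-plating (`NA` if unknown).
#'
#' @examples
#' m <- generateAggregateMask(radius = 30, tipAmplitude = 0, seed = 1)
#' m
#' elongation(m)
#' @aliases AggregateMask-class
#' @exportClass AggregateMask
setClass("AggregateMask",
  representation(pixels = "matrix", pixelSize = "numeric", time = "numeric"),
  prototype(time = NA_real_)
)

setValidity("AggregateMask", function(object) {
  p <- object@pixels
  if (!is.numeric(p) && !is.logical(p))
    return("pixels must be a numeric or logical matrix")
  if (!all(p %in% c(0, 1)))
    return("pixels must be binary (0/1)")
  if (sum(p) < 1)
    return("empty-mask: no foreground pixels")
  if (length(object@pixelSize) != 1L || is.na(object@pixelSize) ||
      object@pixelSize <= 0)
    return("pixelSize must be a single positive number")
  TRUE
})

#' @describeIn AggregateMask-class constructor; `keepLargest = TRUE` retains
#'   only the largest 4-connected foreground component (with a warning if a
#'   discarded component exceeds 10\% of the largest) and fills interior
#'   holes so the mask has exactly one simply-connected component.
#' @param pixels binary matrix (x-first).
#' @param pixelSize micrometres per pixel.
#' @param time acquisition time in minutes post-plating.
#' @param keepLargest logical; reduce multi-component masks to their largest
#'   component.
#' @param fillHoles logical; fill interior background holes.
#' @export
AggregateMask <- function(pixels, pixelSize = 1, time = NA_real_,
                          keepLargest = TRUE, fillHoles = TRUE) {
  pixels <- (pixels > 0) * 1
  if (sum(pixels) < 1) stop("empty-mask: no foreground pixels")
  if (keepLargest) pixels <- .largestComponent(pixels)
  if (fillHoles) pixels <- .fillHoles(pixels)
  new("AggregateMask", pixels = pixels, pixelSize = as.numeric(pixelSize),
      time = as.numeric(time))
}

setMethod("show", "AggregateMask", function(object) {
  d <- dim(object@pixels)
  cat("AggregateMask:", d[1], "x", d[2], "px @", object@pixelSize,
      "um/px;", sum(object@pixels), "foreground px")
  if (!is.na(object@time)) cat("; t =", object@time, "min")
  cat("\n")
})

#' EFDSet: elliptic Fourier descriptors of a closed contour
#'
#' Kuhl-Giardina elliptic Fourier coefficients of a closed contour under
#' arc-length parameterization. Each harmonic n carries four coefficients
#' (a_n, b_n, c_n, d_n), in micrometres; the DC term (A0, C0) locates the
#' contour centroid. No size/rotation normalization is applied, so absolute
#' physical scale is preserved.
#'
#' @slot dc numeric length-2, the (A0, C0) offset in micrometres.
#' @slot harmonics N x 4 matrix, columns a, b, c, d; row n is harmonic n.
#'
#' @aliases EFDSet-class
#' @exportClass EFDSet
setClass("EFDSet",
  representation(dc = "numeric", harmonics = "matrix")
)

setValidity("EFDSet", function(object) {
  if (length(object@dc) != 2L || any(!is.finite(object@dc)))
    return("dc must be two finite numbers (A0, C0)")
  h <- object@harmonics
  if (ncol(h) != 4L || nrow(h) < 1L)
    return("harmonics must be an N x 4 matrix with N >= 1")
  if (any(!is.finite(h)))
    return("harmonic coefficients must be finite")
  TRUE
})

setMethod("show", "EFDSet", function(object) {
  cat("EFDSet:", nrow(object@harmonics), "harmonics; centroid (",
      round(object@dc[1], 2), ",", round(object@dc[2], 2), ") um\n")
})

#' @describeIn EFDSet-class number of harmonics stored.
#' @param x an `EFDSet`.
#' @export
nHarmonics <- function(x) nrow(x@harmonics)

#' CellGraph: pruned Delaunay neighborhood graph over cell centroids
#'
#' Delaunay triangulation of labeled cell centroids (2-D or 3-D by input
#' dimensionality) with all edges longer than `pruneLength` removed. Edge
#' lengths are Euclidean distances in micrometres.
#'
#' @slot nodes integer vector of cell ids (one per cell, unique).
#' @slot edges data.frame with columns `from`, `to` (cell ids) and
#'   `length` (um); unordered pairs, no self-loops.
#' @slot pruneLength pruning threshold in micrometres.
#' @slot positions numeric matrix (cells x 2 or 3) of centroid coordinates.
#'
#' @aliases CellGraph-class
#' @exportClass CellGraph
setClass("CellGraph",
  representation(nodes = "integer", edges = "data.frame",
                 pruneLength = "numeric", positions = "matrix")
)

setValidity("CellGraph", function(object) {
  e <- object@edges
  if (!all(c("from", "to", "length") %in% names(e)))
    return("edges must have columns from, to, length")
  if (nrow(e) > 0) {
    if (any(e$from == e$to)) return("self-loops are not allowed")
    if (any(e$length > object@pruneLength + 1e-9))
      return("edge longer than pruneLength present")
    if (!all(e$from %in% object@nodes) || !all(e$to %in% object@nodes))
      return("edge endpoint not among nodes")
  }
  if (anyDuplicated(object@nodes)) return("node ids must be unique")
  TRUE
})

setMethod("show", "CellGraph", function(object) {
  cat("CellGraph:", length(object@nodes), "cells,", nrow(object@edges),
      "edges (Delaunay, pruned at", object@pruneLength, "um),",
      ncol(object@positions), "D\n")
})

#' TimelapseStack: an ordered fluorescence time-lapse
#'
#' Ordered list of congruent 2-D intensity frames with physical pixel size
#' (micrometres) and frame interval (minutes). Frames use the package's
#' x-first matrix convention.
#'
#' @slot frames list of numeric matrices, all the same dimension.
#' @slot pixelSize micrometres per pixel.
#' @slot dt minutes between consecutive frames.
#'
#' @aliases TimelapseStack-class
#' @exportClass TimelapseStack
setClass("TimelapseStack",
  representation(frames = "list", pixelSize = "numeric", dt = "numeric")
)

setValidity("TimelapseStack", function(object) {
  if (length(object@frames) < 2L)
    return("a time-lapse needs at least 2 frames")
  d <- dim(object@frames[[1]])
  for (f in object@frames) {
    if (!is.matrix(f) || !identical(dim(f), d))
      return("frames must be congruent matrices")
  }
  if (object@dt <= 0) return("dt must be positive")
  if (object@pixelSize <= 0) return("pixelSize must be positive")
  TRUE
})

#' @describeIn TimelapseStack-class constructor.
#' @param frames list of congruent numeric matrices (x-first).
#' @param pixelSize micrometres per pixel.
#' @param dt frame interval in minutes.
#' @export
TimelapseStack <- function(frames, pixelSize = 1, dt = 1) {
  new("TimelapseStack", frames = frames, pixelSize = as.numeric(pixelSize),
      dt = as.numeric(dt))
}

setMethod("show", "TimelapseStack", function(object) {
  d <- dim(object@frames[[1]])
  cat("TimelapseStack:", length(object@frames), "frames of", d[1], "x",
      d[2], "px @", object@pixelSize, "um/px, dt =", object@dt, "min\n")
})

#' @describeIn TimelapseStack-class number of frames.
#' @param x a `TimelapseStack`.
#' @export
nFrames <- function(x) length(x@frames)

#' VelocityField: a coarse-grained 2-D velocity field
#'
#' Velocity vectors on a regular grid of window centers, in micrometres per
#' minute. Nodes where the local structure tensor was ill-conditioned are
#' flagged invalid and carry `NA` velocities.
#'
#' @slot x,y numeric vectors of node center coordinates (um).
#' @slot vx,vy numeric matrices (length(x) x length(y)) of velocity
#'   components in um/min.
#' @slot valid logical matrix, same shape; `TRUE` where the estimate is
#'   well-conditioned.
#' @slot windowPx analysis window size in pixels.
#'
#' @aliases VelocityField-class
#' @exportClass VelocityField
setClass("VelocityField",
  representation(x = "numeric", y = "numeric", vx = "matrix", vy = "matrix",
                 valid = "matrix", windowPx = "integer")
)

setValidity("VelocityField", function(object) {
  d <- c(length(object@x), length(object@y))
  for (s in list(object@vx, object@vy, object@valid))
    if (!identical(dim(s), as.integer(d)))
      return("vx, vy, valid must be length(x) x length(y) matrices")
  if (any(!is.finite(object@vx[object@valid])) ||
      any(!is.finite(object@vy[object@valid])))
    return("velocities on valid nodes must be finite")
  TRUE
})

setMethod("show", "VelocityField", function(object) {
  cat("VelocityField:", length(object@x), "x", length(object@y),
      "nodes (window", object@windowPx, "px),",
      sum(object@valid), "valid\n")
})

#' @describeIn VelocityField-class velocities as a data.frame with one row
#'   per node (columns x_um, y_um, vx_um_min, vy_um_min, valid).
#' @param x a `VelocityField`.
#' @export
velocityTable <- function(x) {
  g <- expand.grid(x_um = x@x, y_um = x@y)
  data.frame(g, vx_um_min = as.vector(x@vx), vy_um_min = as.vector(x@vy),
             valid = as.vector(x@valid))
}
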