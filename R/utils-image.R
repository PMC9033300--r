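# Internal raster helpers. All matrices are x-first: m[i, j] is the pixel
# at x = i - 1, y = j - 1 (pixel units); physical coords are pixel centers
# times pixelSize.

.largestComponent <- function(pixels) {
  lab <- EBImage::bwlabel(pixels)  # 4-connected labeling
  n <- max(lab)
  if (n <= 1) return(pixels)
  sizes <- tabulate(lab[lab > 0], nbins = n)
  keep <- which.max(sizes)
  if (any(sizes[-keep] > 0.1 * sizes[keep]))
    warning("multiple foreground components of comparable size; keeping largest")
  (lab == keep) * 1
}

.fillHoles <- function(pixels) {
  as.matrix(EBImage::fillHull(pixels)) * 1
}

# Foreground pixel coordinates in um, one row per pixel.
.foregroundCoords <- function(mask) {
  idx <- which(mask@pixels > 0, arr.ind = TRUE)
  (idx - 1) * mask@pixelSize
}

# Centroid of the foreground, um.
.maskCentroid <- function(mask) {
  colMeans(.foregroundCoords(mask))
}

# Central second moments (uxx, uyy, uxy) of the foreground, um^2.
.maskMoments <- function(mask) {
  xy <- .foregroundCoords(mask)
  xc <- sweep(xy, 2, colMeans(xy))
  c(uxx = mean(xc[, 1]^2), uyy = mean(xc[, 2]^2),
    uxy = mean(xc[, 1] * xc[, 2]))
}

# Orientation (radians, in [0, pi)) of the major inertia axis.
.majorAxisAngle <- function(mask) {
  m <- .maskMoments(mask)
  ang <- 0.5 * atan2(2 * m["uxy"], m["uxx"] - m["uyy"])
  unname(ang %% pi)
}

# Bilinear sampling of matrix `img` at fractional pixel coordinates
# (x, y), 0-based. Out-of-range positions return `fill`.
.bilinearSample <- function(img, x, y, fill = 0) {
  nx <- nrow(img); ny <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  inb <- x0 >= 0 & y0 >= 0 & x0 <= nx - 2 & y0 <= ny - 2
  # clamp positions on the outer edge so x == nx-1 still samples
  edge <- (x >= nx - 1 & x <= nx - 1 + 1e-9) | (y >= ny - 1 & y <= ny - 1 + 1e-9)
  x0c <- pmin(pmax(x0, 0), nx - 2); y0c <- pmin(pmax(y0, 0), ny - 2)
  ok <- inb | (edge & x >= -1e-9 & y >= -1e-9 & x <= nx - 1 + 1e-9 & y <= ny - 1 + 1e-9)
  fxc <- pmin(pmax(x - x0c, 0), 1); fyc <- pmin(pmax(y - y0c, 0), 1)
  v <- (1 - fxc) * (1 - fyc) * img[cbind(x0c + 1, y0c + 1)] +
    fxc * (1 - fyc) * img[cbind(x0c + 2, y0c + 1)] +
    (1 - fxc) * fyc * img[cbind(x0c + 1, y0c + 2)] +
    fxc * fyc * img[cbind(x0c + 2, y0c + 2)]
  v[!ok] <- fill
  v
}

# Catmull-Rom bicubic sampling at fractional pixel coordinates (0-based).
# Out-of-range positions return `fill`. Used for warps, where bilinear
# smoothing would leave phase-dependent artifacts.
.cubicSample <- function(img, x, y, fill = 0) {
  nx <- nrow(img); ny <- ncol(img)
  ok <- x >= 1 & y >= 1 & x <= nx - 2 - 1e-9 & y <= ny - 2 - 1e-9
  xc <- pmin(pmax(x, 1), nx - 2 - 1e-9)
  yc <- pmin(pmax(y, 1), ny - 2 - 1e-9)
  x0 <- floor(xc); y0 <- floor(yc)
  fx <- xc - x0; fy <- yc - y0
  wgt <- function(f, k) {
    # Catmull-Rom kernel weights for offsets -1, 0, 1, 2
    switch(k + 2,
      ((-0.5 * f + 1) * f - 0.5) * f,
      (1.5 * f - 2.5) * f * f + 1,
      ((-1.5 * f + 2) * f + 0.5) * f,
      (0.5 * f - 0.5) * f * f)
  }
  v <- 0
  for (ky in -1:2) {
    row <- 0
    for (kx in -1:2)
      row <- row + wgt(fx, kx) * img[cbind(x0 + kx + 1, y0 + ky + 1)]
    v <- v + wgt(fy, ky) * row
  }
  v[!ok] <- fill
  v
}

# Inverse-mapped rigid warp: output pixel (x, y) takes the value of the
# input at R(-theta) (p - c) + c - t, i.e. the warp applies rotation theta
# (degrees, counter-clockwise about the image center) then translation t
# (pixels) to the image content.
.warpRigid <- function(img, rotationDeg, translationPx, fill = 0) {
  nx <- nrow(img); ny <- ncol(img)
  cx <- (nx - 1) / 2; cy <- (ny - 1) / 2
  th <- -rotationDeg * pi / 180
  g <- expand.grid(x = 0:(nx - 1), y = 0:(ny - 1))
  px <- g$x - translationPx[1] - cx
  py <- g$y - translationPx[2] - cy
  sx <- cos(th) * px - sin(th) * py + cx
  sy <- sin(th) * px + cos(th) * py + cy
  matrix(.cubicSample(img, sx, sy, fill = fill), nx, ny)
}

# Shoelace signed area of a closed polygon (rows = vertices, no repeat).
.polygonArea <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  j <- c(2:nrow(pts), 1)
  0.5 * sum(x * y[j] - x[j] * y)
}
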