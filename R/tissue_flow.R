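#' Suppress bright objects before optic flow
#'
#' Dead cells and fast-moving subcellular vesicles appear as bright spots,
#' far brighter than the cell contours the flow estimation relies on.
#' Pixels above a threshold are replaced by the median of sub-threshold
#' pixels in a local 15-px window (falling back to the global sub-threshold
#' median when the window holds none); sub-threshold pixels pass through
#' unchanged. A clipping alternative (`method = "clip"`) caps bright pixels
#' at the threshold instead.
#'
#' @param frame non-negative intensity matrix.
#' @param threshold absolute intensity threshold; if `NULL`, the
#'   `quantile` of the frame is used.
#' @param quantile quantile defining the threshold when `threshold` is
#'   `NULL` (default 0.995).
#' @param window side of the local median window in pixels (odd).
#' @param method `"median"` (local median replacement) or `"clip"`.
#' @return filtered matrix; maximum value never exceeds the threshold.
#' @export
prefilterBrightObjects <- function(frame, threshold = NULL, quantile = 0.995,
                                   window = 15, method = c("median", "clip")) {
  method <- match.arg(method)
  stopifnot(all(frame >= 0))
  if (is.null(threshold))
    threshold <- stats::quantile(frame, quantile, names = FALSE)
  if (threshold < min(frame))
    stop("threshold-too-low: every pixel is above the threshold")
  above <- which(frame > threshold, arr.ind = TRUE)
  if (nrow(above) == 0) return(frame)
  if (method == "clip") return(pmin(frame, threshold))
  out <- frame
  h <- (window - 1) %/% 2
  nx <- nrow(frame); ny <- ncol(frame)
  globalMed <- stats::median(frame[frame <= threshold])
  for (k in seq_len(nrow(above))) {
    i <- above[k, 1]; j <- above[k, 2]
    w <- frame[max(1, i - h):min(nx, i + h), max(1, j - h):min(ny, j + h)]
    sub <- w[w <= threshold]
    out[i, j] <- if (length(sub)) stats::median(sub) else globalMed
  }
  out
}

# ---- phase correlation -----------------------------------------------

.hann2 <- function(nx, ny) {
  wx <- 0.5 - 0.5 * cos(2 * pi * (0:(nx - 1)) / (nx - 1))
  wy <- 0.5 - 0.5 * cos(2 * pi * (0:(ny - 1)) / (ny - 1))
  outer(wx, wy)
}

# Subpixel peak location of a correlation surface via parabolic fit.
.subpixelPeak <- function(r) {
  nx <- nrow(r); ny <- ncol(r)
  p <- which(r == max(r), arr.ind = TRUE)[1, ]
  parab <- function(m, c0, cp) {
    den <- m - 2 * c0 + cp
    if (abs(den) < 1e-12) 0 else 0.5 * (m - cp) / den
  }
  ix <- p[1]; iy <- p[2]
  xm <- r[(ix - 2) %% nx + 1, iy]; xp <- r[ix %% nx + 1, iy]
  ym <- r[ix, (iy - 2) %% ny + 1]; yp <- r[ix, iy %% ny + 1]
  sx <- ix - 1 + parab(xm, r[ix, iy], xp)
  sy <- iy - 1 + parab(ym, r[ix, iy], yp)
  if (sx > nx / 2) sx <- sx - nx
  if (sy > ny / 2) sy <- sy - ny
  c(sx, sy)
}

# Translation d with b(x) ~= a(x - d), by windowed phase correlation.
# periodicX: skip the x-axis window when that axis is genuinely periodic
# (the angular axis of a polar resampling).
.phaseCorrShift <- function(a, b, periodicX = FALSE) {
  wx <- if (periodicX) rep(1, nrow(a)) else
    0.5 - 0.5 * cos(2 * pi * (0:(nrow(a) - 1)) / (nrow(a) - 1))
  wy <- 0.5 - 0.5 * cos(2 * pi * (0:(ncol(a) - 1)) / (ncol(a) - 1))
  w <- outer(wx, wy)
  fa <- stats::fft(a * w); fb <- stats::fft(b * w)
  cp <- fa * Conj(fb)
  cp <- cp / pmax(Mod(cp), 1e-12)
  r <- Re(stats::fft(cp, inverse = TRUE))
  -.subpixelPeak(r)
}

# Polar resampling of the centered log-magnitude spectrum: rows = angle
# over [0, 180), cols = radius.
.polarSpectrum <- function(img, nTheta = 360, nR = 96) {
  nx <- nrow(img); ny <- ncol(img)
  f <- stats::fft(img * .hann2(nx, ny))
  m <- Mod(f)
  # fftshift
  m <- m[c((nx %/% 2 + 1):nx, 1:(nx %/% 2)), c((ny %/% 2 + 1):ny, 1:(ny %/% 2))]
  m <- log1p(m)
  cx <- nx %/% 2; cy <- ny %/% 2
  th <- seq(0, pi, length.out = nTheta + 1)[1:nTheta]
  rr <- seq(4, 0.45 * min(nx, ny), length.out = nR)
  g <- expand.grid(th = th, r = rr)
  sx <- cx + g$r * cos(g$th)
  sy <- cy + g$r * sin(g$th)
  matrix(.bilinearSample(m, sx, sy), nTheta, nR)
}

# Rotation (degrees) such that b is a rotated by +rot, via phase
# correlation along the angular axis of the polar spectra. A second pass
# on the derotated frame removes most of the angular-bin interpolation
# bias.
.phaseCorrRotation <- function(a, b, nTheta = 720, refine = TRUE) {
  est <- function(x, y) {
    pa <- .polarSpectrum(x, nTheta = nTheta)
    pb <- .polarSpectrum(y, nTheta = nTheta)
    .phaseCorrShift(pa, pb, periodicX = TRUE)[1] * 180 / nTheta
  }
  rot <- est(a, b)
  if (refine && abs(rot) > 1e-6)
    rot <- rot + est(a, .warpRigid(b, -rot, c(0, 0)))
  rot
}

# Gauss-Newton refinement of a rigid coordinate map aligned(x) =
# f(R_rot (x - c) + c + u) toward ref. rot in radians. Phase correlation
# provides the initialization; this removes its interpolation-scale bias.
.refineRigidStep <- function(ref, f, rot0, u0, maxIter = 15, tol = 1e-5,
                             fitRotation = TRUE) {
  nx <- nrow(f); ny <- ncol(f)
  cx <- (nx - 1) / 2; cy <- (ny - 1) / 2
  g <- .gradients(f)
  m <- 8  # margin
  xs <- seq(m, nx - 1 - m, by = 2); ys <- seq(m, ny - 1 - m, by = 2)
  gr <- expand.grid(x = xs, y = ys)
  refv <- .bilinearSample(ref, gr$x, gr$y)
  rot <- rot0; u <- u0
  for (it in seq_len(maxIter)) {
    cr <- cos(rot); sr <- sin(rot)
    rx <- gr$x - cx; ry <- gr$y - cy
    px <- cr * rx - sr * ry + cx + u[1]
    py <- sr * rx + cr * ry + cy + u[2]
    inb <- px >= 1 & py >= 1 & px <= nx - 2 & py <= ny - 2
    fv <- .bilinearSample(f, px, py)
    gx <- .bilinearSample(g$x, px, py)
    gy <- .bilinearSample(g$y, px, py)
    e <- (fv - refv)[inb]
    dpx <- (-sr * rx - cr * ry)[inb]
    dpy <- (cr * rx - sr * ry)[inb]
    J <- if (fitRotation)
      cbind(gx[inb] * dpx + gy[inb] * dpy, gx[inb], gy[inb])
    else cbind(gx[inb], gy[inb])
    step <- tryCatch(solve(crossprod(J), crossprod(J, e)),
                     error = function(err) NULL)
    if (is.null(step)) break
    if (fitRotation) {
      rot <- rot - step[1]; u <- u - step[2:3]
    } else u <- u - step[1:2]
    if (max(abs(step)) < tol) break
  }
  # final residual, for choosing between alternative initializations
  cr <- cos(rot); sr <- sin(rot)
  px <- cr * (gr$x - cx) - sr * (gr$y - cy) + cx + u[1]
  py <- sr * (gr$x - cx) + cr * (gr$y - cy) + cy + u[2]
  inb <- px >= 1 & py >= 1 & px <= nx - 2 & py <= ny - 2
  sse <- mean(((.bilinearSample(f, px, py) - refv)[inb])^2)
  list(rot = rot, u = u, sse = sse)
}

#' Rigid registration of a time-lapse stack
#'
#' Estimates, for every frame, the rigid transform (rotation about the
#' image center plus translation) relating it to frame 1, and resamples the
#' frame into frame 1's coordinates. Translation is estimated by windowed
#' phase correlation with subpixel parabolic peak interpolation; rotation
#' by phase correlation along the angular axis of the polar-resampled
#' spectrum magnitude (translation-invariant). Registration removes the
#' aggregate's global rotations and drift so that subsequent optic flow
#' reflects internal tissue motion only.
#'
#' @param stack a [TimelapseStack-class].
#' @param estimateRotation set `FALSE` to register translations only.
#' @return list with `stack` (registered [TimelapseStack-class]) and
#'   `transforms` (data.frame: frame, rotation_deg, dx_px, dy_px giving
#'   each frame's motion relative to frame 1).
#' @export
registerRigid <- function(stack, estimateRotation = TRUE) {
  stopifnot(is(stack, "TimelapseStack"))
  n <- nFrames(stack)
  frames <- vector("list", n)
  frames[[1]] <- stack@frames[[1]]
  tf <- data.frame(frame = seq_len(n), rotation_deg = 0, dx_px = 0, dy_px = 0)
  rotC <- 0; uC <- c(0, 0)  # cumulative frame-0 -> frame-i coordinate map
  rotMat <- function(deg) {
    a <- deg * pi / 180
    matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  }
  for (i in 2:n) {
    prev <- stack@frames[[i - 1]]; f <- stack@frames[[i]]
    if (stats::sd(f) < 1e-9 || stats::sd(prev) < 1e-9) {
      warning("featureless frame ", i, "; identity step assumed")
      dRot <- 0; dSh <- c(0, 0)
    } else {
      # consecutive-pair estimation keeps per-step errors small; the
      # cumulative transform is composed analytically so each frame is
      # resampled exactly once
      dRot <- if (estimateRotation) .phaseCorrRotation(prev, f) else 0
      der <- if (abs(dRot) > 1e-6) .warpRigid(f, -dRot, c(0, 0)) else f
      dSh <- .phaseCorrShift(prev, der)
      ref0 <- .refineRigidStep(prev, f, dRot * pi / 180,
                               as.vector(rotMat(dRot) %*% dSh),
                               fitRotation = estimateRotation)
      if (estimateRotation && abs(dRot) > 0.5) {
        # guard against false peaks in the angular correlation: also
        # refine from a translation-only initialization and keep the
        # lower-residual solution
        alt <- .refineRigidStep(prev, f, 0, .phaseCorrShift(prev, f))
        if (alt$sse < ref0$sse) ref0 <- alt
      }
      dRot <- ref0$rot * 180 / pi
      dSh <- as.vector(rotMat(-dRot) %*% ref0$u)
    }
    u <- as.vector(rotMat(dRot) %*% dSh)
    uC <- as.vector(rotMat(dRot) %*% uC) + u
    rotC <- rotC + dRot
    dTot <- as.vector(rotMat(-rotC) %*% uC)
    frames[[i]] <- .warpRigid(f, -rotC, -dTot, fill = NA_real_)
    tf$rotation_deg[i] <- rotC; tf$dx_px[i] <- dTot[1]; tf$dy_px[i] <- dTot[2]
  }
  list(stack = TimelapseStack(frames, stack@pixelSize, stack@dt),
       transforms = tf)
}

# ---- Lucas-Kanade flow ------------------------------------------------

#' Analysis window size from the cell diameter
#'
#' The flow window covers a square of 2 cells by 2 cells:
#' `round(2 * cellDiameter / pixelSize)` pixels, clamped to at least 8.
#'
#' @param cellDiameter typical cell diameter in micrometres (default 12).
#' @param pixelSize micrometres per pixel.
#' @return integer window side in pixels.
#' @examples
#' windowFromCellSize(12, 0.75)  # 32
#' @export
windowFromCellSize <- function(cellDiameter = 12, pixelSize) {
  stopifnot(cellDiameter > 0, pixelSize > 0)
  max(8L, as.integer(round(2 * cellDiameter / pixelSize)))
}

# Antialiased factor-2 downsampling; NA pixels (outside the registered
# support) are excluded from the blur and re-imposed, slightly dilated.
.downsample2 <- function(img) {
  na <- !is.finite(img)
  z <- img
  if (any(na)) z[na] <- mean(img[!na])
  s <- as.matrix(EBImage::gblur(z, sigma = 1))
  if (any(na)) {
    spread <- as.matrix(EBImage::gblur(na * 1, sigma = 1)) > 1e-3
    s[spread] <- NA_real_
  }
  s[seq(1, nrow(s), by = 2), seq(1, ncol(s), by = 2)]
}

.gradients <- function(img) {
  nx <- nrow(img); ny <- ncol(img)
  gx <- img; gy <- img
  gx[2:(nx - 1), ] <- (img[3:nx, ] - img[1:(nx - 2), ]) / 2
  gx[c(1, nx), ] <- 0
  gy[, 2:(ny - 1)] <- (img[, 3:ny] - img[, 1:(ny - 2)]) / 2
  gy[, c(1, ny)] <- 0
  list(x = gx, y = gy)
}

# One-level iterative LK at a set of window centers (0-based px coords).
# d0: initial displacements (n x 2). Returns displacements + validity.
.lkLevel <- function(I, J, centers, win, d0, maxIter = 20, tol = 0.01,
                     condMax = 1e4) {
  g <- .gradients(I)
  h <- win / 2
  off <- expand.grid(ox = seq(-h + 0.5, h - 0.5, by = 1),
                     oy = seq(-h + 0.5, h - 0.5, by = 1))
  n <- nrow(centers)
  d <- d0; valid <- rep(TRUE, n)
  for (k in seq_len(n)) {
    px <- centers[k, 1] + off$ox
    py <- centers[k, 2] + off$oy
    iv <- .bilinearSample(I, px, py, fill = NA_real_)
    ix <- .bilinearSample(g$x, px, py, fill = NA_real_)
    iy <- .bilinearSample(g$y, px, py, fill = NA_real_)
    m0 <- is.finite(iv) & is.finite(ix) & is.finite(iy)
    if (mean(m0) < 0.7) { valid[k] <- FALSE; d[k, ] <- NA_real_; next }
    dk <- d[k, ]
    if (any(!is.finite(dk))) dk <- c(0, 0)
    ok <- TRUE
    for (it in seq_len(maxIter)) {
      if (any(abs(dk) > win)) { ok <- FALSE; break }
      jv <- .bilinearSample(J, px + dk[1], py + dk[2], fill = NA_real_)
      m <- m0 & is.finite(jv)
      # windows partly outside the support keep their in-bounds pixels,
      # provided enough of the window remains
      if (mean(m) < 0.7) { ok <- FALSE; break }
      gxx <- sum(ix[m]^2); gxy <- sum(ix[m] * iy[m]); gyy <- sum(iy[m]^2)
      tr <- gxx + gyy; det <- gxx * gyy - gxy^2
      disc <- sqrt(max(tr^2 / 4 - det, 0))
      l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
      if (l2 <= 0 || l1 / l2 > condMax) { ok <- FALSE; break }
      e <- (iv - jv)[m]
      b1 <- sum(ix[m] * e); b2 <- sum(iy[m] * e)
      step <- c(gyy * b1 - gxy * b2, -gxy * b1 + gxx * b2) / det
      dk <- dk + step
      if (sqrt(sum(step^2)) < tol) break
    }
    if (!ok) { valid[k] <- FALSE; dk <- c(NA_real_, NA_real_) }
    d[k, ] <- dk
  }
  list(d = d, valid = valid)
}

#' Pyramidal Lucas-Kanade optic flow on a registered stack
#'
#' Estimates, for every consecutive frame pair, the local displacement of
#' each analysis window by iterative Lucas-Kanade least squares, refined
#' coarse-to-fine over an image pyramid (factor-2 downsampling with
#' Gaussian antialiasing; the default of 2 levels means full plus half
#' resolution). Windows whose structure tensor is ill-conditioned
#' (condition number above `condMax`) are flagged invalid. Displacements
#' are converted to micrometres per minute using the stack's pixel size
#' and frame interval.
#'
#' @param stack a registered, prefiltered [TimelapseStack-class].
#' @param windowPx analysis window side in pixels (>= 8); see
#'   [windowFromCellSize()].
#' @param pyramidLevels number of pyramid levels (default 2).
#' @param stride node spacing in pixels (default `windowPx / 2`, 50\%
#'   overlap).
#' @param maxIter,tol Lucas-Kanade iteration cap and convergence threshold
#'   (pixels).
#' @param condMax structure-tensor condition-number cutoff for validity.
#' @return list of [VelocityField-class], one per consecutive frame pair.
#' @export
kltFlow <- function(stack, windowPx, pyramidLevels = 2,
                    stride = windowPx %/% 2, maxIter = 20, tol = 0.01,
                    condMax = 1e4) {
  stopifnot(is(stack, "TimelapseStack"), windowPx >= 8)
  dims <- dim(stack@frames[[1]])
  if (windowPx > min(dims)) stop("window-too-large")
  h <- windowPx / 2
  cx <- seq(h, dims[1] - h, by = stride)
  cy <- seq(h, dims[2] - h, by = stride)
  centers <- as.matrix(expand.grid(x = cx, y = cy))
  scale <- stack@pixelSize / stack@dt
  out <- vector("list", nFrames(stack) - 1)
  for (p in seq_len(nFrames(stack) - 1)) {
    I <- stack@frames[[p]]; J <- stack@frames[[p + 1]]
    pyrI <- list(I); pyrJ <- list(J)
    for (l in seq_len(pyramidLevels - 1)) {
      pyrI[[l + 1]] <- .downsample2(pyrI[[l]])
      pyrJ[[l + 1]] <- .downsample2(pyrJ[[l]])
    }
    d <- matrix(0, nrow(centers), 2)
    valid <- rep(TRUE, nrow(centers))
    for (l in pyramidLevels:1) {
      f <- 2^(l - 1)
      lev <- .lkLevel(pyrI[[l]], pyrJ[[l]], centers / f,
                      max(windowPx / f, 4), d / f,
                      maxIter = maxIter, tol = tol / f, condMax = condMax)
      dNew <- lev$d * f
      # keep coarse estimate where the fine level was degenerate
      bad <- !lev$valid
      dNew[bad, ] <- if (l == pyramidLevels) NA_real_ else d[bad, ]
      valid <- valid & lev$valid
      d <- dNew
    }
    d[!valid, ] <- NA_real_
    out[[p]] <- new("VelocityField",
                    x = cx * stack@pixelSize, y = cy * stack@pixelSize,
                    vx = matrix(d[, 1] * scale, length(cx), length(cy)),
                    vy = matrix(d[, 2] * scale, length(cx), length(cy)),
                    valid = matrix(valid, length(cx), length(cy)),
                    windowPx = as.integer(windowPx))
  }
  out
}
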