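# Independent oracles used across the suite. Each re-derives its result
# by a different route than the implementation (dense quadrature, brute
# enumeration, per-pixel bookkeeping, breadth-first search).

# Kuhl-Giardina coefficients by dense numerical quadrature of the Fourier
# integrals along the arc-length-parameterized polygon.
oracleEfd <- function(contour, nh, ns = 4096) {
  nxt <- c(2:nrow(contour), 1)
  seg <- sqrt(rowSums((contour[nxt, ] - contour)^2))
  tcum <- c(0, cumsum(seg))
  T <- tcum[length(tcum)]
  ts <- seq(0, T, length.out = ns + 1)[-(ns + 1)]
  idx <- findInterval(ts, tcum, rightmost.closed = TRUE)
  idx[idx > nrow(contour)] <- nrow(contour)
  fr <- (ts - tcum[idx]) / seg[idx]
  x <- contour[idx, 1] + fr * (contour[nxt, ][idx, 1] - contour[idx, 1])
  y <- contour[idx, 2] + fr * (contour[nxt, ][idx, 2] - contour[idx, 2])
  t(sapply(seq_len(nh), function(n) {
    w <- 2 * pi * n * ts / T
    c(2 * mean(x * cos(w)), 2 * mean(x * sin(w)),
      2 * mean(y * cos(w)), 2 * mean(y * sin(w)))
  }))
}

# Two-half contrast by explicit per-pixel bookkeeping.
oracleHalfContrast <- function(mask, intensity, angleDeg) {
  fg <- which(mask@pixels > 0, arr.ind = TRUE)
  xy <- (fg - 1) * mask@pixelSize
  cen <- c(mean(xy[, 1]), mean(xy[, 2]))
  th <- angleDeg * pi / 180
  n <- c(-sin(th), cos(th))
  side <- (xy[, 1] - cen[1]) * n[1] + (xy[, 2] - cen[2]) * n[2] >= 0
  v <- intensity[fg]
  m <- sort(c(mean(v[side]), mean(v[!side])), decreasing = TRUE)
  if (sum(m) == 0) 0 else (m[1] - m[2]) / (m[1] + m[2])
}

# Brute-force Delaunay edges: enumerate all (d+1)-point simplices and keep
# those whose circumsphere contains no other point.
bruteDelaunayEdges <- function(pos) {
  n <- nrow(pos); d <- ncol(pos)
  combs <- utils::combn(n, d + 1)
  edges <- NULL
  for (k in seq_len(ncol(combs))) {
    s <- combs[, k]
    V <- pos[s, , drop = FALSE]
    A <- 2 * sweep(V[-1, , drop = FALSE], 2, V[1, ])
    b <- rowSums(V[-1, , drop = FALSE]^2) - sum(V[1, ]^2)
    ctr <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(ctr)) next
    r2 <- sum((ctr - V[1, ])^2)
    others <- setdiff(seq_len(n), s)
    d2 <- rowSums(sweep(pos[others, , drop = FALSE], 2, ctr)^2)
    if (all(d2 > r2 * (1 - 1e-9))) {
      pr <- utils::combn(s, 2)
      edges <- rbind(edges, cbind(pmin(pr[1, ], pr[2, ]),
                                  pmax(pr[1, ], pr[2, ])))
    }
  }
  unique(edges)
}

edgeKey <- function(e) sort(paste(e[, 1], e[, 2]))

# Connected components by breadth-first search over an edge list.
bfsComponents <- function(ids, edgeFrom, edgeTo) {
  comp <- stats::setNames(rep(NA_integer_, length(ids)), as.character(ids))
  adj <- split(c(as.character(edgeTo), as.character(edgeFrom)),
               c(as.character(edgeFrom), as.character(edgeTo)))
  cc <- 0
  for (id in as.character(ids)) {
    if (!is.na(comp[id])) next
    cc <- cc + 1
    queue <- id
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[cur])) next
      comp[cur] <- cc
      queue <- c(queue, setdiff(intersect(adj[[cur]], as.character(ids)),
                                names(comp)[!is.na(comp)]))
    }
  }
  comp
}

# Random cell table with k types scattered uniformly in a box.
randomCellTable <- function(n, dim = 2, types = c("A", "B", "C"),
                            extent = 80) {
  pos <- matrix(stats::runif(n * dim, 0, extent), n, dim)
  tb <- data.frame(cell_id = seq_len(n), x = pos[, 1], y = pos[, 2])
  if (dim == 3) tb$z <- pos[, 3]
  tb$cell_type <- factor(sample(types, n, replace = TRUE), levels = types)
  tb
}

# Disk mask plus an intensity field, used by polarization tests.
diskMask <- function(r = 30, px = 1) {
  n <- 2 * r + 5
  c0 <- (n - 1) / 2
  g <- expand.grid(x = 0:(n - 1), y = 0:(n - 1))
  AggregateMask(matrix(((g$x - c0)^2 + (g$y - c0)^2 <= r^2) * 1, n, n),
                pixelSize = px)
}
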