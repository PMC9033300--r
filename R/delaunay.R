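# Delaunay edge extraction. 2-D goes through deldir; 3-D uses an
# incremental Bowyer-Watson triangulation implemented here (no 3-D
# Delaunay package is available in the supported dependency set).

.delaunayEdges <- function(pos) {
  d <- ncol(pos)
  ctr <- sweep(pos, 2, colMeans(pos))
  if (qr(ctr)$rank < d)
    stop("degenerate-configuration: points are collinear/coplanar for their dimension")
  if (d == 2) {
    dd <- deldir::deldir(pos[, 1], pos[, 2], suppressMsge = TRUE)
    cbind(pmin(dd$delsgs$ind1, dd$delsgs$ind2),
          pmax(dd$delsgs$ind1, dd$delsgs$ind2))
  } else if (d == 3) {
    .bowyerWatsonEdges(pos)
  } else stop("only 2-D and 3-D point sets are supported")
}

# Circumcenter^2 radius of a d-simplex; returns c(center, r2).
.circumsphere <- function(V) {
  d <- ncol(V)
  A <- 2 * sweep(V[-1, , drop = FALSE], 2, V[1, ])
  b <- rowSums(V[-1, , drop = FALSE]^2) - sum(V[1, ]^2)
  ctr <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(ctr)) return(c(rep(Inf, d), Inf))
  c(ctr, sum((ctr - V[1, ])^2))
}

# Incremental Bowyer-Watson Delaunay triangulation in d dimensions,
# returning the unique edge index pairs among the input points. Intended
# for the moderate point counts of labeled-cell tables (hundreds).
.bowyerWatsonEdges <- function(pts) {
  n0 <- nrow(pts); d <- ncol(pts)
  ctr <- colMeans(pts)
  sc <- max(apply(pts, 2, function(v) diff(range(v))), 1e-9)
  P <- sweep(pts, 2, ctr) / sc
  # enclosing super-simplex, far larger than the unit-scaled cloud
  M <- 100
  super <- rbind(rep(-M, d))
  for (i in seq_len(d)) {
    v <- rep(-M, d); v[i] <- v[i] + 3 * M * d
    super <- rbind(super, v)
  }
  V <- rbind(P, super)
  simpl <- matrix(n0 + seq_len(d + 1), nrow = 1)
  cs <- matrix(.circumsphere(V[simpl[1, ], , drop = FALSE]), nrow = 1)
  for (i in seq_len(n0)) {
    p <- V[i, ]
    dist2 <- rowSums(sweep(cs[, seq_len(d), drop = FALSE], 2, p)^2)
    bad <- which(dist2 < cs[, d + 1] * (1 + 1e-9) + 1e-12)
    if (length(bad) == 0) next  # numerically outside everything; skip
    # boundary facets = facets of bad simplices seen exactly once
    facets <- do.call(rbind, lapply(bad, function(s) {
      t(vapply(seq_len(d + 1),
               function(k) sort(simpl[s, -k]), integer(d)))
    }))
    key <- apply(facets, 1, paste, collapse = ",")
    once <- facets[key %in% names(which(table(key) == 1)), , drop = FALSE]
    simpl <- simpl[-bad, , drop = FALSE]
    cs <- cs[-bad, , drop = FALSE]
    newS <- cbind(once, i)
    newC <- t(apply(newS, 1, function(s) .circumsphere(V[s, , drop = FALSE])))
    simpl <- rbind(simpl, newS)
    cs <- rbind(cs, newC)
  }
  real <- simpl[apply(simpl <= n0, 1, all), , drop = FALSE]
  if (nrow(real) == 0)
    stop("degenerate-configuration: triangulation failed")
  pairs <- utils::combn(d + 1, 2)
  e <- do.call(rbind, lapply(seq_len(nrow(real)), function(r) {
    s <- real[r, ]
    cbind(pmin(s[pairs[1, ]], s[pairs[2, ]]),
          pmax(s[pairs[1, ]], s[pairs[2, ]]))
  }))
  unique(e)
}
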