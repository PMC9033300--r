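test_that("graph pruning follows the 12-um rule on hand-built configurations", {
  # near-collinear triple at x = 0, 10, 20: path graph, long chord pruned
  cells <- data.frame(cell_id = 1:3, x = c(0, 10, 20),
                      y = c(0, 0.01, 0), cell_type = factor(rep("A", 3)))
  g <- buildCellGraph(cells, pruneLength = 12)
  expect_equal(nrow(g@edges), 2)
  expect_false(any(g@edges$from == 1 & g@edges$to == 3))

  # 13-um pair is "more than 12 um": pruned
  cells2 <- data.frame(cell_id = 1:4, x = c(0, 13, 100, 100),
                       y = c(0, 0, 0, 90), cell_type = factor(rep("A", 4)))
  g2 <- buildCellGraph(cells2, pruneLength = 12)
  expect_false(any((g2@edges$from == 1 & g2@edges$to == 2) |
                   (g2@edges$from == 2 & g2@edges$to == 1)))
  # exactly 12 um is kept
  cells3 <- data.frame(cell_id = 1:3, x = c(0, 12, 6), y = c(0, 0, 40),
                       cell_type = factor(rep("A", 3)))
  g3 <- buildCellGraph(cells3, pruneLength = 12)
  expect_true(any(g3@edges$from == 1 & g3@edges$to == 2))
})

test_that("pruned edge sets equal the brute-force Delaunay oracle in 2-D and 3-D", {
  for (seed in 1:12) {
    set.seed(seed)
    n <- sample(15:35, 1)
    tb <- randomCellTable(n, dim = 2)
    g <- buildCellGraph(tb, pruneLength = 25)
    pos <- cbind(tb$x, tb$y)
    ora <- bruteDelaunayEdges(pos)
    len <- sqrt(rowSums((pos[ora[, 1], ] - pos[ora[, 2], ])^2))
    expect_identical(edgeKey(g@edges[, c("from", "to")]),
                     edgeKey(ora[len <= 25, , drop = FALSE]))
  }
  for (seed in 1:6) {
    set.seed(100 + seed)
    u <- matrix(rnorm(3 * 50), 50)
    pos <- u / sqrt(rowSums(u^2)) * 30 * runif(50)^(1/3)  # 60-um ball
    tb <- data.frame(cell_id = 1:50, x = pos[, 1], y = pos[, 2], z = pos[, 3],
                     cell_type = factor(rep("A", 50)))
    g <- buildCellGraph(tb, pruneLength = 18)
    ora <- bruteDelaunayEdges(pos)
    len <- sqrt(rowSums((pos[ora[, 1], ] - pos[ora[, 2], ])^2))
    expect_identical(edgeKey(g@edges[, c("from", "to")]),
                     edgeKey(ora[len <= 18, , drop = FALSE]))
  }
})

test_that("the graph is invariant under rigid transforms of the positions", {
  cells <- generateCellPopulation(coreCount = 40, shellCount = 15, seed = 8)
  g0 <- buildCellGraph(cells)
  th <- 0.6
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  pos <- as.matrix(cells[, c("x", "y", "z")]) %*% t(R)
  cells2 <- cells
  cells2$x <- pos[, 1] + 13; cells2$y <- pos[, 2] - 7; cells2$z <- pos[, 3] + 2
  g1 <- buildCellGraph(cells2)
  expect_identical(edgeKey(g0@edges[, c("from", "to")]),
                   edgeKey(g1@edges[, c("from", "to")]))
})

test_that("degenerate configurations and unknown types are rejected", {
  flat <- data.frame(cell_id = 1:5, x = 1:5, y = 2 * (1:5),
                     cell_type = factor(rep("A", 5)))
  expect_error(buildCellGraph(flat), "degenerate-configuration")
  cells <- randomCellTable(20, dim = 2)
  g <- buildCellGraph(cells, pruneLength = 40)
  expect_error(componentStats(g, cells, "Z"), "unknown-type")
})

test_that("component statistics match trivial clusters and the BFS oracle", {
  # two 10-cell clusters 100 um apart
  set.seed(21)
  mkCluster <- function(cx, id0) data.frame(
    cell_id = id0 + 1:10, x = cx + runif(10, 0, 14), y = runif(10, 0, 14),
    cell_type = factor(rep("A", 10), levels = c("A", "B")))
  cells <- rbind(mkCluster(0, 0), mkCluster(100, 10))
  g <- buildCellGraph(cells, pruneLength = 12)
  cs <- componentStats(g, cells, "A")
  expect_gte(cs$n_components, 2)
  expect_true(all(table(bfsComponents(cells$cell_id, g@edges$from,
                                      g@edges$to)) <= 10))
  expect_equal(componentStats(g, cells, "B"),
               list(n_components = 0L, largest_component_size = 0L))

  # seeded island+shell population against the BFS oracle, per type
  cells <- generateCellPopulation(coreCount = 60, shellCount = 25, seed = 11)
  g <- buildCellGraph(cells)
  for (tp in levels(cells$cell_type)) {
    ids <- cells$cell_id[cells$cell_type == tp]
    if (length(ids) == 0) next
    sub <- g@edges[g@edges$from %in% ids & g@edges$to %in% ids, ]
    comp <- bfsComponents(ids, sub$from, sub$to)
    cs <- componentStats(g, cells, tp)
    expect_identical(cs$n_components, as.integer(max(comp)))
    expect_identical(cs$largest_component_size,
                     as.integer(max(table(comp))))
  }
})

test_that("majority-neighborhood typing matches hand cases and the counting oracle", {
  # star: center A with neighbors A, A, B within range
  cells <- data.frame(cell_id = 1:4, x = c(0, 8, -8, 0), y = c(0, 1, 1, 9),
                      cell_type = factor(c("A", "A", "A", "B"),
                                         levels = c("A", "B")))
  nt <- neighborhoodTyping(buildCellGraph(cells, pruneLength = 12), cells)
  expect_equal(nt$perCell$majority_type[1], "A")
  expect_true(nt$perCell$is_homotypic[1])

  cells$cell_type <- factor(c("A", "B", "B", "A"), levels = c("A", "B"))
  nt2 <- neighborhoodTyping(buildCellGraph(cells, pruneLength = 12), cells)
  expect_equal(nt2$perCell$majority_type[1], "B")
  expect_false(nt2$perCell$is_homotypic[1])

  # seeded random configurations vs explicit neighbor counting
  for (seed in 1:8) {
    set.seed(300 + seed)
    tb <- randomCellTable(100, dim = 2, extent = 120)
    g <- buildCellGraph(tb, pruneLength = 20)
    nt <- neighborhoodTyping(g, tb)
    typeOf <- setNames(as.character(tb$cell_type), tb$cell_id)
    for (k in seq_len(nrow(tb))) {
      id <- tb$cell_id[k]
      nb <- c(g@edges$to[g@edges$from == id], g@edges$from[g@edges$to == id])
      expct <- if (length(nb) == 0) "isolated" else {
        tab <- table(typeOf[as.character(nb)])
        top <- names(tab)[tab == max(tab)]
        if (length(top) > 1) "tie" else top
      }
      expect_identical(nt$perCell$majority_type[k], expct)
      expect_identical(nt$perCell$is_homotypic[k],
                       expct == as.character(tb$cell_type[k]))
      expect_identical(nt$perCell$degree[k], length(nb))
    }
  }
})

test_that("the island+shell population reproduces the compact-core statistics", {
  cells <- syntheticPreset("island_shell", seed = 11)
  g <- buildCellGraph(cells)
  nt <- neighborhoodTyping(g, cells)
  core <- nt$perType[nt$perType$cell_type == "Ecad+Tbra+", ]
  shell <- nt$perType[nt$perType$cell_type == "Tbra+", ]
  expect_gt(core$largest_component_size / core$n_cells, 0.9)
  expect_gt(core$n_homotypic / core$n_cells, 0.8)
  expect_gt(shell$n_components, 5)
  # homotypic/tie/isolated counts partition each type
  het <- vapply(split(nt$perCell, nt$perCell$cell_type), function(d)
    sum(!d$is_homotypic & !d$majority_type %in% c("tie", "isolated")),
    numeric(1))
  expect_equal(nt$perType$n_homotypic + nt$perType$n_tie +
                 nt$perType$n_isolated + as.numeric(het[nt$perType$cell_type]),
               nt$perType$n_cells)
})

test_that("radial profiles: fractions, KDE normalization, and the two-shell fixture", {
  set.seed(5)
  mkRing <- function(n, r0, r1, type, id0) {
    th <- runif(n, 0, 2 * pi); r <- sqrt(runif(n, r0^2, r1^2))
    data.frame(cell_id = id0 + 1:n, x = r * cos(th), y = r * sin(th),
               cell_type = factor(type, levels = c("A", "B")))
  }
  cells <- rbind(mkRing(500, 0, 0.5, "A", 0), mkRing(500, 0.5, 1, "B", 500))
  rp <- radialProfile(cells, origin = c(0, 0), normalize = TRUE, bins = 10)
  # fractions match direct counting and sum to 1
  r <- sqrt(cells$x^2 + cells$y^2) / max(sqrt(cells$x^2 + cells$y^2))
  bins <- pmin(findInterval(r, seq(0, 1, 0.1), rightmost.closed = TRUE), 10)
  for (b in 1:10) {
    inb <- bins == b
    expect_equal(rp$bins$A[b], mean(cells$cell_type[inb] == "A"))
    expect_equal(rp$bins$n[b], sum(inb))
    expect_equal(rp$bins$A[b] + rp$bins$B[b], 1)
  }
  # step at r = 0.5
  expect_equal(rp$bins$A[1:5], rep(1, 5))
  expect_equal(rp$bins$B[6:10], rep(1, 5))
  # densities integrate to one over the unit domain
  for (tp in c("A", "B")) {
    d <- rp$density[rp$density$cell_type == tp, ]
    integ <- sum(diff(d$r) * (d$density[-1] + d$density[-nrow(d)]) / 2)
    expect_equal(integ, 1, tolerance = 1e-2)
    expect_equal(max(d$cumprob), integ, tolerance = 1e-9)
  }
  # single type: every nonempty bin has fraction one
  one <- mkRing(80, 0, 1, "A", 0)
  rp1 <- radialProfile(one, origin = c(0, 0), bins = 8)
  expect_true(all(rp1$bins$A[rp1$bins$n > 0] == 1))
  # a single cell of a type is flagged unreliable
  two <- rbind(one, data.frame(cell_id = 99, x = 0.2, y = 0,
                               cell_type = factor("B", levels = c("A", "B"))))
  rp2 <- radialProfile(two, origin = c(0, 0))
  expect_true("B" %in% rp2$unreliable)
})

test_that("the tip origin is the major-axis contour end farthest from the centroid", {
  m <- generateAggregateMask(radius = 40, tipAmplitude = 0.5, tipAngle = 0)
  tp <- gastrukit:::.tipPoint(m)
  cen <- colMeans(gastrukit:::.foregroundCoords(m))
  ctr <- extractContour(m)
  # lies on the contour and on the major axis (here the x axis)
  expect_lt(min(sqrt((ctr[, 1] - tp[1])^2 + (ctr[, 2] - tp[2])^2)), 1e-9)
  expect_lt(abs(tp[2] - cen[2]), 5)
  # it is the more distal of the two axis ends
  proj <- ctr[, 1] - cen[1]
  ends <- rbind(ctr[which.max(proj), ], ctr[which.min(proj), ])
  dist <- sqrt(rowSums(sweep(ends, 2, cen)^2))
  expect_equal(unname(tp), unname(ends[which.max(dist), ]))
  # a usable radial profile results when a mask supplies the origin
  cells <- randomCellTable(40, dim = 2, extent = 80)
  rp <- radialProfile(cells, origin = "tip", mask = m, bins = 5)
  expect_equal(sum(rp$bins$n), 40)
})

test_that("pooling registers, normalizes, and accumulates histograms additively", {
  set.seed(9)
  tabs <- lapply(1:7, function(k)
    generateCellPopulation(coreCount = 30, shellCount = 12, dim = 3,
                           seed = 40 + k))
  pooled <- poolAggregates(tabs)
  expect_equal(nrow(pooled), 7 * 42)
  rr <- sqrt(pooled$x^2 + pooled$y^2 + pooled$z^2)
  expect_lte(max(rr), 1 + 1e-12)
  # per-type pooled histogram equals the sum of individual histograms
  edges <- seq(0, 1, 0.1)
  hcount <- function(tb) {
    pos <- as.matrix(tb[, c("x", "y", "z")])
    pos <- sweep(pos, 2, colMeans(pos))
    r <- sqrt(rowSums(pos^2)); r <- r / max(r)
    table(cut(r[tb$cell_type == "Ecad+Tbra+"], edges, include.lowest = TRUE))
  }
  ind <- Reduce(`+`, lapply(tabs, hcount))
  rp <- sqrt(pooled$x^2 + pooled$y^2 + pooled$z^2)
  pl <- table(cut(rp[pooled$cell_type == "Ecad+Tbra+"], edges,
                  include.lowest = TRUE))
  expect_equal(as.vector(pl), as.vector(ind))

  # identical duplicated table doubles counts at identical radii
  p2 <- poolAggregates(list(tabs[[1]], tabs[[1]]))
  expect_equal(nrow(p2), 2 * nrow(tabs[[1]]))
  r2 <- sqrt(p2$x^2 + p2$y^2 + p2$z^2)
  expect_equal(r2[p2$aggregate == 1], r2[p2$aggregate == 2])

  # mixed dimensionality is rejected
  t2d <- randomCellTable(10, dim = 2, types = levels(tabs[[1]]$cell_type))
  t2d$cell_type <- factor(t2d$cell_type, levels = levels(tabs[[1]]$cell_type))
  expect_error(poolAggregates(list(tabs[[1]], t2d)), "2-D and 3-D")
})
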