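#' @importFrom stats bw.nrd0 dnorm sd cor quantile median rnorm runif
NULL

# ---- CellTable helpers ------------------------------------------------

#' Validate a labeled cell-centroid table
#'
#' A cell table is a data.frame with columns `cell_id` (unique integers),
#' `x`, `y` and optionally `z` (micrometres), and `cell_type` (factor; its
#' levels are the declared label set). An optional `aggregate` column
#' carries provenance after pooling.
#'
#' @param cells data.frame to validate.
#' @return the table, invisibly, with `cell_type` coerced to factor.
#' @export
validateCellTable <- function(cells) {
  req <- c("cell_id", "x", "y", "cell_type")
  if (!all(req %in% names(cells)))
    stop("cell table needs columns cell_id, x, y, cell_type")
  if (anyDuplicated(cells$cell_id)) stop("cell ids must be unique")
  pos <- .cellPositions(cells)
  if (any(!is.finite(pos))) stop("cell coordinates must be finite")
  if (!is.factor(cells$cell_type))
    cells$cell_type <- factor(cells$cell_type)
  if (anyNA(cells$cell_type)) stop("cell_type outside the declared label set")
  invisible(cells)
}

.cellPositions <- function(cells) {
  cols <- c("x", "y", if ("z" %in% names(cells)) "z")
  as.matrix(cells[, cols, drop = FALSE])
}

# ---- graph construction ----------------------------------------------

#' Build a pruned Delaunay neighborhood graph over cell centroids
#'
#' Computes the Delaunay triangulation of the cell centroids (2-D or 3-D
#' according to the presence of a `z` column) and removes every edge
#' strictly longer than `pruneLength` micrometres. The default of 12 um
#' corresponds to the average cell size, so retained edges connect cells
#' that plausibly touch.
#'
#' @param cells a cell table (see [validateCellTable()]).
#' @param pruneLength pruning threshold in micrometres (default 12).
#' @return a [CellGraph-class].
#' @examples
#' cells <- generateCellPopulation(coreCount = 40, shellCount = 15, seed = 1)
#' g <- buildCellGraph(cells)
#' g
#' @export
buildCellGraph <- function(cells, pruneLength = 12) {
  cells <- validateCellTable(cells)
  pos <- .cellPositions(cells)
  d <- ncol(pos)
  if (nrow(pos) < d + 1)
    stop("need at least dim + 1 cells to triangulate")
  e <- .delaunayEdges(pos)
  len <- sqrt(rowSums((pos[e[, 1], , drop = FALSE] -
                       pos[e[, 2], , drop = FALSE])^2))
  keep <- len <= pruneLength
  ids <- as.integer(cells$cell_id)
  edges <- data.frame(from = ids[e[keep, 1]], to = ids[e[keep, 2]],
                      length = len[keep])
  new("CellGraph", nodes = ids, edges = edges,
      pruneLength = as.numeric(pruneLength), positions = pos)
}

.asIgraph <- function(graph) {
  igraph::graph_from_data_frame(
    data.frame(from = as.character(graph@edges$from),
               to = as.character(graph@edges$to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(graph@nodes)))
}

#' Connected-component statistics of one cell type
#'
#' Counts the connected components of the subgraph induced by the cells of
#' a given type, and the size of the largest one. A compact, tightly packed
#' population yields a single dominant component; a sparse population
#' fragments into many.
#'
#' @param graph a [CellGraph-class] built from `cells`.
#' @param cells the cell table the graph was built from.
#' @param type a label from the declared cell-type set.
#' @return list with `n_components` and `largest_component_size`.
#' @export
componentStats <- function(graph, cells, type) {
  cells <- validateCellTable(cells)
  if (!type %in% levels(cells$cell_type))
    stop("unknown-type: '", type, "' not in the declared label set")
  ids <- cells$cell_id[cells$cell_type == type]
  if (length(ids) == 0)
    return(list(n_components = 0L, largest_component_size = 0L))
  g <- .asIgraph(graph)
  sub <- igraph::induced_subgraph(g, as.character(ids))
  comp <- igraph::components(sub)
  list(n_components = as.integer(comp$no),
       largest_component_size = as.integer(max(comp$csize)))
}

#' Majority-neighborhood typing of every cell
#'
#' Assigns each cell the most dominant type among its graph neighbors and
#' flags whether its neighborhood is homotypic (majority type equals its
#' own). Ties for the majority are recorded as `"tie"` and isolated cells
#' as `"isolated"`; both count as heterotypic but are reported separately.
#'
#' @param graph a [CellGraph-class] built from `cells`.
#' @param cells the cell table the graph was built from.
#' @return list with `perCell` (cell_id, cell_type, degree, majority_type,
#'   is_homotypic) and `perType` (per-type component counts, largest
#'   component size and homotypic counts).
#' @export
neighborhoodTyping <- function(graph, cells) {
  cells <- validateCellTable(cells)
  ids <- cells$cell_id
  typeOf <- stats::setNames(as.character(cells$cell_type), as.character(ids))
  adj <- vector("list", length(ids))
  names(adj) <- as.character(ids)
  for (k in seq_len(nrow(graph@edges))) {
    f <- as.character(graph@edges$from[k]); t <- as.character(graph@edges$to[k])
    adj[[f]] <- c(adj[[f]], t); adj[[t]] <- c(adj[[t]], f)
  }
  maj <- character(length(ids)); deg <- integer(length(ids))
  for (k in seq_along(ids)) {
    nb <- adj[[as.character(ids[k])]]
    deg[k] <- length(nb)
    if (length(nb) == 0) { maj[k] <- "isolated"; next }
    tb <- table(typeOf[nb])
    top <- names(tb)[tb == max(tb)]
    maj[k] <- if (length(top) > 1) "tie" else top
  }
  homo <- maj == as.character(cells$cell_type)
  perCell <- data.frame(cell_id = ids, cell_type = cells$cell_type,
                        degree = deg, majority_type = maj,
                        is_homotypic = homo)
  types <- levels(cells$cell_type)
  perType <- do.call(rbind, lapply(types, function(tp) {
    cst <- componentStats(graph, cells, tp)
    data.frame(cell_type = tp,
               n_cells = sum(cells$cell_type == tp),
               n_components = cst$n_components,
               largest_component_size = cst$largest_component_size,
               n_homotypic = sum(homo & cells$cell_type == tp),
               n_tie = sum(maj == "tie" & cells$cell_type == tp),
               n_isolated = sum(maj == "isolated" & cells$cell_type == tp))
  }))
  list(perCell = perCell, perType = perType)
}

# ---- radial profiles --------------------------------------------------

# Tip of an aggregate: the contour point with the extreme projection on
# the major inertia axis, picking the end farther from the centroid.
.tipPoint <- function(mask) {
  ctr <- extractContour(mask)
  cen <- colMeans(.foregroundCoords(mask))
  ang <- .majorAxisAngle(mask)
  u <- c(cos(ang), sin(ang))
  proj <- (ctr[, 1] - cen[1]) * u[1] + (ctr[, 2] - cen[2]) * u[2]
  ends <- c(which.max(proj), which.min(proj))
  dist <- sqrt((ctr[ends, 1] - cen[1])^2 + (ctr[ends, 2] - cen[2])^2)
  unname(ctr[ends[which.max(dist)], ])
}

# Gaussian KDE with reflection at both domain boundaries, so the density
# integrates to ~1 over [lo, hi] despite the bounded support.
.boundedKde <- function(r, lo, hi, bw = NULL, n = 512) {
  if (is.null(bw)) bw <- stats::bw.nrd0(r)
  grid <- seq(lo, hi, length.out = n)
  f <- function(x) rowMeans(stats::dnorm(outer(x, r, "-"), sd = bw))
  dens <- f(grid) + f(2 * lo - grid) + f(2 * hi - grid)
  list(r = grid, density = dens, bw = bw)
}

.trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Radial population-fraction profile of labeled cells
#'
#' Computes distances of all cells from a common origin (the population
#' centroid, the aggregate tip derived from a mask, or an explicit point),
#' optionally normalized by the maximum cell distance (unit-sphere
#' normalization for near-spherical aggregates), then summarizes each cell
#' type by (i) its population fraction per distance bin and (ii) a bounded
#' Gaussian kernel-density estimate over distance whose numerical integral
#' over the domain is 1; the cumulative integral gives the probability of
#' finding the type within a given distance.
#'
#' @param cells a cell table (possibly pooled, see [poolAggregates()]).
#' @param origin `"centroid"`, `"tip"` (requires `mask`), or a numeric
#'   point of the table's dimensionality.
#' @param normalize divide distances by the maximum cell distance.
#' @param bins number of distance bins (half-open, last bin closed).
#' @param bw kernel bandwidth; default Silverman's rule per type.
#' @param mask optional [AggregateMask-class] used when `origin = "tip"`.
#' @return list with `bins` (per-bin per-type fractions), `density`
#'   (long data.frame: cell_type, r, density, cumprob), `bandwidths`, and
#'   `unreliable` (types with a single cell, for which no density is
#'   estimated).
#' @export
radialProfile <- function(cells, origin = "centroid", normalize = TRUE,
                          bins = 10, bw = NULL, mask = NULL) {
  cells <- validateCellTable(cells)
  pos <- .cellPositions(cells)
  org <- if (is.numeric(origin)) {
    if (length(origin) != ncol(pos)) stop("origin dimensionality mismatch")
    origin
  } else if (identical(origin, "centroid")) {
    colMeans(pos)
  } else if (identical(origin, "tip")) {
    if (is.null(mask)) stop("origin = 'tip' requires a mask")
    tp <- .tipPoint(mask)
    if (ncol(pos) == 3) c(tp, mean(pos[, 3])) else tp
  } else stop("origin must be 'centroid', 'tip' or a point")
  r <- sqrt(rowSums(sweep(pos, 2, org)^2))
  rmax <- max(r)
  if (normalize && rmax > 0) { r <- r / rmax; rmax <- 1 }
  edges <- seq(0, rmax, length.out = bins + 1)
  # half-open bins [e_i, e_{i+1}), last bin closed on the right
  bin <- findInterval(r, edges, rightmost.closed = TRUE, left.open = FALSE)
  bin[bin > bins] <- bins
  types <- levels(cells$cell_type)
  counts <- table(factor(bin, levels = seq_len(bins)), cells$cell_type)
  tot <- rowSums(counts)
  frac <- sweep(unclass(counts), 1, pmax(tot, 1), "/")
  binDf <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                      n = as.integer(tot))
  for (tp in types) binDf[[tp]] <- frac[, tp]
  densL <- list(); bws <- c(); unreliable <- character(0)
  for (tp in types) {
    rt <- r[cells$cell_type == tp]
    if (length(rt) == 0) next
    if (length(rt) < 2 || stats::sd(rt) == 0) {
      unreliable <- c(unreliable, tp); next
    }
    kd <- .boundedKde(rt, 0, rmax, bw = bw)
    cp <- cumsum(c(0, diff(kd$r) * (kd$density[-1] + kd$density[-length(kd$density)]) / 2))
    densL[[tp]] <- data.frame(cell_type = tp, r = kd$r,
                              density = kd$density, cumprob = cp)
    bws[tp] <- kd$bw
  }
  list(bins = binDf,
       density = if (length(densL)) do.call(rbind, densL) else NULL,
       bandwidths = bws, unreliable = unreliable, origin = org,
       r_scale = if (normalize) "unit" else "um")
}

#' Pool several aggregates into one registered cell table
#'
#' Re-expresses each aggregate's cell positions relative to its own origin,
#' normalizes them by the aggregate's maximum cell distance so all cells
#' lie in a unit sphere, and concatenates the tables with an `aggregate`
#' provenance column. Registered pooling lets per-type radial statistics be
#' accumulated across aggregates of different sizes.
#'
#' @param tables list of cell tables sharing dimensionality and label set.
#' @param origins list of origins, one per table (default: each table's
#'   centroid); each is `"centroid"` or a numeric point.
#' @return a pooled cell table with renumbered `cell_id`, original ids in
#'   `orig_cell_id`, and provenance in `aggregate`.
#' @export
poolAggregates <- function(tables, origins = NULL) {
  stopifnot(length(tables) >= 1)
  tables <- lapply(tables, validateCellTable)
  dims <- vapply(tables, function(tb) ncol(.cellPositions(tb)), integer(1))
  if (length(unique(dims)) != 1)
    stop("tables mix 2-D and 3-D coordinates")
  lsets <- lapply(tables, function(tb) levels(tb$cell_type))
  if (!all(vapply(lsets, identical, logical(1), lsets[[1]])))
    stop("tables must share the declared label set")
  if (is.null(origins)) origins <- rep(list("centroid"), length(tables))
  out <- vector("list", length(tables))
  for (k in seq_along(tables)) {
    tb <- tables[[k]]
    pos <- .cellPositions(tb)
    org <- if (identical(origins[[k]], "centroid")) colMeans(pos)
           else as.numeric(origins[[k]])
    pos <- sweep(pos, 2, org)
    rmax <- max(sqrt(rowSums(pos^2)))
    if (rmax > 0) pos <- pos / rmax
    tb$x <- pos[, 1]; tb$y <- pos[, 2]
    if (ncol(pos) == 3) tb$z <- pos[, 3]
    tb$aggregate <- k
    tb$orig_cell_id <- tb$cell_id
    out[[k]] <- tb
  }
  pooled <- do.call(rbind, out)
  pooled$cell_id <- seq_len(nrow(pooled))
  rownames(pooled) <- NULL
  pooled
}
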