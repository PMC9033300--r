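# TIFF and CSV interfaces. TIFF pages are converted between the on-disk
# row-major layout (rows = y) and the package's x-first matrices.

#' Read a single- or multi-page TIFF as a list of intensity matrices
#'
#' @param path TIFF file.
#' @return list of numeric matrices in the package's x-first convention.
#' @export
readFrames <- function(path) {
  img <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(img)) img <- list(img)
  lapply(img, function(m) {
    if (length(dim(m)) == 3) m <- m[, , 1]  # first channel
    t(m)
  })
}

#' Read binary aggregate masks from a TIFF stack
#'
#' Pages are binarized at half their maximum value; each page must contain
#' one aggregate (largest-component selection and hole filling are applied
#' by the [AggregateMask()] constructor).
#'
#' @param path TIFF file.
#' @param pixelSize micrometres per pixel.
#' @param times optional vector of acquisition times (minutes).
#' @return list of [AggregateMask-class] objects.
#' @export
readMaskStack <- function(path, pixelSize = 1, times = NULL) {
  frames <- readFrames(path)
  lapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    AggregateMask(f > max(f) / 2, pixelSize = pixelSize,
                  time = if (is.null(times)) NA_real_ else times[i])
  })
}

#' Write a list of frames (or masks) to a multi-page TIFF
#'
#' Intensities are rescaled to the unit range expected by the TIFF writer;
#' the common scale is returned invisibly.
#'
#' @param frames list of matrices (x-first) or [AggregateMask-class]
#'   objects.
#' @param path output file.
#' @export
writeFrames <- function(frames, path) {
  if (!is.list(frames)) frames <- list(frames)
  mats <- lapply(frames, function(f)
    if (is(f, "AggregateMask")) f@pixels else f)
  mx <- max(vapply(mats, max, numeric(1)), 1e-12)
  pages <- lapply(mats, function(m) t(m) / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(mx)
}

#' Read a labeled cell-centroid CSV
#'
#' Accepts columns `cell_id`, `x`/`x_um`, `y`/`y_um`, optional `z`/`z_um`,
#' `cell_type`, optional `aggregate_id`/`aggregate`.
#'
#' @param path CSV file.
#' @return validated cell table.
#' @export
readCellTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ren <- c(x_um = "x", y_um = "y", z_um = "z", aggregate_id = "aggregate")
  for (from in names(ren))
    if (from %in% names(df)) names(df)[names(df) == from] <- ren[[from]]
  df$cell_type <- factor(df$cell_type)
  validateCellTable(df)
  df
}

#' Write velocity fields to CSV (plus a JSON grid header)
#'
#' One row per node and frame pair: `pair, x_um, y_um, vx_um_min,
#' vy_um_min, valid`. A sidecar `<path>.json` documents the grid.
#'
#' @param fields list of [VelocityField-class] (as from [kltFlow()]).
#' @param path output CSV path.
#' @export
writeVelocityCSV <- function(fields, path) {
  rows <- do.call(rbind, lapply(seq_along(fields), function(i)
    cbind(pair = i, velocityTable(fields[[i]]))))
  utils::write.csv(rows, path, row.names = FALSE)
  f <- fields[[1]]
  jsonlite::write_json(
    list(nx = length(f@x), ny = length(f@y), window_px = f@windowPx,
         x_um = f@x, y_um = f@y, n_pairs = length(fields)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
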