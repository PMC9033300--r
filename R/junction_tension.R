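#' Relative interfacial tension from junction contact angles
#'
#' Under the assumption that cell shapes at a three-way junction are set by
#' interfacial tension, force balance along the homotypic interface gives
#' the relative tension between heterotypic (island boundary) and
#' homotypic (island internal) contacts as the reciprocal of the sum of
#' the cosines of the two contact angles:
#' `gamma+- / gamma++ = 1 / (cos(theta1) + cos(theta2))`.
#' The ratio is symmetric in its arguments and strictly increasing in each
#' angle: wider contact angles mean proportionally higher boundary tension.
#'
#' @param theta1,theta2 contact angles in degrees, each in `[0, 90)`;
#'   vectorized.
#' @return tension ratio(s) `> 0`.
#' @examples
#' tensionRatio(60, 60)  # 1
#' tensionRatio(0, 0)    # 0.5
#' @export
tensionRatio <- function(theta1, theta2) {
  stopifnot(all(theta1 >= 0), all(theta1 < 90),
            all(theta2 >= 0), all(theta2 < 90))
  den <- cos(theta1 * pi / 180) + cos(theta2 * pi / 180)
  if (any(den <= 1e-6))
    stop("force-balance-degenerate: cos(theta1) + cos(theta2) too small")
  1 / den
}

#' Contact angles from interface directions at a junction vertex
#'
#' Given the tangent directions of the three interfaces meeting at a
#' junction vertex -- the homotypic interface between two island cells and
#' the two heterotypic interfaces to the neighbor -- returns the contact
#' angles between each heterotypic interface and the reversed homotypic
#' direction. This convention makes the force balance along the homotypic
#' interface read `gamma++ = gamma+- (cos(theta1) + cos(theta2))`,
#' consistent with [tensionRatio()].
#'
#' @param dirPP length-2 direction vector of the homotypic interface.
#' @param dirPM1,dirPM2 direction vectors of the two heterotypic
#'   interfaces.
#' @return numeric vector `c(theta1, theta2)` in degrees.
#' @export
anglesFromVertex <- function(dirPP, dirPM1, dirPM2) {
  ang <- function(u, v) {
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu < 1e-12 || nv < 1e-12) stop("zero-length interface direction")
    acos(pmin(pmax(sum(u * v) / (nu * nv), -1), 1)) * 180 / pi
  }
  back <- -dirPP
  c(theta1 = ang(dirPM1, back), theta2 = ang(dirPM2, back))
}

#' Box-whisker summary of junction tension ratios by group
#'
#' Per group (e.g. fixation time point): number of junctions, median,
#' 25th/75th quartiles (type-7 linear interpolation, so small-sample
#' summaries are deterministic), minimum and maximum.
#'
#' @param ratios numeric vector of tension ratios.
#' @param group grouping labels, same length (a single label is recycled).
#' @return data.frame with columns `group`, `n`, `min`, `q25`, `median`,
#'   `q75`, `max`.
#' @export
summarizeJunctions <- function(ratios, group = "all") {
  if (length(group) == 1) group <- rep(group, length(ratios))
  stopifnot(length(group) == length(ratios))
  if (length(ratios) == 0) stop("empty group")
  sp <- split(ratios, group)
  if (any(vapply(sp, length, integer(1)) == 0)) stop("empty group")
  do.call(rbind, lapply(names(sp), function(g) {
    v <- sp[[g]]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(group = g, n = length(v), min = min(v), q25 = q[1],
               median = q[2], q75 = q[3], max = max(v))
  }))
}
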