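# Centerline fitting, frames, and cross-section extraction.

#' Fit a smooth centerline through ordered seed points
#'
#' Interpolates a cubic spline through manually identified center points,
#' resamples it at uniform arc length, and propagates rotation-minimizing
#' orthonormal frames (double-reflection transport) along the curve.
#'
#' @param seedPoints n x 3 matrix of ordered points, mm (n >= 4, no
#'   duplicate consecutive points).
#' @param sampleSpacing arc-length sample spacing, mm (default 0.04, one
#'   40-um voxel).
#' @return A [Centerline-class].
#' @examples
#' cl <- fitCenterline(cbind(0, 0, seq(0, 3, by = 1)))
#' arcLength(cl)[nrow(centerPoints(cl))]
#' @export
fitCenterline <- function(seedPoints, sampleSpacing = 0.04) {
  seedPoints <- as.matrix(seedPoints)
  if (nrow(seedPoints) < 4)
    stop("at least 4 ordered center points are required")
  steps <- sqrt(rowSums(diff(seedPoints)^2))
  if (any(steps < 1e-12))
    stop("duplicate consecutive center points")
  tknot <- c(0, cumsum(steps))
  fx <- stats::splinefun(tknot, seedPoints[, 1], method = "natural")
  fy <- stats::splinefun(tknot, seedPoints[, 2], method = "natural")
  fz <- stats::splinefun(tknot, seedPoints[, 3], method = "natural")

  # dense arc-length table, then uniform resampling
  nDense <- max(2000L, 20L * ceiling(max(tknot) / sampleSpacing))
  td <- seq(0, max(tknot), length.out = nDense)
  pd <- cbind(fx(td), fy(td), fz(td))
  cum <- c(0, cumsum(sqrt(rowSums(diff(pd)^2))))
  L <- cum[nDense]
  ns <- max(2L, round(L / sampleSpacing) + 1L)
  sOut <- seq(0, L, length.out = ns)
  tOut <- stats::approx(cum, td, xout = sOut, ties = "ordered")$y
  pts <- cbind(fx(tOut), fy(tOut), fz(tOut))
  tg <- cbind(fx(tOut, deriv = 1), fy(tOut, deriv = 1), fz(tOut, deriv = 1))
  tg <- tg / sqrt(rowSums(tg^2))
  fr <- .rmfFrames(pts, tg)
  new("Centerline", points = pts, tangents = tg,
      normalU = fr$u, normalV = fr$v, arcLength = sOut)
}

# Point, tangent and frame at an arbitrary arc position by linear
# interpolation between samples, re-orthonormalized.
.centerlineAt <- function(cl, s) {
  sv <- cl@arcLength
  if (s < sv[1] - 1e-9 || s > sv[length(sv)] + 1e-9)
    stop(sprintf("arc position s = %.4f mm outside the centerline range", s))
  s <- min(max(s, sv[1]), sv[length(sv)])
  i <- findInterval(s, sv, rightmost.closed = TRUE)
  i <- min(max(i, 1L), length(sv) - 1L)
  w <- (s - sv[i]) / (sv[i + 1] - sv[i])
  p <- (1 - w) * cl@points[i, ] + w * cl@points[i + 1, ]
  t <- (1 - w) * cl@tangents[i, ] + w * cl@tangents[i + 1, ]
  t <- t / sqrt(sum(t^2))
  u <- (1 - w) * cl@normalU[i, ] + w * cl@normalU[i + 1, ]
  u <- u - sum(u * t) * t
  u <- u / sqrt(sum(u^2))
  v <- c(t[2] * u[3] - t[3] * u[2],
         t[3] * u[1] - t[1] * u[3],
         t[1] * u[2] - t[2] * u[1])
  list(p = p, t = t, u = u, v = v)
}

#' Extract a cross-section perpendicular to the centerline
#'
#' Samples the volume by trilinear interpolation on a square grid in the
#' plane normal to the centerline tangent at arc position `s`.
#'
#' @param volume an [ImageVolume-class].
#' @param centerline a [Centerline-class].
#' @param s arc position, mm.
#' @param halfWidth half-extent of the sampled plane, um (default 1000).
#' @param spacing in-plane pixel spacing, um (default 10; never undersample
#'   beyond the voxel size).
#' @return A [CrossSection-class].
#' @export
extractCrossSection <- function(volume, centerline, s,
                                halfWidth = 1000, spacing = 10) {
  if (spacing > volume@voxelSize * 1000 + 1e-9)
    stop("in-plane spacing must not exceed the voxel size")
  fr <- .centerlineAt(centerline, s)
  off <- seq(-halfWidth, halfWidth, by = spacing)
  grid <- expand.grid(a = off, b = off)
  pts <- matrix(fr$p, nrow(grid), 3, byrow = TRUE) +
    (grid$a / 1000) %o% fr$u + (grid$b / 1000) %o% fr$v
  hu <- .trilinear(volume, pts,
                   sprintf("cross-section plane at s = %.4f mm", s))
  new("CrossSection", hu = matrix(hu, length(off), length(off)),
      spacing = spacing, offsets = off, center = fr$p,
      axisU = fr$u, axisV = fr$v, s = s)
}

#' Interpolate a closed contour through manually placed border points
#'
#' Border points traced on longitudinal planes at three rotations (0, 60 and
#' 120 degrees) give six (theta, r) samples per slice; a periodic cubic
#' spline through them, resampled at K uniform angles, yields the initial
#' contour.
#'
#' @param borderPoints matrix with columns `theta` (radians) and `r` (um);
#'   at least 6 points covering at least 3 distinct plane rotations.
#' @param K number of output angles (default 72).
#' @param s arc position recorded on the contour, mm (default 0).
#' @return A [Contour-class].
#' @examples
#' th <- c(0, 60, 120, 180, 240, 300) * pi / 180
#' interpBorderContour(cbind(theta = th, r = rep(200, 6)))
#' @export
interpBorderContour <- function(borderPoints, K = 72L, s = 0) {
  borderPoints <- as.matrix(borderPoints)
  if (nrow(borderPoints) < 6)
    stop("at least 6 border samples (3 plane rotations) are required")
  th <- borderPoints[, 1]
  r <- borderPoints[, 2]
  if (any(r <= 0)) stop("border radii must be > 0")
  rot <- sort(unique(round((th %% pi) * 1e6) / 1e6))
  if (length(rot) < 3)
    stop("border points must cover at least 3 distinct plane rotations")
  thOut <- 2 * pi * (seq_len(K) - 1) / K
  new("Contour", theta = thOut, radius = .periodicSpline(th, r, thOut), s = s)
}

#' Circular initial contour
#'
#' Automated stand-in for manual border placement: a circle of the given
#' radius centered on the centerline point of a cross-section.
#'
#' @param crossSection a [CrossSection-class].
#' @param radiusEstimate circle radius, um (> 0).
#' @param K number of contour angles (default 72).
#' @return A [Contour-class].
#' @export
initContourCircle <- function(crossSection, radiusEstimate, K = 72L) {
  if (radiusEstimate <= 0) stop("radiusEstimate must be > 0")
  th <- 2 * pi * (seq_len(K) - 1) / K
  new("Contour", theta = th, radius = rep(radiusEstimate, K),
      s = crossSection@s)
}
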