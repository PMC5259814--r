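# Synthetic contrast-enhanced micro-CT phantom of a cast-constricted carotid.

# Inner diameter of the cast (um) at arc positions s (mm); NA outside the cast.
.castIdAt <- function(cast, s) {
  frac <- (s - cast@castStart) / cast@castLength
  id <- cast@proximalDiameter -
    (cast@proximalDiameter - cast@distalDiameter) * frac
  id[frac < 0 | frac > 1] <- NA_real_
  id
}

# Blend weight in [0, 1] for the cast-constricted state: 1 inside the cast,
# ramping linearly to 0 over the entrance/exit transition zones of length Lt
# (mm) so the true radius profile stays continuous.
.castBlend <- function(cast, s, Lt) {
  e0 <- cast@castStart
  e1 <- cast@castStart + cast@castLength
  w <- rep(0, length(s))
  w[s >= e0 & s <= e1] <- 1
  if (Lt > 0) {
    up <- s > e0 - Lt & s < e0
    w[up] <- (s[up] - (e0 - Lt)) / Lt
    dn <- s > e1 & s < e1 + Lt
    w[dn] <- ((e1 + Lt) - s[dn]) / Lt
  }
  w
}

# True lumen radius (um) at arc positions s given config + cast: the free
# vessel radius blended into the compressed in-cast radius (cast inner radius
# minus the wall thickness) across the transition zones.
.trueRadiusAt <- function(config, cast, s) {
  sCl <- pmin(pmax(s, cast@castStart), cast@castStart + cast@castLength)
  rCast <- .castIdAt(cast, sCl) / 2 - config@wallThicknessInCast
  w <- .castBlend(cast, s, config@transitionLength)
  (1 - w) * config@vesselRadiusNoncast + w * rCast
}

#' Generate a synthetic micro-CT phantom with known ground truth
#'
#' Builds a 3D Hounsfield-unit volume of a contrast-filled carotid lumen
#' running along the z axis (with an optional gentle sinusoidal in-plane
#' curvature), surrounded by soft-tissue background, with a low-HU tapering
#' cast annulus around the compressed vessel segment. Each voxel's HU is the
#' average of `supersample^3` subsamples of the material map (a box-filter
#' partial-volume model), the lumen intensity is modulated axially by a
#' sinusoid, and i.i.d. Gaussian noise is added. Values are rounded and
#' stored as signed 16-bit integers.
#'
#' Inside the cast the lumen radius is the cast inner radius minus the
#' compressed wall thickness; the thin wall layer between lumen and cast is
#' soft tissue at the background HU.
#'
#' @param config a [PhantomConfig-class].
#' @param cast a [CastSpec-class].
#' @return A list with elements `volume` ([ImageVolume-class]) and `truth`
#'   ([GroundTruth-class]). Identical `config@seed` gives a bitwise-identical
#'   volume.
#' @examples
#' p <- generatePhantom(phantomConfig(gridShape = c(48, 48, 60), noiseSd = 0,
#'                                    supersample = 1L, curvatureAmplitude = 0,
#'                                    fluctuationAmplitude = 0),
#'                      castSpec(outerDiameter = 700, castStart = 0.5))
#' p$volume
#' @export
generatePhantom <- function(config = phantomConfig(), cast = castSpec()) {
  stopifnot(is(config, "PhantomConfig"), is(cast, "CastSpec"))
  validObject(config)
  validObject(cast)
  if (config@supersample < 1L) stop("supersample must be >= 1")
  if (cast@distalDiameter / 2 - config@wallThicknessInCast <= 0)
    stop("wall thickness leaves no lumen at the distal cast end")

  vox <- config@voxelSize / 1000  # mm
  d <- config@gridShape
  xs <- (seq_len(d[1]) - 1) * vox
  ys <- (seq_len(d[2]) - 1) * vox
  zs <- (seq_len(d[3]) - 1) * vox
  xc <- (d[1] - 1) / 2 * vox
  yc <- (d[2] - 1) / 2 * vox
  Ac <- config@curvatureAmplitude / 1000
  Pc <- config@curvaturePeriod
  rOut <- cast@outerDiameter / 2 / 1000
  rVes <- config@vesselRadiusNoncast / 1000
  maxR <- max(rOut, rVes)

  if (xc - (maxR + Ac) < 10 * vox || yc - maxR < 10 * vox)
    stop("vessel radius exceeds the grid extent ",
         "(need a background margin of at least 10 voxels)")

  # arc length s(z) along the curved centerline
  zf <- seq(-vox, max(zs) + vox, length.out = 4096)
  slope <- if (Ac > 0) Ac * 2 * pi / Pc * cos(2 * pi * zf / Pc) else
    rep(0, length(zf))
  sf <- c(0, cumsum(sqrt(1 + slope[-1]^2) * diff(zf)))
  sf <- sf - stats::approx(zf, sf, xout = 0)$y  # s = 0 at z = 0
  sAt <- stats::approxfun(zf, sf)

  ampHU <- config@fluctuationAmplitude *
    (config@lumenHuNoncast - config@backgroundHu)
  lumenHuAt <- function(s, w) {
    base <- (1 - w) * config@lumenHuNoncast + w * config@lumenHuCast
    if (ampHU != 0)
      base <- base + ampHU * sin(2 * pi * s / config@fluctuationPeriod)
    base
  }

  # bounding box of the vessel + cast, with a blur margin
  ix <- which(abs(xs - xc) <= maxR + Ac + 2.5 * vox)
  iy <- which(abs(ys - yc) <= maxR + 2.5 * vox)
  nbx <- length(ix); nby <- length(iy); nz <- d[3]

  ss <- config@supersample
  offs <- (((seq_len(ss) - 1) + 0.5) / ss - 0.5) * vox
  acc <- array(0, c(nbx, nby, nz))

  for (dzo in offs) {
    zsub <- zs + dzo
    sArc <- sAt(zsub)
    id <- .castIdAt(cast, sArc)
    inC <- !is.na(id)
    rl <- .trueRadiusAt(config, cast, sArc) / 1000
    rcin <- ifelse(inC, id / 2 / 1000, NA_real_)
    lh <- lumenHuAt(sArc, .castBlend(cast, sArc, config@transitionLength))
    cxz <- xc + if (Ac > 0) Ac * sin(2 * pi * zsub / Pc) else 0
    RL2 <- array(rep(rl^2, each = nbx * nby), c(nbx, nby, nz))
    INC <- array(rep(inC, each = nbx * nby), c(nbx, nby, nz))
    RCIN2 <- array(rep(ifelse(inC, rcin^2, Inf), each = nbx * nby),
                   c(nbx, nby, nz))
    LH <- array(rep(lh, each = nbx * nby), c(nbx, nby, nz))
    for (dyo in offs) {
      B2 <- (ys[iy] + dyo - yc)^2
      BB <- array(rep(rep(B2, each = nbx), nz), c(nbx, nby, nz))
      for (dxo in offs) {
        A2 <- outer(xs[ix] + dxo, cxz, "-")^2          # nbx x nz
        AA <- aperm(array(A2, c(nbx, nz, nby)), c(1, 3, 2))
        rho2 <- AA + BB
        hu <- array(config@backgroundHu, c(nbx, nby, nz))
        hu[INC & rho2 > RCIN2 & rho2 <= rOut^2] <- config@castHu
        lum <- rho2 <= RL2
        hu[lum] <- LH[lum]
        acc <- acc + hu
      }
    }
  }

  vol <- array(config@backgroundHu, d)
  vol[ix, iy, ] <- acc / ss^3
  if (config@noiseSd > 0) {
    set.seed(config@seed)
    vol <- vol + stats::rnorm(length(vol), 0, config@noiseSd)
  }
  vol <- round(vol)
  vol[vol > 32767] <- 32767
  vol[vol < -32768] <- -32768
  storage.mode(vol) <- "integer"

  sTruth <- sAt(zs)
  cx <- xc + if (Ac > 0) Ac * sin(2 * pi * zs / Pc) else 0
  truth <- new("GroundTruth",
               centerline = cbind(x = cx, y = rep(yc, nz), z = zs),
               arcLength = sTruth,
               trueRadius = .trueRadiusAt(config, cast, sTruth),
               cast = cast,
               huParams = list(
                 lumenHuNoncast = config@lumenHuNoncast,
                 lumenHuCast = config@lumenHuCast,
                 backgroundHu = config@backgroundHu,
                 castHu = config@castHu, noiseSd = config@noiseSd,
                 fluctuationAmplitude = config@fluctuationAmplitude,
                 fluctuationPeriod = config@fluctuationPeriod,
                 wallThicknessInCast = config@wallThicknessInCast,
                 vesselRadiusNoncast = config@vesselRadiusNoncast))

  list(volume = new("ImageVolume", hu = vol, voxelSize = vox,
                    origin = c(0, 0, 0)),
       truth = truth)
}

#' Ground-truth contours of a phantom
#'
#' Converts the phantom's true radius profile into a [ContourStack-class] of
#' circular contours, e.g. to seed a segmentation or to validate diameter
#' profiling on exact geometry.
#'
#' @param truth a [GroundTruth-class].
#' @param K number of contour angles (default 72).
#' @param sRange optional `c(min, max)` arc-length window, mm.
#' @param by optional resampling step in arc length, mm (default: native
#'   sample spacing).
#' @return A [ContourStack-class] of circles at the true lumen radius.
#' @export
truthContours <- function(truth, K = 72L, sRange = NULL, by = NULL) {
  s <- truth@arcLength
  r <- truth@trueRadius
  if (!is.null(by)) {
    sq <- seq(min(s), max(s), by = by)
    r <- stats::approx(s, r, xout = sq)$y
    s <- sq
  }
  if (!is.null(sRange)) {
    keep <- s >= sRange[1] & s <= sRange[2]
    s <- s[keep]; r <- r[keep]
  }
  th <- 2 * pi * (seq_len(K) - 1) / K
  new("ContourStack",
      contours = lapply(seq_along(s), function(i)
        new("Contour", theta = th, radius = rep(r[i], K), s = s[i])),
      s = s, metadata = list(source = "ground truth"))
}
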