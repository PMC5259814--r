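# Shared fixtures, built in code and cached across test files.

.fixtures <- new.env(parent = emptyenv())

cachedFixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# The study-condition phantom: defaults calibrated to the published
# cross-animal HU averages.
defaultPhantom <- function() {
  cachedFixture("defaultPhantom",
                generatePhantom(phantomConfig(), castSpec()))
}

# Centerline + initial contours + both segmentations of the default phantom.
defaultSegmentation <- function() {
  cachedFixture("defaultSegmentation", {
    p <- defaultPhantom()
    ds0 <- diff(p$truth@arcLength[1:2])
    seedIdx <- unique(c(seq(1, nrow(p$truth@centerline),
                            by = round(0.5 / ds0)),
                        nrow(p$truth@centerline)))
    cl <- fitCenterline(p$truth@centerline[seedIdx, ], sampleSpacing = 0.04)
    sPos <- seq(0.3, max(arcLength(cl)) - 0.3, by = 0.04)
    init <- initialContours(p$volume, cl, sPos)
    list(cl = cl, init = init,
         local = segmentVessel(p$volume, cl, init, mode = "local"),
         global = segmentVessel(p$volume, cl, init, mode = "global"))
  })
}

# A small, fast phantom for unit-level checks.
smallPhantom <- function(noiseSd = 0, supersample = 1L,
                         curvatureAmplitude = 0, fluctuationAmplitude = 0,
                         gridShape = c(64L, 64L, 80L), seed = 1L) {
  key <- paste("smallPhantom", noiseSd, supersample, curvatureAmplitude,
               fluctuationAmplitude, paste(gridShape, collapse = "x"), seed,
               sep = "_")
  cachedFixture(key, generatePhantom(
    phantomConfig(gridShape = gridShape, noiseSd = noiseSd,
                  supersample = supersample,
                  curvatureAmplitude = curvatureAmplitude,
                  fluctuationAmplitude = fluctuationAmplitude, seed = seed),
    castSpec(outerDiameter = 700, castStart = 1.0)))
}

# Analytic cross-section: a bright disk of the given radius on a dark
# background (hard step at the pixel level).
diskCrossSection <- function(radius = 200, spacing = 10, halfWidth = 500,
                             hi = 339, lo = 53, s = 0) {
  off <- seq(-halfWidth, halfWidth, by = spacing)
  A <- matrix(off, length(off), length(off))
  rho <- sqrt(A^2 + t(A)^2)
  hu <- matrix(lo, length(off), length(off))
  hu[rho < radius] <- hi
  new("CrossSection", hu = hu, spacing = spacing, offsets = off,
      center = c(0, 0, 0), axisU = c(1, 0, 0), axisV = c(0, 1, 0), s = s)
}

# Stack of circular contours r(s) over arc positions s.
circleStack <- function(rfun, s, K = 72L) {
  th <- 2 * pi * (seq_len(K) - 1) / K
  new("ContourStack", contours = lapply(seq_along(s), function(i)
    new("Contour", theta = th, radius = rep(rfun(s[i]), K), s = s[i])),
    s = s, metadata = list())
}

straightCenterline <- function(zmax = 2, spacing = 0.02) {
  fitCenterline(cbind(0, 0, seq(0, zmax, by = zmax / 8)),
                sampleSpacing = spacing)
}

# Small pipeline configuration used by pipeline tests; overrides are merged
# element-wise into the small-phantom base.
smallPipelineConfig <- function(...) {
  cfg <- pipelineConfig(
    phantom = list(gridShape = c(72L, 72L, 110L), curvatureAmplitude = 100,
                   curvaturePeriod = 4),
    cast = list(castStart = 1.6, outerDiameter = 800),
    segmentation = list(margin = 0.24, seedPointSpacing = 0.3),
    seed = 5L)
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  cfg
}
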