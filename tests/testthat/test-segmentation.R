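# Region statistics, midway thresholds, binarization, contour refinement.

test_that("contour scaling is a radial similarity", {
  cs <- diskCrossSection()
  ct <- initContourCircle(cs, 100)
  expect_true(all(scaleContour(ct, 0.8)@radius == 80))
  expect_identical(scaleContour(ct, 1)@radius, ct@radius)
  expect_true(all(scaleContour(ct, 1.4)@radius == 140))
  a0 <- castseg:::.polyAreaRadial(ct@theta, ct@radius)
  a1 <- castseg:::.polyAreaRadial(ct@theta, scaleContour(ct, 0.8)@radius)
  expect_equal(a1 / a0, 0.64, tolerance = 1e-12)
  expect_error(scaleContour(ct, 0), "> 0")
  expect_error(scaleContour(ct, -2), "> 0")
})

test_that("region masks match analytic areas and never overlap", {
  cs <- diskCrossSection(radius = 250, spacing = 10, halfWidth = 500)
  ct <- initContourCircle(cs, 200)
  m <- regionMasks(ct, cs)
  pxArea <- cs@spacing^2
  expect_lt(abs(sum(m$lumen) * pxArea - pi * 160^2) / (pi * 160^2), 0.03)
  annTrue <- pi * (280^2 - 240^2)
  expect_lt(abs(sum(m$background) * pxArea - annTrue) / annTrue, 0.03)
  expect_false(any(m$lumen & m$background))
  # property: disjoint for arbitrary star-shaped contours
  set.seed(21)
  th <- 2 * pi * (0:71) / 72
  for (i in 1:20) {
    r <- 150 + castseg:::.fourierTruncate(runif(72, -60, 60), 4)
    ctR <- new("Contour", theta = th, radius = pmax(r, 40), s = 0)
    mR <- regionMasks(ctR, cs)
    expect_false(any(mR$lumen & mR$background))
  }
  # failure modes
  expect_error(regionMasks(initContourCircle(cs, 450), cs),
               "outside the cross-section")
  # a contour spanning less than one pixel has an empty shrunken lumen
  # (grid chosen so no pixel centre falls inside 0.8 x 20 um)
  csCoarse <- diskCrossSection(radius = 30, spacing = 40, halfWidth = 60)
  expect_error(regionMasks(initContourCircle(csCoarse, 20), csCoarse),
               "one pixel")
})

test_that("region statistics recover the two-level worked example", {
  # two-level plane: 330 HU inside the border, 41 HU outside
  cs <- diskCrossSection(radius = 200, spacing = 10, halfWidth = 400,
                         hi = 330, lo = 41)
  ct <- initContourCircle(cs, 200)
  st <- regionStats(list(cs), list(ct))
  expect_identical(st@lumenMean, 330)
  expect_identical(st@bgMean, 41)
  expect_identical(st@contrast, 289)
  thr <- localThresholds(st)
  expect_identical(localThreshold(thr), 185.5)
  expect_identical(globalThreshold(thr), 185.5)
  # constant plane has zero contrast
  csC <- diskCrossSection(hi = 50, lo = 50)
  stC <- regionStats(list(csC), list(initContourCircle(csC, 200)))
  expect_identical(stC@contrast, 0)
  expect_identical(stC@lumenMean, stC@bgMean)
})

test_that("noise-free phantom slices reproduce the calibrated region means", {
  p <- smallPhantom(supersample = 3L)
  cl <- fitCenterline(p$truth@centerline[seq(1, 80, by = 10), ])
  cs <- extractCrossSection(p$volume, cl, s = 0.5, halfWidth = 500,
                            spacing = 10)
  ct <- initContourCircle(cs, 250)
  st <- regionStats(list(cs), list(ct))
  expect_lt(abs(st@lumenMean - 339), 1)
  expect_lt(abs(st@bgMean - 53), 1)
})

test_that("midway thresholds order cast below non-cast and sit between L and B", {
  # slices at the published averages: non-cast and in-cast
  mk <- function(L, B) new("RegionStats", s = 0, lumenMean = L, lumenSD = 0,
                           bgMean = B, bgSD = 0, contrast = L - B,
                           nLumen = 10, nBg = 10)
  expect_identical(localThreshold(localThresholds(mk(339, 53))), 196)
  expect_identical(localThreshold(localThresholds(mk(257, -97))), 80)
  # property: min(B, L) <= T <= max(B, L) under random stats
  set.seed(33)
  L <- runif(50, -200, 500)
  B <- runif(50, -200, 500)
  st <- new("RegionStats", s = seq_len(50), lumenMean = L,
            lumenSD = rep(0, 50), bgMean = B, bgSD = rep(0, 50),
            contrast = L - B, nLumen = rep(5, 50), nBg = rep(5, 50))
  thr <- localThresholds(st)
  expect_true(all(localThreshold(thr) >= pmin(B, L) - 1e-12))
  expect_true(all(localThreshold(thr) <= pmax(B, L) + 1e-12))
  expect_equal(globalThreshold(thr), mean(localThreshold(thr)))
  expect_error(localThresholds(new("RegionStats", s = numeric(),
                                   lumenMean = numeric(),
                                   lumenSD = numeric(), bgMean = numeric(),
                                   bgSD = numeric(), contrast = numeric(),
                                   nLumen = numeric(), nBg = numeric())),
               "empty")
})

test_that("binarization thresholds behave at the extremes and on a phantom slice", {
  cs <- diskCrossSection()
  expect_true(all(binarize(cs, min(cs@hu) - 1)))
  expect_false(any(binarize(cs, max(cs@hu) + 1)))
  p <- smallPhantom()
  cl <- fitCenterline(p$truth@centerline[seq(1, 80, by = 10), ])
  csP <- extractCrossSection(p$volume, cl, s = 0.5, halfWidth = 400,
                             spacing = 10)
  bw <- binarize(csP, 196)
  off <- csP@offsets
  rho <- sqrt(outer(off^2, off^2, "+"))
  # foreground is one filled disk around the center: everything inside the
  # true radius minus a voxel, nothing beyond it plus a voxel
  expect_true(all(bw[rho < 250 - 45]))
  expect_false(any(bw[rho > 250 + 45]))
})

test_that("ray-cast refinement finds subpixel boundaries", {
  # analytic step disk on a fine grid: sub-um mean accuracy
  cs <- diskCrossSection(radius = 200, spacing = 4, halfWidth = 400)
  ct <- refineContour(cs, threshold = (339 + 53) / 2, K = 72, rMax = 350)
  expect_lt(abs(mean(ct@radius) - 200), 1)
  # blur-free phantom slice: every ray within half a voxel of truth
  p <- smallPhantom()
  cl <- fitCenterline(p$truth@centerline[seq(1, 80, by = 10), ])
  csP <- extractCrossSection(p$volume, cl, s = 0.5, halfWidth = 500,
                             spacing = 10)
  ctP <- refineContour(csP, threshold = 196, K = 72, rMax = 450)
  expect_true(all(abs(ctP@radius - 250) <= 20))
  # center outside the lumen
  expect_error(refineContour(csP, center = c(450, 0), threshold = 196),
               "below the threshold")
  # unclosed lumen: nothing ever drops below the threshold
  csB <- diskCrossSection(radius = 390, spacing = 10, halfWidth = 400,
                          hi = 339, lo = 339)
  expect_error(refineContour(csB, threshold = 100, rMax = 350),
               "not closed")
})

test_that("Fourier smoothing preserves smooth contours and removes spikes", {
  th <- 2 * pi * (0:71) / 72
  ct <- new("Contour", theta = th, radius = 200 + 20 * cos(2 * th), s = 0)
  sm <- smoothContour(ct, 8)
  expect_equal(sm@radius, ct@radius, tolerance = 1e-9)
  spiky <- ct
  spiky@radius[10] <- 320
  smS <- smoothContour(spiky, 8)
  expect_lt(abs(smS@radius[10] - ct@radius[10]), 30)
  expect_equal(mean(smS@radius), mean(spiky@radius), tolerance = 1e-9)
})

test_that("segmentation pipeline tracks truth and shows the global-threshold bias", {
  p <- defaultPhantom()
  seg <- defaultSegmentation()
  dL <- diameterProfile(seg$local)
  trR <- approx(p$truth@arcLength, p$truth@trueRadius, xout = dL@s)$y
  relErr <- abs(dL@diameter - 2 * trR) / (2 * trR)
  expect_lt(max(relErr), 0.10)
  # the global threshold narrows the distal cast region
  dG <- diameterProfile(seg$global)
  distal <- dL@s >= 6.9 & dL@s <= 7.45
  iG <- match(dL@s[distal], dG@s)
  expect_true(all(dG@diameter[iG] < dL@diameter[distal]))
})

test_that("equal local thresholds make local and global modes identical", {
  cfg <- phantomConfig(gridShape = c(64L, 64L, 80L), noiseSd = 0,
                       supersample = 1L, curvatureAmplitude = 0,
                       fluctuationAmplitude = 0, lumenHuCast = 339,
                       castHu = 53)
  cast <- castSpec(outerDiameter = 700, castStart = 1.0)
  p <- generatePhantom(cfg, cast)
  cl <- fitCenterline(p$truth@centerline[seq(1, 80, by = 10), ])
  sPos <- seq(0.3, max(arcLength(cl)) - 0.3, by = 0.08)
  init <- initialContours(p$volume, cl, sPos)
  segL <- segmentVessel(p$volume, cl, init, mode = "local", passes = 1L)
  segG <- segmentVessel(p$volume, cl, init, mode = "global", passes = 1L)
  # with uniform contrast the local thresholds are constant up to the
  # interpolation skirt entering the narrow-cast annulus (a few HU against
  # a 116 HU swing on the calibrated phantom), so the modes nearly coincide
  thr <- segL@metadata$thresholds
  expect_lt(diff(range(localThreshold(thr))), 5)
  dL <- diameterProfile(segL)
  dG <- diameterProfile(segG)
  expect_lt(max(abs(dL@diameter - dG@diameter) / dL@diameter), 0.005)
})

test_that("per-vessel contrast report summarises regions like the published table", {
  st <- new("RegionStats", s = c(1, 2, 3, 4), lumenMean = c(330, 330, 250, 260),
            lumenSD = rep(0, 4), bgMean = c(40, 42, -90, -100),
            bgSD = rep(0, 4), contrast = c(290, 288, 340, 360),
            nLumen = rep(10, 4), nBg = rep(10, 4))
  rep1 <- table1Report(st, c(2.5, 4))
  expect_equal(rep1["noncast", "lumenMean"], 330)
  expect_equal(rep1["cast", "lumenMean"], 255)
  expect_equal(rep1["cast", "contrastMean"], 350)
  expect_equal(rep1["noncast", "nSlices"], 2)
  # single slice region has zero SD
  st2 <- new("RegionStats", s = 1:2, lumenMean = c(300, 310),
             lumenSD = c(0, 0), bgMean = c(50, 60), bgSD = c(0, 0),
             contrast = c(250, 250), nLumen = c(5, 5), nBg = c(5, 5))
  r2 <- table1Report(st2, c(1.5, 2))
  expect_identical(r2["cast", "lumenSD"], 0)
  expect_error(table1Report(st2, c(5, 6)), "outside")
})
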