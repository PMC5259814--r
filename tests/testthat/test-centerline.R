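# Centerline fitting, frames, cross-sections, initial contours.

test_that("straight seed points give a straight, constant-frame centerline", {
  cl <- fitCenterline(cbind(0, 0, 0:4))
  expect_equal(max(arcLength(cl)), 4)
  expect_true(all(abs(tangents(cl) -
                      matrix(c(0, 0, 1), nrow(tangents(cl)), 3,
                             byrow = TRUE)) < 1e-9))
  u <- cl@normalU
  expect_lt(max(abs(sweep(u, 2, u[1, ]))), 1e-9)
})

test_that("helix arc length matches the closed form to 0.1%", {
  t <- seq(0, 4 * pi, length.out = 400)
  cl <- fitCenterline(cbind(cos(t), sin(t), 2 * t / (2 * pi)),
                      sampleSpacing = 0.02)
  Ltrue <- 2 * sqrt((2 * pi)^2 + 2^2)  # two turns, R = 1 mm, pitch 2 mm
  expect_lt(abs(max(arcLength(cl)) - Ltrue) / Ltrue, 1e-3)
})

test_that("fitted centerline interpolates the seed points", {
  p <- smallPhantom(curvatureAmplitude = 200)
  seed <- p$truth@centerline[seq(1, 80, by = 10), ]
  cl <- fitCenterline(seed, sampleSpacing = 0.002)
  pts <- centerPoints(cl)
  for (i in seq_len(nrow(seed))) {
    dmin <- min(sqrt(rowSums(sweep(pts, 2, seed[i, ])^2)))
    expect_lt(dmin * 1000, 1)  # < 1 um
  }
})

test_that("centerline input validation", {
  expect_error(fitCenterline(cbind(0, 0, 0:2)), "at least 4")
  expect_error(fitCenterline(cbind(0, 0, c(0, 1, 1, 2, 3))), "duplicate")
})

test_that("cross-section of a constant volume is constant and node sampling is exact", {
  set.seed(11)
  arr <- array(round(runif(21^3, -100, 400)), c(21, 21, 21))
  storage.mode(arr) <- "integer"
  vol <- new("ImageVolume", hu = arr, voxelSize = 0.04, origin = c(0, 0, 0))
  cl <- fitCenterline(cbind(0.4, 0.4, seq(0, 0.8, by = 0.2)))
  # node-exact: spacing = voxel size, plane through voxel centers
  cs <- extractCrossSection(vol, cl, s = 0.4, halfWidth = 160, spacing = 40)
  expect_equal(cs@hu, matrix(as.double(arr[7:15, 7:15, 11]), 9, 9),
               tolerance = 1e-12)
  volC <- new("ImageVolume", hu = array(7, c(21, 21, 21)), voxelSize = 0.04,
              origin = c(0, 0, 0))
  csC <- extractCrossSection(volC, cl, s = 0.3, halfWidth = 200, spacing = 10)
  expect_true(all(abs(csC@hu - 7) < 1e-9))
  expect_error(extractCrossSection(vol, cl, s = 0.4, halfWidth = 2000,
                                   spacing = 10), "outside")
})

test_that("cross-section extraction commutes with rigid translation", {
  p <- smallPhantom(noiseSd = 20, supersample = 2L)
  cl <- fitCenterline(p$truth@centerline[seq(1, 80, by = 10), ])
  cs1 <- extractCrossSection(p$volume, cl, s = 1.1, halfWidth = 400,
                             spacing = 10)
  dlt <- c(0.123, -0.456, 0.789)
  vol2 <- new("ImageVolume", hu = voxelData(p$volume),
              voxelSize = p$volume@voxelSize,
              origin = worldOrigin(p$volume) + dlt)
  cl2 <- fitCenterline(sweep(p$truth@centerline[seq(1, 80, by = 10), ], 2,
                             -dlt))
  cs2 <- extractCrossSection(vol2, cl2, s = 1.1, halfWidth = 400,
                             spacing = 10)
  expect_lt(max(abs(cs1@hu - cs2@hu)), 1e-6)
})

test_that("mid-vessel cross-section recovers the true radius at half contrast", {
  p <- smallPhantom(supersample = 3L)
  cl <- fitCenterline(p$truth@centerline[seq(1, 80, by = 10), ])
  cs <- extractCrossSection(p$volume, cl, s = 0.5, halfWidth = 400,
                            spacing = 10)
  half <- (339 + 53) / 2
  area <- sum(cs@hu > half) * cs@spacing^2
  rEq <- sqrt(area / pi)
  expect_lt(abs(rEq - 250), 20)
})

test_that("border-point contour interpolation handles circle and ellipse", {
  th6 <- c(0, 60, 120, 180, 240, 300) * pi / 180
  ct <- interpBorderContour(cbind(theta = th6, r = rep(200, 6)))
  expect_true(all(abs(ct@radius - 200) < 1e-9))
  a <- 250; b <- 200
  rEll <- function(th) a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
  ctE <- interpBorderContour(cbind(theta = th6, r = rEll(th6)))
  expect_true(all(abs(ctE@radius - rEll(ctE@theta)) / rEll(ctE@theta) < 0.05))
  expect_error(interpBorderContour(cbind(th6[1:5], rep(200, 5))),
               "at least 6")
  expect_error(
    interpBorderContour(cbind(c(0, pi, 0.3, pi + 0.3, 0, pi),
                              rep(200, 6))), "rotations")
})

test_that("circular initial contour has the requested radius and area", {
  cs <- diskCrossSection()
  ct <- initContourCircle(cs, 200)
  expect_true(all(ct@radius == 200))
  area <- castseg:::.polyAreaRadial(ct@theta, ct@radius)
  expect_lt(abs(area - pi * 200^2) / (pi * 200^2), 0.005)
  expect_error(initContourCircle(cs, 0), "> 0")
})
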