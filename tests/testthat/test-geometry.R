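# Diameter profiling, cast comparison, lofting, smoothing, extensions.

test_that("equivalent diameters match circles and ellipses", {
  st <- circleStack(function(s) 100, c(0, 1))
  dp <- diameterProfile(st)
  expect_true(all(abs(dp@diameter - 200) / 200 < 0.005))
  # ellipse a = 250, b = 160: D = 2 sqrt(ab)
  th <- 2 * pi * (0:71) / 72
  rEll <- 250 * 160 / sqrt((160 * cos(th))^2 + (250 * sin(th))^2)
  stE <- new("ContourStack", contours = list(
    new("Contour", theta = th, radius = rEll, s = 0)), s = 0,
    metadata = list())
  dpE <- diameterProfile(stE)
  expect_lt(abs(dpE@diameter - 2 * sqrt(250 * 160)) / 400, 0.01)
  expect_error(diameterProfile(new("ContourStack", contours = list(),
                                   s = numeric(), metadata = list())),
               "at least one")
})

test_that("cast inner diameter interpolates the taper", {
  cast <- castSpec(castStart = 6)
  expect_equal(castInnerDiameter(cast, 6), 400)
  expect_equal(castInnerDiameter(cast, 6.75), 300)
  expect_equal(castInnerDiameter(cast, 7.5), 200)
  expect_error(castInnerDiameter(cast, 5.9), "outside the cast")
})

test_that("percent undershoot against the cast follows its definition", {
  cast <- castSpec(castStart = 0.1, castLength = 1.5)
  s <- seq(0.2, 1.5, by = 0.1)
  # equivalent diameter of a 72-gon circle is radius * 2 * pf; build the
  # contours so the equivalent diameter is exactly the target
  pf <- sqrt(72 * sin(2 * pi / 72) / (2 * pi))
  identical_ <- circleStack(function(si) castInnerDiameter(cast, si) / 2 / pf,
                            s)
  cmp0 <- compareToCast(diameterProfile(identical_), cast)
  expect_lt(abs(cmp0$meanPct), 0.01)
  shrunk <- circleStack(
    function(si) 0.904 * castInnerDiameter(cast, si) / 2 / pf, s)
  cmp <- compareToCast(diameterProfile(shrunk), cast)
  expect_equal(cmp$meanPct, 9.6, tolerance = 0.01)
  few <- circleStack(function(si) 100, c(2, 3))
  expect_error(compareToCast(diameterProfile(few), cast), "at least 3")
})

test_that("wall thickness is half the cast-vessel diameter gap", {
  cast <- castSpec(castStart = 0.1, castLength = 1.5)
  s <- seq(0.2, 1.5, by = 0.1)
  pf <- sqrt(72 * sin(2 * pi / 72) / (2 * pi))
  st <- circleStack(function(si) (castInnerDiameter(cast, si) / 2 - 13.5) / pf,
                    s)
  w <- wallThickness(diameterProfile(st), cast)
  expect_true(all(abs(w$thickness - 13.5) < 1e-6))
  expect_false(any(w$overshoot))
  stEq <- circleStack(function(si) castInnerDiameter(cast, si) / 2 / pf, s)
  wEq <- wallThickness(diameterProfile(stEq), cast)
  expect_true(all(abs(wEq$thickness) < 1e-6))
  # phantom truth with 13.5 um wall reproduces itself (polygonal contours
  # carry a 0.06% equivalent-diameter discretisation at K = 72)
  p <- defaultPhantom()
  stT <- truthContours(p$truth, sRange = c(6.05, 7.45))
  wT <- wallThickness(diameterProfile(stT), castSpec())
  expect_true(all(abs(wT$thickness - 13.5) < 0.2))
})

test_that("lofted surfaces reproduce cylinder and frustum volumes", {
  cl <- straightCenterline()
  st <- circleStack(function(s) 100, seq(0.2, 1.2, by = 0.05))
  vol <- enclosedVolume(loftSurface(st, cl))
  expect_lt(abs(vol - pi * 0.1^2) / (pi * 0.1^2), 0.01)
  fr <- circleStack(function(s) 200 - 100 * (s - 0.2), seq(0.2, 1.2, by = 0.02))
  vf <- enclosedVolume(loftSurface(fr, cl))
  vTrue <- pi / 3 * (0.2^2 + 0.2 * 0.1 + 0.1^2)
  expect_lt(abs(vf - vTrue) / vTrue, 0.01)
  one <- circleStack(function(s) 100, 0.5)
  expect_error(loftSurface(one, cl), "at least 2")
})

test_that("lofted volume converges to the integral of contour areas", {
  cl <- straightCenterline()
  # curved radius profile so axial discretisation matters; the reference is
  # the integral of the polygon contour areas along s (fine quadrature)
  rf <- function(s) 150 + 50 * sin(2 * pi * (s - 0.2))
  K <- 72L
  sFine <- seq(0.2, 1.2, length.out = 4001)
  vRef <- castseg:::.trapz(sFine, 0.5 * K * sin(2 * pi / K) *
                             (rf(sFine) / 1000)^2)
  errs <- vapply(c(0.2, 0.1, 0.05), function(dz) {
    fr <- circleStack(rf, seq(0.2, 1.2, by = dz), K = K)
    abs(enclosedVolume(loftSurface(fr, cl)) - vRef)
  }, 1)
  expect_true(all(diff(errs) < 0))
})

test_that("band-pass smoothing preserves volume and reduces roughness", {
  cl <- straightCenterline()
  s <- seq(0.2, 1.2, by = 0.01)
  st <- circleStack(function(si) 100, s)
  surf <- loftSurface(st, cl)
  expect_identical(smoothSurface(surf, passes = 0L), surf)
  sm <- smoothSurface(surf, passes = 20L)
  v0 <- enclosedVolume(surf)
  expect_lt(abs(enclosedVolume(sm) - v0) / v0, 0.005)
  # jittered cylinder gets smoother
  set.seed(5)
  stJ <- st
  stJ@contours <- lapply(stJ@contours, function(ct) {
    ct@radius <- ct@radius + rnorm(72, 0, 5)
    ct
  })
  sj <- loftSurface(stJ, cl)
  rms <- function(su) {
    v <- vertices(su)
    mid <- v[, 3] > 0.4 & v[, 3] < 1.0
    sqrt(mean((sqrt(v[mid, 1]^2 + v[mid, 2]^2) - 0.1)^2))
  }
  sjs <- smoothSurface(sj, passes = 10L)
  expect_lt(rms(sjs), rms(sj))
})

test_that("flow extensions lengthen each end by factor times its radius", {
  cl <- straightCenterline()
  fr <- circleStack(function(s) 200 - 100 * (s - 0.2), seq(0.2, 1.2, by = 0.02))
  dp <- diameterProfile(fr)
  rIn <- dp@diameter[1] / 2 / 1000
  rOut <- dp@diameter[length(dp@s)] / 2 / 1000
  ext <- addFlowExtensions(fr, cl, factor = 5)
  expect_equal(min(ext$stack@s), 0.2 - 5 * rIn, tolerance = 1e-9)
  expect_equal(max(ext$stack@s), 1.2 + 5 * rOut, tolerance = 1e-9)
  expect_equal(diff(range(ext$stack@s)) - diff(range(fr@s)),
               5 * (rIn + rOut), tolerance = 1e-9)
  # extension cross-sections are constant and the result still lofts
  first <- ext$stack@contours[[1]]
  expect_identical(first@radius, fr@contours[[1]]@radius)
  expect_gt(enclosedVolume(loftSurface(ext$stack, ext$centerline)), 0)
  ext0 <- addFlowExtensions(fr, cl, factor = 0)
  expect_identical(ext0$stack, fr)
})
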