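# Waveform processing, Poiseuille WSS, TAWSS/OSI, Reynolds number.

test_that("identical cycles average to one cycle", {
  tr <- syntheticDopplerTrace(nCycles = 6, noiseSd = 0)
  wf <- averageCycles(tr$time, tr$velocity, nCycles = 5)
  # the ensemble mean must equal any single cycle resampled on the same grid
  pk <- which.max(tr$velocity[tr$time < 0.12])
  t0 <- tr$time[pk]
  one <- approx(tr$time, tr$velocity, xout = t0 + wf@time)$y
  expect_equal(wf@value, one, tolerance = 1e-9)
  expect_equal(max(wf@time), 0.12, tolerance = 1e-2)
})

test_that("ensemble averaging suppresses noise by about sqrt(n)", {
  clean <- syntheticDopplerTrace(nCycles = 6, noiseSd = 0)
  noisy <- syntheticDopplerTrace(nCycles = 6, noiseSd = 0.035, seed = 77)
  wf0 <- averageCycles(clean$time, clean$velocity, nCycles = 5)
  wfN <- averageCycles(noisy$time, noisy$velocity, nCycles = 5)
  rmsSingle <- sd(noisy$velocity - clean$velocity)
  rmsEnsemble <- sqrt(mean((wfN@value - wf0@value)^2))
  ratio <- rmsSingle / rmsEnsemble
  expect_gt(ratio, 1.6)   # around sqrt(5) = 2.24
  expect_lt(ratio, 3.2)
})

test_that("too few cycles is reported with the detected count", {
  tr <- syntheticDopplerTrace(nCycles = 3)
  expect_error(averageCycles(tr$time, tr$velocity, nCycles = 5),
               "detected only 2")
})

test_that("Fourier low-pass keeps band-limited waveforms and the mean", {
  t <- seq(0, 1, length.out = 101)
  wf <- new("FlowWaveform", time = t, value = 2 + sin(2 * pi * t),
            kind = "velocity")
  out <- lowpassFilter(wf, 8)
  expect_equal(out@value, wf@value, tolerance = 1e-9)
  # a harsh pulse collapses to mean + one sinusoid under n = 1
  pulse <- new("FlowWaveform", time = t,
               value = c(as.numeric(t[-101] %% 1 < 0.2), 1), kind = "flow")
  f1 <- lowpassFilter(pulse, 1)
  x <- f1@value[-101]
  expect_equal(mean(x), mean(pulse@value[-101]), tolerance = 1e-9)
  spec <- Mod(fft(x - mean(x)))[2:50]
  expect_lt(max(spec[-1]) / spec[1], 1e-9)
  expect_error(lowpassFilter(wf, 0), ">= 1")
})

test_that("velocity-to-flow conversion follows the profile assumption", {
  t <- c(0, 0.5, 1)
  wf <- new("FlowWaveform", time = t, value = rep(0.2, 3),
            kind = "velocity")
  qPar <- flowRate(wf, 250, "parabolic")
  expect_equal(qPar@value[1], 0.1 * pi * 0.25^2 * 1000, tolerance = 1e-9)
  expect_equal(qPar@value[1], 19.63, tolerance = 1e-2)
  qPlug <- flowRate(wf, 250, "plug")
  expect_equal(qPlug@value / qPar@value, rep(2, 3))
  zero <- flowRate(new("FlowWaveform", time = t, value = rep(0, 3),
                       kind = "velocity"), 250)
  expect_true(all(zero@value == 0))
  expect_error(flowRate(wf, -1), "> 0")
  expect_error(flowRate(qPar, 250), "velocity-kind")
})

test_that("Poiseuille WSS follows the inverse-cube law", {
  t <- c(0, 0.5, 1)
  q <- new("FlowWaveform", time = t, value = rep(25.8, 3), kind = "flow")
  f <- poiseuilleWSS(q, data.frame(s = 0, r = 250))
  expect_equal(f@tau[1, 1], 7.36, tolerance = 0.01)
  f2 <- poiseuilleWSS(q, data.frame(s = c(0, 1), r = c(250, 125)))
  expect_equal(f2@tau[2, 1] / f2@tau[1, 1], 8, tolerance = 1e-9)
  q0 <- new("FlowWaveform", time = t, value = rep(0, 3), kind = "flow")
  expect_true(all(poiseuilleWSS(q0, data.frame(s = 0, r = 250))@tau == 0))
  expect_error(poiseuilleWSS(q, data.frame(s = 0, r = -5)), "> 0")
})

test_that("TAWSS integrates |tau| and scales linearly", {
  t <- seq(0, 1, length.out = 101)
  const <- new("WSSField", s = 0, time = t,
               tau = matrix(6, 1, 101))
  expect_equal(tawss(const), 6)
  A <- 3
  sine <- new("WSSField", s = 0, time = t,
              tau = matrix(A * sin(2 * pi * t), 1))
  expect_equal(tawss(sine), 2 * A / pi, tolerance = 0.005)
  scaled <- new("WSSField", s = 0, time = t,
                tau = matrix(-2.5 * 6, 1, 101))
  expect_equal(tawss(scaled), 2.5 * tawss(const))
})

test_that("OSI spans unidirectional to purely oscillatory flow", {
  t <- seq(0, 1, length.out = 101)
  uni <- new("WSSField", s = 0, time = t,
             tau = matrix(2 + sin(2 * pi * t), 1))
  expect_equal(osi(uni), 0)
  osc <- new("WSSField", s = 0, time = t,
             tau = matrix(sin(2 * pi * t), 1))
  expect_equal(osi(osc), 0.5, tolerance = 1e-3)
  # randomized waveform against an independent quadrature oracle
  set.seed(9)
  for (i in 1:10) {
    tau <- sin(2 * pi * t + runif(1, 0, 2 * pi)) * runif(1, 0.5, 3) +
      rnorm(1, 0, 1)
    fld <- new("WSSField", s = 0, time = t, tau = matrix(tau, 1))
    m <- sum((tau[-1] + tau[-101]) / 2 * diff(t))
    I <- sum((abs(tau)[-1] + abs(tau)[-101]) / 2 * diff(t))
    expect_equal(osi(fld), 0.5 * (1 - abs(m) / I), tolerance = 1e-12)
  }
})

test_that("OSI stays in [0, 0.5] and TAWSS bounds the mean shear", {
  set.seed(17)
  t <- seq(0, 1, length.out = 101)
  for (i in 1:25) {
    tau <- as.vector(castseg:::.fourierTruncate(rnorm(100, sd = 2), 6))
    fld <- new("WSSField", s = 0, time = t, tau = matrix(c(tau, tau[1]), 1))
    o <- osi(fld)
    expect_gte(o, 0)
    expect_lte(o, 0.5)
    Tp <- 1
    meanTau <- abs(sum((fld@tau[1, -1] + fld@tau[1, -101]) / 2 * diff(t))) / Tp
    expect_gte(tawss(fld) + 1e-12, meanTau)
  }
})

test_that("Reynolds number uses the mean-velocity diameter convention", {
  expect_equal(reynoldsNumber(19.8, 500), 15.27, tolerance = 0.001)
  expect_equal(reynoldsNumber(0, 500), 0)
  expect_equal(reynoldsNumber(19.8, 1000), reynoldsNumber(19.8, 500) / 2)
  expect_error(reynoldsNumber(-1, 500), ">= 0")
})

test_that("cross-animal flow/WSS summary excludes missing animals", {
  r <- table2Report(c(10, NA, 20), c(1, 2, NA))
  expect_equal(r["flow", "mean"], 15)
  expect_equal(r["flow", "n"], 2)
  expect_equal(r["wss", "mean"], 1.5)
  one <- table2Report(5, 2)
  expect_identical(one["flow", "sd"], 0)
  expect_error(table2Report(NA, NA), "missing")
})

test_that("external WSS tables round-trip through CSV", {
  t <- seq(0, 0.1, length.out = 11)
  fld <- new("WSSField", s = c(0, 1, 2), time = t,
             tau = matrix(rnorm(33), 3, 11))
  path <- tempfile(fileext = ".csv")
  writeWSSField(fld, path)
  back <- readWSSField(path)
  expect_equal(back@tau, fld@tau, tolerance = 1e-9)
  expect_equal(back@s, fld@s)
})
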