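# Doppler waveform processing and quasi-1D wall shear stress.

#' Ensemble-average consecutive cardiac cycles
#'
#' Detects cycles peak-to-peak in a Doppler velocity trace, resamples each
#' cycle to a common phase grid and returns the ensemble mean as one
#' periodic waveform.
#'
#' @param time,velocity the recorded trace (s, m/s), strictly increasing
#'   time.
#' @param nCycles number of cycles to average (default 5).
#' @param phasePoints samples per cycle in the output (default 100).
#' @return A velocity-kind [FlowWaveform-class] over one mean period, with
#'   the endpoint duplicated.
#' @export
averageCycles <- function(time, velocity, nCycles = 5L, phasePoints = 100L) {
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  n <- length(velocity)
  lo <- min(velocity)
  hi <- max(velocity)
  # fundamental period from the periodogram of the detrended trace
  x <- velocity - mean(velocity)
  pw <- Mod(stats::fft(x))^2
  half <- 2:floor(n / 2)
  kStar <- half[which.max(pw[half])] - 1  # cycles over the whole trace
  span <- time[n] - time[1]
  periodEst <- span / kStar
  # candidate local maxima above mid-range, then greedy selection by height
  # with a minimum separation of 0.6 periods
  cand <- which(velocity > lo + 0.5 * (hi - lo))
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[velocity[cand] >= velocity[cand - 1] &
               velocity[cand] >= velocity[cand + 1]]
  cand <- cand[order(velocity[cand], decreasing = TRUE)]
  peaks <- integer()
  for (i in cand)
    if (!length(peaks) || all(abs(time[i] - time[peaks]) > 0.6 * periodEst))
      peaks <- c(peaks, i)
  peaks <- sort(peaks)
  nDetected <- max(0L, length(peaks) - 1L)
  if (nDetected < nCycles)
    stop(sprintf("detected only %d complete cycles; %d requested",
                 nDetected, nCycles))
  phase <- (seq_len(phasePoints) - 1) / phasePoints
  ens <- matrix(0, nCycles, phasePoints)
  periods <- numeric(nCycles)
  for (c in seq_len(nCycles)) {
    t0 <- time[peaks[c]]
    t1 <- time[peaks[c + 1]]
    periods[c] <- t1 - t0
    ens[c, ] <- stats::approx(time, velocity, xout = t0 + phase * (t1 - t0),
                              ties = "ordered")$y
  }
  Tm <- mean(periods)
  val <- colMeans(ens)
  new("FlowWaveform", time = c(phase, 1) * Tm, value = c(val, val[1]),
      kind = "velocity")
}

#' Fourier low-pass filter of a periodic waveform
#'
#' Truncates the Fourier series of the waveform, keeping the mean and the
#' first `nHarmonics` harmonics. The mean (DC component) is preserved
#' exactly.
#'
#' @param waveform a [FlowWaveform-class] over one period.
#' @param nHarmonics harmonics kept (default 8, >= 1).
#' @return The filtered [FlowWaveform-class].
#' @export
lowpassFilter <- function(waveform, nHarmonics = 8L) {
  if (nHarmonics < 1) stop("nHarmonics must be >= 1")
  n <- length(waveform@value)
  x <- waveform@value[-n]  # drop the duplicated endpoint
  y <- .fourierTruncate(x, nHarmonics)
  new("FlowWaveform", time = waveform@time, value = c(y, y[1]),
      kind = waveform@kind)
}

#' Convert a Doppler velocity waveform to volumetric flow
#'
#' Treats the Doppler velocity as the centerline peak of a fully developed
#' parabolic profile (`Q = U/2 * pi r^2`, default) or as a plug velocity
#' (`Q = U * pi r^2`).
#'
#' @param waveform a velocity-kind [FlowWaveform-class] (m/s).
#' @param inletRadius inlet radius, um (> 0).
#' @param profile `"parabolic"` or `"plug"`.
#' @return A flow-kind [FlowWaveform-class] (mm^3/s).
#' @examples
#' wf <- new("FlowWaveform", time = c(0, 1), value = c(0.2, 0.2),
#'           kind = "velocity")
#' flowRate(wf, 250)  # ~19.6 mm^3/s
#' @export
flowRate <- function(waveform, inletRadius,
                     profile = c("parabolic", "plug")) {
  profile <- match.arg(profile)
  if (inletRadius <= 0) stop("inletRadius must be > 0")
  if (waveform@kind != "velocity")
    stop("flowRate expects a velocity-kind waveform")
  rMm <- inletRadius / 1000
  fac <- if (profile == "parabolic") 0.5 else 1
  q <- fac * waveform@value * 1000 * pi * rMm^2   # m/s -> mm/s
  new("FlowWaveform", time = waveform@time, value = q, kind = "flow")
}

#' Quasi-1D Poiseuille wall shear stress field
#'
#' Fully developed Poiseuille surrogate for the wall shear stress along a
#' tapered vessel: `tau(s, t) = 4 mu Q(t) / (pi r(s)^3)`, signed with the
#' flow. Appropriate in the viscous-dominated low-Reynolds regime of the
#' murine carotid; it cannot represent the post-cast jet or recirculation
#' (externally computed tau tables can be ingested with [readWSSField()]).
#'
#' @param flow a flow-kind [FlowWaveform-class] (mm^3/s).
#' @param radiusProfile data frame or matrix with columns `s` (mm) and `r`
#'   (um), all radii > 0.
#' @param blood a [BloodModel-class].
#' @return A [WSSField-class] (Pa).
#' @export
poiseuilleWSS <- function(flow, radiusProfile, blood = bloodModel()) {
  if (flow@kind != "flow") stop("poiseuilleWSS expects a flow-kind waveform")
  rp <- as.data.frame(radiusProfile)
  names(rp)[1:2] <- c("s", "r")
  if (any(rp$r <= 0)) stop("all radii must be > 0")
  rM <- rp$r * 1e-6                # um -> m
  qM <- flow@value * 1e-9          # mm^3/s -> m^3/s
  tau <- (4 * blood@viscosity / (pi * rM^3)) %o% qM
  new("WSSField", s = rp$s, time = flow@time, tau = tau)
}

#' Time-averaged wall shear stress
#'
#' `TAWSS(s) = (1/T) integral |tau(s, t)| dt` by trapezoidal quadrature on
#' the periodic time grid.
#'
#' @param field a [WSSField-class] with >= 2 time samples.
#' @return Numeric TAWSS per arc position, Pa.
#' @export
tawss <- function(field) {
  if (length(field@time) < 2) stop("need at least 2 time samples")
  Tp <- field@time[length(field@time)] - field@time[1]
  apply(abs(field@tau), 1, function(y) .trapz(field@time, y)) / Tp
}

#' Oscillatory shear index
#'
#' `OSI(s) = 0.5 * (1 - |integral tau dt| / integral |tau| dt)`, in
#' `[0, 0.5]`; defined as 0 where the shear magnitude integral vanishes.
#' 0 means unidirectional shear, 0.5 purely oscillatory.
#'
#' @param field a [WSSField-class] with >= 2 time samples.
#' @return Numeric OSI per arc position.
#' @export
osi <- function(field) {
  if (length(field@time) < 2) stop("need at least 2 time samples")
  num <- abs(apply(field@tau, 1, function(y) .trapz(field@time, y)))
  den <- apply(abs(field@tau), 1, function(y) .trapz(field@time, y))
  out <- ifelse(den > 0, 0.5 * (1 - num / den), 0)
  pmin(pmax(out, 0), 0.5)
}

#' Reynolds number of the mean flow
#'
#' Mean-velocity, diameter-based convention:
#' `Re = 4 rho Q / (pi mu D)`.
#'
#' @param flow mean volumetric flow rate, mm^3/s (>= 0).
#' @param diameter vessel diameter, um (> 0).
#' @param blood a [BloodModel-class].
#' @return Dimensionless Reynolds number.
#' @examples
#' reynoldsNumber(19.8, 500)  # ~15
#' @export
reynoldsNumber <- function(flow, diameter, blood = bloodModel()) {
  if (flow < 0) stop("flow must be >= 0")
  if (diameter <= 0) stop("diameter must be > 0")
  4 * blood@density * (flow * 1e-9) /
    (pi * blood@viscosity * (diameter * 1e-6))
}

#' Cross-animal summary of inlet flow and wall shear stress
#'
#' Mean and SD across animals of the per-animal mean flow rate and inlet
#' WSS; missing entries (`NA`) are excluded per column.
#'
#' @param flowRates per-animal mean flow rates, mm^3/s (NA allowed).
#' @param inletWSS per-animal inlet WSS, Pa (NA allowed).
#' @return A data frame with rows `flow` and `wss` and columns `mean`, `sd`,
#'   `n`.
#' @export
table2Report <- function(flowRates, inletWSS) {
  f <- flowRates[!is.na(flowRates)]
  w <- inletWSS[!is.na(inletWSS)]
  if (!length(f) && !length(w)) stop("all entries are missing")
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  data.frame(row.names = c("flow", "wss"),
             mean = c(mean(f), mean(w)),
             sd = c(sd0(f), sd0(w)),
             n = c(length(f), length(w)))
}

#' Synthetic Doppler velocity trace
#'
#' A murine-carotid-like centerline velocity trace: repeated cardiac cycles
#' (default period 0.12 s, i.e. 500 bpm) with a systolic Gaussian pulse over
#' a diastolic baseline, plus optional Gaussian measurement noise. Default
#' amplitudes give a mean centerline velocity near 0.18 m/s, which with a
#' 250 um inlet radius and a parabolic profile corresponds to a mean flow in
#' the published cross-animal range.
#'
#' @param nCycles cycles in the trace (default 6).
#' @param period cardiac period, s (default 0.12).
#' @param base diastolic baseline velocity, m/s (default 0.12).
#' @param amplitude systolic pulse amplitude, m/s (default 0.35).
#' @param width Gaussian pulse width as a fraction of the period
#'   (default 0.1).
#' @param dt sampling interval, s (default 1e-3).
#' @param noiseSd measurement noise SD, m/s (default 0).
#' @param seed RNG seed for the noise.
#' @return A data frame with columns `time` (s) and `velocity` (m/s).
#' @export
syntheticDopplerTrace <- function(nCycles = 6L, period = 0.12, base = 0.12,
                                  amplitude = 0.35, width = 0.1, dt = 1e-3,
                                  noiseSd = 0, seed = 1L) {
  time <- seq(0, nCycles * period, by = dt)
  phase <- (time / period) %% 1
  v <- base + amplitude * exp(-((phase - 0.3) / width)^2)
  if (noiseSd > 0) {
    set.seed(seed)
    v <- v + stats::rnorm(length(v), 0, noiseSd)
  }
  data.frame(time = time, velocity = v)
}
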