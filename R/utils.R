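# Internal numerical helpers.

# Trilinear interpolation of an ImageVolume at world points (n x 3, mm).
# Errors if any point falls outside the voxel grid.
.trilinear <- function(volume, pts, context = "sample points") {
  d <- dim(volume@hu)
  idx <- sweep(pts, 2, volume@origin) / volume@voxelSize
  for (c in 1:3) {
    if (any(idx[, c] < -1e-9) || any(idx[, c] > d[c] - 1 + 1e-9))
      stop(context, " fall outside the image volume")
    idx[, c] <- pmin(pmax(idx[, c], 0), d[c] - 1)
  }
  i0 <- floor(idx)
  f <- idx - i0
  for (c in 1:3) {
    hi <- i0[, c] > d[c] - 2
    if (any(hi)) {
      i0[hi, c] <- d[c] - 2
      f[hi, c] <- idx[hi, c] - (d[c] - 2)
    }
  }
  g <- function(a, b, cc)
    volume@hu[cbind(i0[, 1] + a + 1, i0[, 2] + b + 1, i0[, 3] + cc + 1)]
  w1 <- 1 - f
  g(0, 0, 0) * w1[, 1] * w1[, 2] * w1[, 3] +
    g(1, 0, 0) * f[, 1] * w1[, 2] * w1[, 3] +
    g(0, 1, 0) * w1[, 1] * f[, 2] * w1[, 3] +
    g(0, 0, 1) * w1[, 1] * w1[, 2] * f[, 3] +
    g(1, 1, 0) * f[, 1] * f[, 2] * w1[, 3] +
    g(1, 0, 1) * f[, 1] * w1[, 2] * f[, 3] +
    g(0, 1, 1) * w1[, 1] * f[, 2] * f[, 3] +
    g(1, 1, 1) * f[, 1] * f[, 2] * f[, 3]
}

# Bilinear interpolation on a CrossSection at in-plane coordinates (um).
# Returns NA outside the sampled plane.
.csInterp <- function(cs, a, b) {
  off0 <- cs@offsets[1]
  n <- length(cs@offsets)
  ia <- (a - off0) / cs@spacing
  ib <- (b - off0) / cs@spacing
  out <- ia < -1e-9 | ia > n - 1 + 1e-9 | ib < -1e-9 | ib > n - 1 + 1e-9
  ia <- pmin(pmax(ia, 0), n - 1)
  ib <- pmin(pmax(ib, 0), n - 1)
  i0 <- pmin(floor(ia), n - 2)
  j0 <- pmin(floor(ib), n - 2)
  fa <- ia - i0
  fb <- ib - j0
  v <- cs@hu[cbind(i0 + 1, j0 + 1)] * (1 - fa) * (1 - fb) +
    cs@hu[cbind(i0 + 2, j0 + 1)] * fa * (1 - fb) +
    cs@hu[cbind(i0 + 1, j0 + 2)] * (1 - fa) * fb +
    cs@hu[cbind(i0 + 2, j0 + 2)] * fa * fb
  v[out] <- NA_real_
  v
}

# Shoelace polygon area of a radial contour (um^2); positive for r > 0.
.polyAreaRadial <- function(theta, r) {
  x <- r * cos(theta)
  y <- r * sin(theta)
  n <- length(x)
  j <- c(2:n, 1)
  0.5 * sum(x * y[j] - x[j] * y)
}

# Periodic linear interpolation of r(theta) at query angles.
.periodicInterp <- function(theta, r, q) {
  q <- q %% (2 * pi)
  n <- length(theta)
  thExt <- c(theta, theta[1] + 2 * pi)
  rExt <- c(r, r[1])
  stats::approx(thExt, rExt, xout = q, rule = 2)$y
}

# Periodic cubic spline through (theta, r), evaluated at K uniform angles.
.periodicSpline <- function(theta, r, thetaOut) {
  o <- order(theta %% (2 * pi))
  th <- (theta %% (2 * pi))[o]
  rr <- r[o]
  sp <- stats::spline(c(th, th[1] + 2 * pi), c(rr, rr[1]),
                      method = "periodic", xout = thetaOut %% (2 * pi))
  sp$y
}

# Fourier truncation of a periodic signal, keeping the mean plus the first
# nHarm harmonics. Used both for contour smoothing and waveform filtering.
.fourierTruncate <- function(x, nHarm) {
  n <- length(x)
  X <- stats::fft(x)
  keep <- rep(FALSE, n)
  keep[1] <- TRUE
  if (nHarm >= 1) {
    h <- seq_len(min(nHarm, floor((n - 1) / 2)))
    keep[1 + h] <- TRUE
    keep[n + 1 - h] <- TRUE
  }
  if (n %% 2 == 0 && nHarm >= n / 2) keep[n / 2 + 1] <- TRUE
  X[!keep] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

# Rotation-minimizing frames by the double-reflection method.
# points/tangs: n x 3. Returns list(u, v) of n x 3 matrices.
.rmfFrames <- function(points, tangs) {
  n <- nrow(points)
  u <- matrix(0, n, 3)
  t1 <- tangs[1, ]
  seedv <- if (abs(t1[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u0 <- seedv - sum(seedv * t1) * t1
  u[1, ] <- u0 / sqrt(sum(u0^2))
  for (i in seq_len(n - 1)) {
    v1 <- points[i + 1, ] - points[i, ]
    c1 <- sum(v1^2)
    if (c1 < 1e-300) {
      u[i + 1, ] <- u[i, ]
      next
    }
    rL <- u[i, ] - (2 / c1) * sum(v1 * u[i, ]) * v1
    tL <- tangs[i, ] - (2 / c1) * sum(v1 * tangs[i, ]) * v1
    v2 <- tangs[i + 1, ] - tL
    c2 <- sum(v2^2)
    ui <- if (c2 < 1e-300) rL else rL - (2 / c2) * sum(v2 * rL) * v2
    # re-orthogonalize against accumulated numerical drift
    ui <- ui - sum(ui * tangs[i + 1, ]) * tangs[i + 1, ]
    u[i + 1, ] <- ui / sqrt(sum(ui^2))
  }
  v <- cbind(tangs[, 2] * u[, 3] - tangs[, 3] * u[, 2],
             tangs[, 3] * u[, 1] - tangs[, 1] * u[, 3],
             tangs[, 1] * u[, 2] - tangs[, 2] * u[, 1])
  list(u = u, v = v)
}

# Trapezoidal quadrature.
.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}
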