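# Local midway-threshold segmentation: region statistics, thresholds,
# binarization and subvoxel contour refinement.

#' Scale a contour about the centerline point
#'
#' Radial similarity scaling, used to build the 20%-shrunken lumen region and
#' the 20-40% expanded background annulus.
#'
#' @param contour a [Contour-class].
#' @param factor positive scale factor.
#' @return The scaled [Contour-class].
#' @examples
#' cs <- new("CrossSection", hu = matrix(0, 3, 3), spacing = 10,
#'           offsets = c(-10, 0, 10), center = c(0, 0, 0),
#'           axisU = c(1, 0, 0), axisV = c(0, 1, 0), s = 0)
#' scaleContour(initContourCircle(cs, 100), 0.8)
#' @export
scaleContour <- function(contour, factor) {
  if (!is.numeric(factor) || factor <= 0) stop("scale factor must be > 0")
  new("Contour", theta = contour@theta, radius = factor * contour@radius,
      s = contour@s)
}

#' Lumen and background region masks for one slice
#'
#' The lumen region contains pixels strictly inside the contour shrunk to
#' `shrink` of its radius; the background region is the annulus between the
#' `expand[1]`- and `expand[2]`-scaled contour. The two masks are disjoint by
#' construction.
#'
#' @param contour a [Contour-class] (radii in um).
#' @param crossSection a [CrossSection-class].
#' @param shrink lumen shrink factor (default 0.8).
#' @param expand background annulus scale range (default `c(1.2, 1.4)`).
#' @return A list with logical matrices `lumen` and `background`.
#' @export
regionMasks <- function(contour, crossSection, shrink = 0.8,
                        expand = c(1.2, 1.4)) {
  off <- crossSection@offsets
  if (expand[2] * max(contour@radius) > max(off) + 1e-9)
    stop(sprintf(
      "contour (with its background annulus) extends outside the cross-section at s = %.4f mm",
      crossSection@s))
  A <- matrix(off, length(off), length(off))
  B <- t(A)
  rho <- sqrt(A^2 + B^2)
  phi <- atan2(B, A)
  rC <- matrix(.periodicInterp(contour@theta, contour@radius, as.vector(phi)),
               length(off), length(off))
  lumen <- rho < shrink * rC
  background <- rho >= expand[1] * rC & rho <= expand[2] * rC
  if (!any(lumen))
    stop(sprintf(
      paste0("empty lumen region at s = %.4f mm: the 20%% shrink assumes the ",
             "contour spans at least 5 pixels (so 20%% of it is one pixel)"),
      crossSection@s))
  list(lumen = lumen, background = background)
}

#' Per-slice lumen/background statistics along the vessel
#'
#' For each cross-section/contour pair, computes the mean and SD of the HU
#' values inside the lumen and background regions and the per-slice contrast
#' difference `C_i = L_i - B_i`.
#'
#' @param crossSections list of [CrossSection-class] objects.
#' @param contourList list of [Contour-class] objects (one per slice).
#' @param shrink,expand region factors, see [regionMasks()].
#' @return A [RegionStats-class].
#' @export
regionStats <- function(crossSections, contourList, shrink = 0.8,
                        expand = c(1.2, 1.4)) {
  if (length(crossSections) != length(contourList))
    stop("one contour per cross-section is required")
  n <- length(crossSections)
  out <- matrix(NA_real_, n, 7)
  for (i in seq_len(n)) {
    cs <- crossSections[[i]]
    m <- tryCatch(
      regionMasks(contourList[[i]], cs, shrink, expand),
      error = function(e)
        stop(sprintf("slice s = %.4f mm: %s", cs@s, conditionMessage(e)),
             call. = FALSE))
    lv <- cs@hu[m$lumen]
    bv <- cs@hu[m$background]
    out[i, ] <- c(mean(lv), stats::sd(lv), mean(bv), stats::sd(bv),
                  length(lv), length(bv), cs@s)
  }
  out[is.na(out[, 2]), 2] <- 0
  out[is.na(out[, 4]), 4] <- 0
  new("RegionStats", s = out[, 7], lumenMean = out[, 1], lumenSD = out[, 2],
      bgMean = out[, 3], bgSD = out[, 4],
      contrast = out[, 1] - out[, 3], nLumen = out[, 5], nBg = out[, 6])
}

#' Midway local thresholds and the global threshold
#'
#' The local threshold of each contour is the midway value between its lumen
#' and background means, `T_i = (L_i + B_i) / 2`; the global threshold is the
#' arithmetic mean of the local thresholds along the vessel.
#'
#' @param stats a [RegionStats-class] (nonempty).
#' @return A [ThresholdProfile-class].
#' @examples
#' st <- new("RegionStats", s = 0, lumenMean = 330, lumenSD = 0, bgMean = 41,
#'           bgSD = 0, contrast = 289, nLumen = 10, nBg = 10)
#' localThreshold(localThresholds(st))  # 185.5
#' @export
localThresholds <- function(stats) {
  if (!length(stats@s)) stop("empty region statistics")
  Ti <- (stats@lumenMean + stats@bgMean) / 2
  new("ThresholdProfile", s = stats@s, local = Ti, global = mean(Ti))
}

#' Binarize a cross-section at a threshold
#'
#' @param crossSection a [CrossSection-class].
#' @param threshold HU threshold; pixels at or above it are foreground.
#' @return A logical matrix (TRUE = lumen foreground).
#' @export
binarize <- function(crossSection, threshold) {
  crossSection@hu >= threshold
}

#' Refine a contour by subvoxel ray casting
#'
#' Casts K rays from the centerline point and locates, on each, the first
#' subpixel crossing of the interpolated intensity below the threshold.
#' Sampling proceeds in quarter-pixel steps; the crossing is located by
#' linear interpolation between the bracketing samples.
#'
#' @param crossSection a [CrossSection-class].
#' @param center in-plane ray origin, um (default the centerline point).
#' @param threshold HU threshold.
#' @param K number of rays (default 72).
#' @param rMax maximum search radius, um (default 600).
#' @return A [Contour-class]. Rays without a crossing are filled by periodic
#'   interpolation from their neighbours; if more than 10% of rays fail the
#'   lumen is considered not closed and an error is raised.
#' @export
refineContour <- function(crossSection, center = c(0, 0), threshold,
                          K = 72L, rMax = 600) {
  centerI <- .csInterp(crossSection, center[1], center[2])
  if (is.na(centerI) || centerI < threshold)
    stop(sprintf(
      "ray origin lies below the threshold (off-lumen centerline) at s = %.4f mm",
      crossSection@s))
  th <- 2 * pi * (seq_len(K) - 1) / K
  step <- crossSection@spacing / 4
  rr <- seq(step, rMax, by = step)
  nr <- length(rr)
  A <- cos(th) %o% rr + center[1]
  B <- sin(th) %o% rr + center[2]
  I <- matrix(.csInterp(crossSection, as.vector(A), as.vector(B)), K, nr)
  I[is.na(I)] <- Inf  # leaving the sampled plane never counts as a crossing
  r <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    j <- which(I[k, ] < threshold)[1]
    if (is.na(j)) next
    prevI <- if (j > 1) I[k, j - 1] else centerI
    prevR <- if (j > 1) rr[j - 1] else 0
    r[k] <- prevR + (rr[j] - prevR) * (prevI - threshold) / (prevI - I[k, j])
  }
  bad <- is.na(r)
  if (mean(bad) > 0.10)
    stop(sprintf(
      "lumen not closed at s = %.4f mm: %d of %d rays found no crossing within %g um",
      crossSection@s, sum(bad), K, rMax))
  if (any(bad))
    r[bad] <- .periodicInterp(th[!bad], r[!bad], th[bad])
  new("Contour", theta = th, radius = r, s = crossSection@s)
}

#' Smooth a contour by Fourier truncation
#'
#' Removes single-ray noise spikes from a refined boundary by keeping the
#' mean and the first `harmonics` angular harmonics of r(theta).
#'
#' @param contour a [Contour-class].
#' @param harmonics number of harmonics kept (default 8).
#' @return The smoothed [Contour-class].
#' @export
smoothContour <- function(contour, harmonics = 8L) {
  r <- .fourierTruncate(contour@radius, harmonics)
  if (any(r <= 0))
    stop(sprintf("contour smoothing produced non-positive radii at s = %.4f mm",
                 contour@s))
  new("Contour", theta = contour@theta, radius = r, s = contour@s)
}

#' Segment a vessel with local or global midway thresholds
#'
#' The full per-contour protocol: extract perpendicular cross-sections at the
#' arc positions of the initial contours, compute lumen/background region
#' statistics (20% shrink / 20-40% expansion), derive midway local thresholds
#' and their global mean, then refine each contour by subvoxel ray casting
#' against its local threshold (`mode = "local"`) or the single global
#' threshold (`mode = "global"`), followed by Fourier smoothing. The regions
#' are then re-derived from the refined contours and the loop repeats until
#' the maximum radial change falls below a tenth of a voxel (or `passes`
#' iterations). Iterating to convergence makes the result essentially
#' independent of the initial contours; it typically converges in 3 passes.
#'
#' Slices whose background annulus leaves the sampled plane (or whose plane
#' leaves the volume) are dropped with a warning rather than failing the run.
#'
#' @param volume an [ImageVolume-class].
#' @param centerline a [Centerline-class].
#' @param initContours a [ContourStack-class] of initial contours.
#' @param mode `"local"` or `"global"`.
#' @param shrink,expand region factors, see [regionMasks()].
#' @param passes maximum number of refinement passes (default 4; set 1 for
#'   a single pass against the initial-contour regions).
#' @param spacing cross-section pixel spacing, um (default 10).
#' @param halfWidth cross-section half extent, um (default: sized to the
#'   initial contours and `rMax`).
#' @param harmonics Fourier harmonics kept in contour smoothing (default 8).
#' @param rMax maximum ray-cast radius, um (default 600).
#' @param convergenceTol radial convergence tolerance for `passes > 1`, um
#'   (default: voxel size / 10).
#' @return A [ContourStack-class]; `metadata` holds the [RegionStats-class],
#'   the [ThresholdProfile-class], the mode and the dropped slices.
#' @export
segmentVessel <- function(volume, centerline, initContours,
                          mode = c("local", "global"), shrink = 0.8,
                          expand = c(1.2, 1.4), passes = 4L, spacing = 10,
                          halfWidth = NULL, harmonics = 8L, rMax = 600,
                          convergenceTol = NULL) {
  mode <- match.arg(mode)
  if (is.null(convergenceTol)) convergenceTol <- volume@voxelSize * 1000 / 10
  maxr <- max(vapply(initContours@contours, function(ct) max(ct@radius), 1))
  if (is.null(halfWidth))
    halfWidth <- max(1.45 * maxr, rMax)

  sAll <- initContours@s
  cs <- vector("list", length(sAll))
  keep <- rep(TRUE, length(sAll))
  for (i in seq_along(sAll)) {
    cs[[i]] <- tryCatch(
      extractCrossSection(volume, centerline, sAll[i], halfWidth, spacing),
      error = function(e) {
        warning(sprintf("WARN dropping slice s = %.4f mm: %s", sAll[i],
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
    if (is.null(cs[[i]])) keep[i] <- FALSE
  }
  cs <- cs[keep]
  cts <- initContours@contours[keep]
  sKept <- sAll[keep]
  if (!length(cs)) stop("no usable slices: every cross-section left the volume")

  stats <- NULL
  thr <- NULL
  passesRun <- 0L
  for (p in seq_len(max(1L, passes))) {
    dropNow <- rep(FALSE, length(cs))
    for (i in seq_along(cs)) {
      ok <- tryCatch({
        regionMasks(cts[[i]], cs[[i]], shrink, expand)
        TRUE
      }, error = function(e) {
        if (grepl("outside the cross-section", conditionMessage(e))) {
          warning(sprintf("WARN dropping slice s = %.4f mm: %s", cs[[i]]@s,
                          conditionMessage(e)), call. = FALSE)
          FALSE
        } else stop(e)
      })
      if (!ok) dropNow[i] <- TRUE
    }
    if (any(dropNow)) {
      cs <- cs[!dropNow]; cts <- cts[!dropNow]; sKept <- sKept[!dropNow]
      if (!length(cs)) stop("no usable slices after region-mask checks")
    }
    stats <- regionStats(cs, cts, shrink, expand)
    thr <- localThresholds(stats)
    Tuse <- if (mode == "local") thr@local else rep(thr@global, length(cs))
    newCts <- vector("list", length(cs))
    maxChange <- 0
    for (i in seq_along(cs)) {
      rc <- refineContour(cs[[i]], c(0, 0), Tuse[i],
                          K = length(cts[[i]]@theta), rMax = rMax)
      rc <- smoothContour(rc, harmonics)
      maxChange <- max(maxChange, max(abs(rc@radius - cts[[i]]@radius)))
      newCts[[i]] <- rc
    }
    cts <- newCts
    passesRun <- p
    if (maxChange < convergenceTol) break
  }

  new("ContourStack", contours = cts, s = sKept,
      metadata = list(stats = stats, thresholds = thr, mode = mode,
                      passes = passesRun, dropped = sAll[!keep]))
}

#' Automatic initial contours from provisional midway thresholds
#'
#' A stand-in for manual border placement: for each slice a provisional
#' threshold is taken as the midway value between the intensity sampled at
#' the centerline point and the intensity sampled on a far annulus well
#' outside the vessel, and one ray-cast refinement against it gives the
#' initial contour.
#'
#' @param volume an [ImageVolume-class].
#' @param centerline a [Centerline-class].
#' @param sPositions arc positions of the slices, mm.
#' @param radiusEstimate coarse lumen radius estimate, um (default 250).
#' @param K contour angles (default 72).
#' @param spacing cross-section pixel spacing, um (default 10).
#' @param rMax maximum ray-cast radius, um (default 600).
#' @param harmonics Fourier harmonics for smoothing (default 8).
#' @return A [ContourStack-class] of initial contours.
#' @export
initialContours <- function(volume, centerline, sPositions,
                            radiusEstimate = 250, K = 72L, spacing = 10,
                            rMax = 600, harmonics = 8L) {
  halfWidth <- max(2.1 * radiusEstimate, rMax)
  th <- 2 * pi * (seq_len(36) - 1) / 36
  cts <- vector("list", length(sPositions))
  for (i in seq_along(sPositions)) {
    cs <- extractCrossSection(volume, centerline, sPositions[i],
                              halfWidth, spacing)
    nearI <- .csInterp(cs, c(0, spacing, -spacing, 0, 0),
                       c(0, 0, 0, spacing, -spacing))
    farR <- c(1.6, 1.8, 2.0) * radiusEstimate
    farA <- as.vector(cos(th) %o% farR)
    farB <- as.vector(sin(th) %o% farR)
    farI <- .csInterp(cs, farA, farB)
    thr <- (mean(nearI, na.rm = TRUE) + mean(farI, na.rm = TRUE)) / 2
    ct <- refineContour(cs, c(0, 0), thr, K = K, rMax = rMax)
    cts[[i]] <- smoothContour(ct, harmonics)
  }
  new("ContourStack", contours = cts, s = sPositions,
      metadata = list(source = "provisional midway initialization"))
}

#' Jitter initial contour radii
#'
#' Applies an independent multiplicative perturbation, uniform in
#' `[1 - amount, 1 + amount]`, to each slice's contour radius. Used to probe
#' the reproducibility of the segmentation under different initializations.
#'
#' @param stack a [ContourStack-class].
#' @param amount maximum relative perturbation (default 0.15).
#' @param seed RNG seed.
#' @return The jittered [ContourStack-class].
#' @export
jitterContours <- function(stack, amount = 0.15, seed = 1L) {
  set.seed(seed)
  f <- stats::runif(length(stack@contours), 1 - amount, 1 + amount)
  new("ContourStack",
      contours = lapply(seq_along(stack@contours), function(i)
        scaleContour(stack@contours[[i]], f[i])),
      s = stack@s, metadata = c(stack@metadata, list(jitter = amount)))
}
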