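# Diameter / wall-thickness profiling and surface construction.

#' Equivalent-diameter profile of a contour stack
#'
#' Computes the polygon area of each contour and the equivalent-area
#' diameter `D = 2 * sqrt(A / pi)`.
#'
#' @param stack a [ContourStack-class] (>= 1 contour).
#' @return A [DiameterProfile-class].
#' @examples
#' th <- 2 * pi * (0:71) / 72
#' st <- new("ContourStack", contours = list(
#'   new("Contour", theta = th, radius = rep(100, 72), s = 0)), s = 0,
#'   metadata = list())
#' diameterProfile(st)
#' @export
diameterProfile <- function(stack) {
  if (!length(stack@contours)) stop("at least one contour is required")
  area <- vapply(stack@contours, function(ct) {
    a <- .polyAreaRadial(ct@theta, ct@radius)
    if (a <= 0)
      stop(sprintf("self-intersecting contour (non-positive area) at s = %.4f mm",
                   ct@s))
    a
  }, 1)
  new("DiameterProfile", s = stack@s, area = area,
      diameter = 2 * sqrt(area / pi))
}

#' Cast inner diameter at an arc position
#'
#' Linear interpolation of the cast taper (400 to 200 um over 1.5 mm by
#' default) between the proximal and distal inner diameters.
#'
#' @param cast a [CastSpec-class].
#' @param s arc position(s), mm; must lie within the cast extent.
#' @return Inner diameter(s), um.
#' @examples
#' castInnerDiameter(castSpec(castStart = 6), c(6, 6.75, 7.5))
#' @export
castInnerDiameter <- function(cast, s) {
  id <- .castIdAt(cast, s)
  if (any(is.na(id)))
    stop("arc position outside the cast extent")
  id
}

#' Compare segmented diameters to the known cast taper
#'
#' Over the slices inside the cast, computes the mean and SD of the percent
#' undershoot `100 * (D_cast - D_vessel) / D_cast`. Positive values mean the
#' segmented vessel is narrower than the cast lumen.
#'
#' @param diameters a [DiameterProfile-class].
#' @param cast a [CastSpec-class]; at least 3 profile slices must fall
#'   inside the cast.
#' @return A list with `meanPct`, `sdPct`, and the per-slice data frame
#'   `perSlice` (s, castDiameter, vesselDiameter, pct).
#' @export
compareToCast <- function(diameters, cast) {
  inC <- diameters@s >= cast@castStart &
    diameters@s <= cast@castStart + cast@castLength
  if (sum(inC) < 3)
    stop("need at least 3 profile slices inside the cast")
  dc <- castInnerDiameter(cast, diameters@s[inC])
  dv <- diameters@diameter[inC]
  pct <- 100 * (dc - dv) / dc
  list(meanPct = mean(pct), sdPct = stats::sd(pct),
       perSlice = data.frame(s = diameters@s[inC], castDiameter = dc,
                             vesselDiameter = dv, pct = pct))
}

#' Vessel wall thickness inside the cast
#'
#' Defined as half the difference between the cast inner diameter and the
#' segmented vessel diameter, `w(s) = (D_cast(s) - D_vessel(s)) / 2`.
#' Negative values (segmentation overshoot beyond the cast lumen) are
#' flagged, not raised.
#'
#' @param diameters a [DiameterProfile-class].
#' @param cast a [CastSpec-class].
#' @return A data frame with columns `s` (mm), `castDiameter`,
#'   `vesselDiameter`, `thickness` (um) and logical `overshoot`.
#' @export
wallThickness <- function(diameters, cast) {
  inC <- diameters@s >= cast@castStart &
    diameters@s <= cast@castStart + cast@castLength
  if (sum(inC) < 3)
    stop("need at least 3 profile slices inside the cast")
  dc <- castInnerDiameter(cast, diameters@s[inC])
  dv <- diameters@diameter[inC]
  w <- (dc - dv) / 2
  data.frame(s = diameters@s[inC], castDiameter = dc, vesselDiameter = dv,
             thickness = w, overshoot = w < 0)
}

#' Loft a contour stack into a watertight triangle mesh
#'
#' Places each contour in 3D using the centerline frames (which also align
#' the angular origin between slices), connects adjacent contours with
#' triangulated quad strips, and caps both ends with triangle fans to the
#' end-contour centroids. The mesh is oriented outward.
#'
#' @param stack a [ContourStack-class] (>= 2 contours, consistent K).
#' @param centerline a [Centerline-class] covering the stack's arc range.
#' @return A [VesselSurface-class].
#' @export
loftSurface <- function(stack, centerline) {
  n <- length(stack@contours)
  if (n < 2) stop("at least 2 contours are required to loft a surface")
  K <- length(stack@contours[[1]]@theta)
  if (any(vapply(stack@contours, function(ct) length(ct@theta), 1L) != K))
    stop("all contours must share the same number of angles K")
  ds <- diff(stack@s)
  for (i in seq_len(n - 1)) {
    jump <- max(abs(stack@contours[[i + 1]]@radius -
                    stack@contours[[i]]@radius)) / 1000
    if (jump > 20 * ds[i])
      stop(sprintf(
        "connecting strip self-intersects between s = %.4f and %.4f mm",
        stack@s[i], stack@s[i + 1]))
  }
  verts <- matrix(0, n * K, 3)
  for (i in seq_len(n)) {
    fr <- .centerlineAt(centerline, stack@s[i])
    ct <- stack@contours[[i]]
    r <- ct@radius / 1000
    verts[(i - 1) * K + seq_len(K), ] <-
      matrix(fr$p, K, 3, byrow = TRUE) +
      (r * cos(ct@theta)) %o% fr$u + (r * sin(ct@theta)) %o% fr$v
  }
  faces <- matrix(0L, 2 * (n - 1) * K + 2 * K, 3)
  row <- 0L
  for (i in seq_len(n - 1)) {
    a <- (i - 1) * K + seq_len(K)
    b <- (i - 1) * K + c(2:K, 1)
    c1 <- i * K + seq_len(K)
    d1 <- i * K + c(2:K, 1)
    faces[row + seq_len(K), ] <- cbind(a, b, d1)
    faces[row + K + seq_len(K), ] <- cbind(a, d1, c1)
    row <- row + 2L * K
  }
  # end caps: fans to the end-contour centroids
  cen1 <- colMeans(verts[seq_len(K), , drop = FALSE])
  cen2 <- colMeans(verts[(n - 1) * K + seq_len(K), , drop = FALSE])
  verts <- rbind(verts, cen1, cen2)
  i1 <- n * K + 1L
  i2 <- n * K + 2L
  faces[row + seq_len(K), ] <- cbind(rep(i1, K), c(2:K, 1), seq_len(K))
  row <- row + K
  faces[row + seq_len(K), ] <-
    cbind(rep(i2, K), (n - 1) * K + seq_len(K), (n - 1) * K + c(2:K, 1))
  surf <- new("VesselSurface", vertices = verts, faces = faces)
  if (enclosedVolume(surf) < 0)
    surf <- new("VesselSurface", vertices = verts,
                faces = faces[, c(1, 3, 2)])
  surf
}

#' @describeIn VesselSurface-class Signed enclosed volume (mm^3) by the
#'   divergence theorem; positive for outward orientation.
#' @aliases enclosedVolume,VesselSurface-method
#' @export
setMethod("enclosedVolume", "VesselSurface", function(object) {
  v <- object@vertices
  f <- object@faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
      p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
      p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
})

#' Volume-preserving (band-pass) surface smoothing
#'
#' Taubin lambda/mu smoothing: each pass applies a shrinking Laplacian step
#' (`lambda > 0`) followed by an inflating step (`mu < -lambda`), which
#' suppresses surface roughness while preserving the enclosed volume. The
#' result is gated: if the volume changes by more than 1% an error advises
#' reducing the parameters.
#'
#' @param mesh a watertight [VesselSurface-class].
#' @param passes number of lambda+mu passes (default 20).
#' @param lambda positive smoothing step (default 0.5).
#' @param mu negative inflation step (default -0.53).
#' @return The smoothed [VesselSurface-class].
#' @export
smoothSurface <- function(mesh, passes = 20L, lambda = 0.5, mu = -0.53) {
  if (passes == 0L) return(mesh)
  v <- mesh@vertices
  f <- mesh@faces
  n <- nrow(v)
  edges <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  edges <- rbind(edges, edges[, 2:1])
  edges <- unique(edges)
  deg <- tabulate(edges[, 1], n)
  v0 <- enclosedVolume(mesh)
  lap <- function(x) {
    sums <- matrix(0, n, 3)
    for (c in 1:3)
      sums[, c] <- as.vector(rowsum(x[edges[, 2], c], edges[, 1],
                                    reorder = TRUE))
    sums / deg - x
  }
  for (p in seq_len(passes)) {
    v <- v + lambda * lap(v)
    v <- v + mu * lap(v)
  }
  out <- new("VesselSurface", vertices = v, faces = f)
  dv <- abs(enclosedVolume(out) - v0) / abs(v0)
  if (dv > 0.01)
    stop(sprintf(
      "smoothing changed the enclosed volume by %.2f%% (> 1%%); reduce passes or lambda",
      100 * dv))
  out
}

#' Add straight flow extensions to both vessel ends
#'
#' Extrudes each end contour along the end tangent for a length equal to
#' `factor` times the end's equivalent radius, with constant cross-section.
#' Extensions let the flow develop before entering the region of interest.
#'
#' @param stack a [ContourStack-class].
#' @param centerline a [Centerline-class] covering the stack.
#' @param factor extension length in units of the end radius (default 5).
#' @param spacing axial spacing of the extension contours, mm (default: the
#'   stack's median slice spacing).
#' @return A list with the extended `stack` and `centerline`. With
#'   `factor = 0` the inputs are returned unchanged.
#' @export
addFlowExtensions <- function(stack, centerline, factor = 5,
                              spacing = NULL) {
  if (factor == 0) return(list(stack = stack, centerline = centerline))
  if (factor < 0) stop("extension factor must be >= 0")
  if (is.null(spacing)) spacing <- stats::median(diff(stack@s))
  n <- length(stack@contours)
  dp <- diameterProfile(stack)
  rIn <- dp@diameter[1] / 2 / 1000   # mm
  rOut <- dp@diameter[n] / 2 / 1000
  lenIn <- factor * rIn
  lenOut <- factor * rOut

  frIn <- .centerlineAt(centerline, stack@s[1])
  frOut <- .centerlineAt(centerline, stack@s[n])
  mkSteps <- function(len) {
    m <- max(1L, ceiling(len / spacing))
    seq_len(m) * (len / m)
  }
  stIn <- rev(mkSteps(lenIn))   # farthest first for the proximal side
  stOut <- mkSteps(lenOut)

  ctIn <- lapply(stIn, function(d) {
    ct <- stack@contours[[1]]
    new("Contour", theta = ct@theta, radius = ct@radius,
        s = stack@s[1] - d)
  })
  ctOut <- lapply(stOut, function(d) {
    ct <- stack@contours[[n]]
    new("Contour", theta = ct@theta, radius = ct@radius,
        s = stack@s[n] + d)
  })
  newS <- c(stack@s[1] - stIn, stack@s, stack@s[n] + stOut)
  newStack <- new("ContourStack", contours = c(ctIn, stack@contours, ctOut),
                  s = newS, metadata = c(stack@metadata,
                                         list(extensionFactor = factor)))

  # extend the centerline linearly along the end tangents, replacing any
  # original samples outside the stack's arc range so the extensions are
  # straight extrusions
  keep <- centerline@arcLength >= stack@s[1] - 1e-9 &
    centerline@arcLength <= stack@s[n] + 1e-9
  ptsIn <- t(vapply(stIn, function(d) frIn$p - d * frIn$t, numeric(3)))
  ptsOut <- t(vapply(stOut, function(d) frOut$p + d * frOut$t, numeric(3)))
  reps <- function(m, x) matrix(x, m, 3, byrow = TRUE)
  newCl <- new("Centerline",
               points = rbind(ptsIn, centerline@points[keep, , drop = FALSE],
                              ptsOut),
               tangents = rbind(reps(length(stIn), frIn$t),
                                centerline@tangents[keep, , drop = FALSE],
                                reps(length(stOut), frOut$t)),
               normalU = rbind(reps(length(stIn), frIn$u),
                               centerline@normalU[keep, , drop = FALSE],
                               reps(length(stOut), frOut$u)),
               normalV = rbind(reps(length(stIn), frIn$v),
                               centerline@normalV[keep, , drop = FALSE],
                               reps(length(stOut), frOut$v)),
               arcLength = c(stack@s[1] - stIn,
                             centerline@arcLength[keep],
                             stack@s[n] + stOut))
  list(stack = newStack, centerline = newCl)
}
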