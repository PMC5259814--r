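#' @import methods
NULL

# ---- cast and phantom configuration ----------------------------------------

#' Tapering cast specification
#'
#' Geometry of the rigid tapering cuff placed around the right common carotid
#' artery (RCCA). The cast lumen tapers linearly from the proximal to the
#' distal inner diameter over the cast length; the vessel inside the cast is
#' compressed to the cast inner diameter minus twice the wall thickness.
#'
#' @slot proximalDiameter proximal inner diameter, micrometres (default 400).
#' @slot distalDiameter distal inner diameter, micrometres (default 200).
#' @slot castLength axial length of the taper, millimetres (default 1.5).
#' @slot outerDiameter outer diameter of the cast body, micrometres.
#' @slot castStart arc-length position of the proximal cast edge along the
#'   centerline, millimetres.
#' @seealso [castSpec()], [castInnerDiameter()]
#' @export
setClass("CastSpec",
  slots = c(
    proximalDiameter = "numeric",
    distalDiameter   = "numeric",
    castLength       = "numeric",
    outerDiameter    = "numeric",
    castStart        = "numeric"
  ),
  validity = function(object) {
    msg <- character()
    if (!(object@proximalDiameter > object@distalDiameter &&
          object@distalDiameter > 0))
      msg <- c(msg, "need proximalDiameter > distalDiameter > 0")
    if (!(object@outerDiameter > object@proximalDiameter))
      msg <- c(msg, "outerDiameter must exceed proximalDiameter")
    if (object@castLength <= 0) msg <- c(msg, "castLength must be > 0")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a tapering cast specification
#'
#' Defaults correspond to the standard shear-modifying carotid cast: inner
#' diameter tapering from 400 to 200 um over 1.5 mm.
#'
#' @param proximalDiameter,distalDiameter inner diameters (um).
#' @param castLength taper length (mm).
#' @param outerDiameter cast outer diameter (um).
#' @param castStart arc-length position of the proximal cast edge (mm).
#' @return A [CastSpec-class] object.
#' @examples
#' castSpec()
#' @export
castSpec <- function(proximalDiameter = 400, distalDiameter = 200,
                     castLength = 1.5, outerDiameter = 1000,
                     castStart = 6) {
  new("CastSpec", proximalDiameter = proximalDiameter,
      distalDiameter = distalDiameter, castLength = castLength,
      outerDiameter = outerDiameter, castStart = castStart)
}

#' Synthetic micro-CT phantom configuration
#'
#' Parameters of the synthetic contrast-enhanced micro-CT volume: grid,
#' Hounsfield-unit regime of lumen / soft-tissue background / cast material,
#' axial contrast fluctuation, noise, and the supersampling factor used to
#' emulate the partial-volume effect.
#'
#' All lengths are micrometres unless noted; `fluctuationPeriod`,
#' `curvaturePeriod` are millimetres.
#'
#' @slot gridShape integer(3), voxels per axis.
#' @slot voxelSize cubic voxel edge, um.
#' @slot lumenHuNoncast,lumenHuCast lumen HU outside / inside the cast.
#' @slot backgroundHu soft-tissue background HU.
#' @slot castHu HU of the cast material.
#' @slot noiseSd additive Gaussian noise SD, HU.
#' @slot fluctuationAmplitude axial lumen-intensity fluctuation as a fraction
#'   of the non-cast lumen-background contrast.
#' @slot fluctuationPeriod axial fluctuation period, mm.
#' @slot supersample per-axis subdivision used for partial-volume averaging.
#' @slot wallThicknessInCast compressed vessel wall thickness inside the
#'   cast, um.
#' @slot vesselRadiusNoncast lumen radius outside the cast, um.
#' @slot transitionLength length of the entrance/exit zones over which the
#'   lumen radius and contrast blend between the free and in-cast state, mm
#'   (keeps the true radius profile continuous).
#' @slot curvatureAmplitude,curvaturePeriod in-plane sinusoidal centerline
#'   offset (um) and its period (mm).
#' @slot seed RNG seed for the noise field.
#' @seealso [phantomConfig()], [generatePhantom()]
#' @export
setClass("PhantomConfig",
  slots = c(
    gridShape = "integer", voxelSize = "numeric",
    lumenHuNoncast = "numeric", lumenHuCast = "numeric",
    backgroundHu = "numeric", castHu = "numeric",
    noiseSd = "numeric", fluctuationAmplitude = "numeric",
    fluctuationPeriod = "numeric", supersample = "integer",
    wallThicknessInCast = "numeric", vesselRadiusNoncast = "numeric",
    transitionLength = "numeric",
    curvatureAmplitude = "numeric", curvaturePeriod = "numeric",
    seed = "integer"
  ),
  validity = function(object) {
    msg <- character()
    if (length(object@gridShape) != 3L || any(object@gridShape < 8L))
      msg <- c(msg, "gridShape must be three axes of at least 8 voxels")
    if (object@voxelSize <= 0) msg <- c(msg, "voxelSize must be > 0")
    if (object@supersample < 1L) msg <- c(msg, "supersample must be >= 1")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (object@vesselRadiusNoncast <= 0)
      msg <- c(msg, "vesselRadiusNoncast must be > 0")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a phantom configuration
#'
#' Defaults reproduce the published cross-animal average Hounsfield regime of
#' an eXIA-160 enhanced carotid scan: lumen 339 HU (non-cast) and 257 HU
#' (in-cast), soft-tissue background 53 HU, cast material -97 HU, on a 40 um
#' cubic grid of 160 x 160 x 300 voxels (6.4 x 6.4 x 12 mm).
#'
#' @param gridShape voxels per axis.
#' @param voxelSize voxel edge, um.
#' @param lumenHuNoncast,lumenHuCast,backgroundHu,castHu HU levels.
#' @param noiseSd Gaussian noise SD, HU.
#' @param fluctuationAmplitude fraction of non-cast contrast (default 0.1).
#' @param fluctuationPeriod mm (default 1.5).
#' @param supersample per-axis partial-volume subdivision (default 3).
#' @param wallThicknessInCast um (default 13.5).
#' @param vesselRadiusNoncast um (default 250).
#' @param transitionLength mm (default 0.3).
#' @param curvatureAmplitude um (default 200).
#' @param curvaturePeriod mm (default 8).
#' @param seed integer RNG seed.
#' @return A [PhantomConfig-class] object.
#' @export
phantomConfig <- function(gridShape = c(160L, 160L, 300L), voxelSize = 40,
                          lumenHuNoncast = 339, lumenHuCast = 257,
                          backgroundHu = 53, castHu = -97,
                          noiseSd = 30, fluctuationAmplitude = 0.1,
                          fluctuationPeriod = 1.5, supersample = 3L,
                          wallThicknessInCast = 13.5,
                          vesselRadiusNoncast = 250,
                          transitionLength = 0.3,
                          curvatureAmplitude = 200, curvaturePeriod = 8,
                          seed = 1L) {
  new("PhantomConfig", gridShape = as.integer(gridShape),
      voxelSize = voxelSize, lumenHuNoncast = lumenHuNoncast,
      lumenHuCast = lumenHuCast, backgroundHu = backgroundHu,
      castHu = castHu, noiseSd = noiseSd,
      fluctuationAmplitude = fluctuationAmplitude,
      fluctuationPeriod = fluctuationPeriod,
      supersample = as.integer(supersample),
      wallThicknessInCast = wallThicknessInCast,
      vesselRadiusNoncast = vesselRadiusNoncast,
      transitionLength = transitionLength,
      curvatureAmplitude = curvatureAmplitude,
      curvaturePeriod = curvaturePeriod, seed = as.integer(seed))
}

# ---- image containers ------------------------------------------------------

#' 3D Hounsfield-unit image volume
#'
#' A scalar 3D grid in Hounsfield units with isotropic voxel spacing. Voxels
#' are node-centered: the world position of voxel `(i, j, k)` (0-based) is
#' `worldOrigin + c(i, j, k) * voxelSize`. World coordinates are millimetres.
#'
#' @slot hu 3D array of HU values (integer after phantom rounding).
#' @slot voxelSize scalar voxel edge, mm.
#' @slot origin numeric(3) world position of voxel (0,0,0), mm.
#' @export
setClass("ImageVolume",
  slots = c(hu = "array", voxelSize = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@hu)) != 3L) msg <- c(msg, "hu must be a 3D array")
    if (object@voxelSize <= 0) msg <- c(msg, "voxelSize must be > 0")
    if (length(object@origin) != 3L) msg <- c(msg, "origin must be length 3")
    if (length(msg)) msg else TRUE
  }
)

#' Phantom ground truth
#'
#' The exact centerline, lumen radius profile and intensity parameters used to
#' build a synthetic phantom. Inside the cast the true lumen diameter equals
#' the cast inner diameter minus twice the compressed wall thickness.
#'
#' @slot centerline n x 3 matrix of centerline points, mm.
#' @slot arcLength arc length at each centerline sample, mm.
#' @slot trueRadius true lumen radius at each sample, um.
#' @slot cast the [CastSpec-class] used.
#' @slot huParams named list of the intensity settings.
#' @export
setClass("GroundTruth",
  slots = c(centerline = "matrix", arcLength = "numeric",
            trueRadius = "numeric", cast = "CastSpec", huParams = "list"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@centerline) != 3L)
      msg <- c(msg, "centerline must be n x 3")
    n <- nrow(object@centerline)
    if (length(object@arcLength) != n || length(object@trueRadius) != n)
      msg <- c(msg, "arcLength/trueRadius must match centerline rows")
    if (any(object@trueRadius <= 0)) msg <- c(msg, "trueRadius must be > 0")
    if (length(msg)) msg else TRUE
  }
)

# ---- centerline / cross-sections / contours --------------------------------

#' Arc-length parameterized centerline with rotation-minimizing frames
#'
#' Samples are uniformly spaced in arc length; each carries a unit tangent and
#' an orthonormal in-plane basis (u, v) propagated by rotation-minimizing
#' (double-reflection) transport, so consecutive frames twist minimally.
#'
#' @slot points n x 3 matrix, mm.
#' @slot tangents n x 3 unit tangents.
#' @slot normalU,normalV n x 3 in-plane basis vectors.
#' @slot arcLength numeric(n), mm, starting at 0.
#' @export
setClass("Centerline",
  slots = c(points = "matrix", tangents = "matrix",
            normalU = "matrix", normalV = "matrix", arcLength = "numeric"),
  validity = function(object) {
    msg <- character()
    n <- nrow(object@points)
    if (any(vapply(list(object@tangents, object@normalU, object@normalV),
                   nrow, 1L) != n))
      msg <- c(msg, "frame matrices must match points rows")
    tn <- sqrt(rowSums(object@tangents^2))
    if (any(abs(tn - 1) > 1e-9)) msg <- c(msg, "tangents must be unit norm")
    if (n > 1) {
      dotu <- rowSums(object@normalU[-n, , drop = FALSE] *
                      object@normalU[-1, , drop = FALSE])
      if (any(dotu < cos(10 * pi / 180)))
        msg <- c(msg, "consecutive frames rotate by >= 10 degrees")
      if (any(diff(object@arcLength) <= 0))
        msg <- c(msg, "arcLength must be strictly increasing")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Planar cross-section of an image volume
#'
#' A 2D HU grid sampled on the plane perpendicular to the centerline tangent
#' at arc position `s`. Pixel `(i, j)` lies at
#' `center + offsets[i]/1000 * axisU + offsets[j]/1000 * axisV` (offsets um,
#' world mm).
#'
#' @slot hu 2D matrix of HU values.
#' @slot spacing in-plane pixel spacing, um.
#' @slot offsets in-plane pixel offsets (shared by both axes), um.
#' @slot center centerline point, mm.
#' @slot axisU,axisV in-plane orthonormal basis.
#' @slot s arc position, mm.
#' @export
setClass("CrossSection",
  slots = c(hu = "matrix", spacing = "numeric", offsets = "numeric",
            center = "numeric", axisU = "numeric", axisV = "numeric",
            s = "numeric"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@hu) != length(object@offsets) ||
        ncol(object@hu) != length(object@offsets))
      msg <- c(msg, "hu grid must match offsets")
    if (object@spacing <= 0) msg <- c(msg, "spacing must be > 0")
    if (length(msg)) msg else TRUE
  }
)

#' Closed planar contour in radial representation
#'
#' The lumen border at one arc position, stored as a radius function
#' `r(theta)` sampled at K uniform angles about the centerline point.
#'
#' @slot theta numeric(K), uniform angles in `[0, 2*pi)`.
#' @slot radius numeric(K), um, strictly positive.
#' @slot s arc position, mm.
#' @export
setClass("Contour",
  slots = c(theta = "numeric", radius = "numeric", s = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@theta) != length(object@radius))
      msg <- c(msg, "theta and radius must have equal length")
    if (any(!is.finite(object@radius)) || any(object@radius <= 0))
      msg <- c(msg, "radius must be finite and > 0 everywhere")
    if (length(object@theta) > 1 &&
        max(abs(diff(object@theta) - diff(object@theta)[1])) > 1e-9)
      msg <- c(msg, "theta must be uniformly spaced")
    if (length(msg)) msg else TRUE
  }
)

#' Stack of per-slice contours along a vessel
#'
#' One closed contour per arc position, ordered proximal to distal. The
#' `metadata` list carries run information (region statistics, thresholds,
#' segmentation mode) when produced by [segmentVessel()].
#'
#' @slot contours list of [Contour-class] objects.
#' @slot s numeric arc positions, mm, strictly increasing.
#' @slot metadata named list.
#' @export
setClass("ContourStack",
  slots = c(contours = "list", s = "numeric", metadata = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@contours) != length(object@s))
      msg <- c(msg, "one arc position per contour required")
    if (length(object@s) > 1 && any(diff(object@s) <= 0))
      msg <- c(msg, "s must be strictly increasing")
    if (!all(vapply(object@contours, is, TRUE, "Contour")))
      msg <- c(msg, "contours must all be Contour objects")
    if (length(msg)) msg else TRUE
  }
)

# ---- region statistics and thresholds --------------------------------------

#' Per-slice lumen/background region statistics
#'
#' For each retained arc position: mean and SD of the HU values inside the
#' shrunken-contour lumen region and the expanded-annulus background region,
#' plus the contrast difference `C = L - B` and the voxel counts.
#'
#' @slot s arc positions, mm.
#' @slot lumenMean,lumenSD,bgMean,bgSD,contrast per-slice statistics, HU.
#' @slot nLumen,nBg pixel counts per region.
#' @export
setClass("RegionStats",
  slots = c(s = "numeric", lumenMean = "numeric", lumenSD = "numeric",
            bgMean = "numeric", bgSD = "numeric", contrast = "numeric",
            nLumen = "numeric", nBg = "numeric"),
  validity = function(object) {
    msg <- character()
    n <- length(object@s)
    lens <- vapply(list(object@lumenMean, object@lumenSD, object@bgMean,
                        object@bgSD, object@contrast, object@nLumen,
                        object@nBg), length, 1L)
    if (any(lens != n)) msg <- c(msg, "all fields must have equal length")
    if (n > 0 && (any(object@nLumen < 1) || any(object@nBg < 1)))
      msg <- c(msg, "each retained slice needs >= 1 lumen and background voxel")
    if (n > 0 &&
        max(abs(object@contrast - (object@lumenMean - object@bgMean))) > 1e-9)
      msg <- c(msg, "contrast must equal lumenMean - bgMean exactly")
    if (length(msg)) msg else TRUE
  }
)

#' Local and global segmentation thresholds
#'
#' Local thresholds are the per-contour midway values
#' `T_i = (L_i + B_i) / 2`; the global threshold is their arithmetic mean
#' along the vessel.
#'
#' @slot s arc positions, mm.
#' @slot local per-slice midway thresholds, HU.
#' @slot global scalar mean of the local thresholds, HU.
#' @export
setClass("ThresholdProfile",
  slots = c(s = "numeric", local = "numeric", global = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@local) != length(object@s))
      msg <- c(msg, "one local threshold per arc position required")
    if (length(object@global) != 1L)
      msg <- c(msg, "global threshold must be a scalar")
    if (length(object@local) &&
        abs(object@global - mean(object@local)) > 1e-9)
      msg <- c(msg, "global threshold must equal the mean of local thresholds")
    if (length(msg)) msg else TRUE
  }
)

# ---- geometry --------------------------------------------------------------

#' Equivalent-diameter profile along the vessel
#'
#' Per arc position: polygon area of the contour and the equivalent-area
#' diameter `D = 2 * sqrt(A / pi)`.
#'
#' @slot s arc positions, mm.
#' @slot area contour polygon area, um^2.
#' @slot diameter equivalent diameter, um.
#' @export
setClass("DiameterProfile",
  slots = c(s = "numeric", area = "numeric", diameter = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@area) != length(object@s) ||
        length(object@diameter) != length(object@s))
      msg <- c(msg, "fields must have equal length")
    if (any(object@diameter <= 0)) msg <- c(msg, "diameter must be > 0")
    if (length(msg)) msg else TRUE
  }
)

#' Triangulated lumen surface
#'
#' A watertight triangle mesh of the vessel lumen with consistent outward
#' orientation.
#'
#' @slot vertices n x 3 matrix, mm.
#' @slot faces m x 3 integer matrix of 1-based vertex indices.
#' @export
setClass("VesselSurface",
  slots = c(vertices = "matrix", faces = "matrix"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@vertices) != 3L) msg <- c(msg, "vertices must be n x 3")
    if (ncol(object@faces) != 3L) msg <- c(msg, "faces must be m x 3")
    if (nrow(object@faces) &&
        (min(object@faces) < 1 || max(object@faces) > nrow(object@vertices)))
      msg <- c(msg, "face indices out of range")
    if (length(msg)) msg else TRUE
  }
)

# ---- hemodynamics ----------------------------------------------------------

#' Inlet flow waveform over one cardiac cycle
#'
#' Time samples cover exactly one period, including the duplicated endpoint
#' (`time[1] = 0`, `time[n] = T`). `kind` records whether values are
#' velocities (m/s) or volumetric flow rates (mm^3/s).
#'
#' @slot time numeric, s, strictly increasing from 0 to the period.
#' @slot value numeric, velocity (m/s) or flow (mm^3/s).
#' @slot kind `"velocity"` or `"flow"`.
#' @export
setClass("FlowWaveform",
  slots = c(time = "numeric", value = "numeric", kind = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@time) != length(object@value))
      msg <- c(msg, "time and value must have equal length")
    if (length(object@time) > 1 && any(diff(object@time) <= 0))
      msg <- c(msg, "time must be strictly increasing")
    if (!object@kind %in% c("velocity", "flow"))
      msg <- c(msg, "kind must be 'velocity' or 'flow'")
    if (length(msg)) msg else TRUE
  }
)

#' Newtonian blood model
#'
#' Defaults are the standard constants for murine CFD: dynamic viscosity
#' 3.5e-3 kg/m/s and density 1060 kg/m^3.
#'
#' @slot viscosity dynamic viscosity, kg/m/s.
#' @slot density kg/m^3.
#' @export
setClass("BloodModel",
  slots = c(viscosity = "numeric", density = "numeric"),
  validity = function(object) {
    if (object@viscosity <= 0 || object@density <= 0)
      "viscosity and density must be > 0" else TRUE
  }
)

#' Construct a blood model
#' @param viscosity dynamic viscosity, kg/m/s (default 3.5e-3).
#' @param density kg/m^3 (default 1060).
#' @return A [BloodModel-class] object.
#' @export
bloodModel <- function(viscosity = 3.5e-3, density = 1060) {
  new("BloodModel", viscosity = viscosity, density = density)
}

#' Signed wall shear stress field
#'
#' Signed WSS tau(s, t) in Pa over a grid of arc positions (rows) and time
#' samples within one cardiac period (columns, endpoint duplicated).
#'
#' @slot s arc positions, mm.
#' @slot time time samples, s.
#' @slot tau matrix `length(s)` x `length(time)` of signed WSS, Pa.
#' @seealso [tawss()], [osi()]
#' @export
setClass("WSSField",
  slots = c(s = "numeric", time = "numeric", tau = "matrix"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@tau) != length(object@s) ||
        ncol(object@tau) != length(object@time))
      msg <- c(msg, "tau must be length(s) x length(time)")
    if (length(object@time) > 1 && any(diff(object@time) <= 0))
      msg <- c(msg, "time must be strictly increasing")
    if (length(msg)) msg else TRUE
  }
)
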