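# Accessor and show methods.

#' @rdname ImageVolume-class
#' @aliases voxelSize,ImageVolume-method
#' @export
setMethod("voxelSize", "ImageVolume", function(object) object@voxelSize)

#' @rdname ImageVolume-class
#' @aliases worldOrigin,ImageVolume-method
#' @export
setMethod("worldOrigin", "ImageVolume", function(object) object@origin)

#' @rdname ImageVolume-class
#' @aliases voxelData,ImageVolume-method
#' @export
setMethod("voxelData", "ImageVolume", function(object) object@hu)

#' @rdname Centerline-class
#' @aliases arcLength,Centerline-method
#' @export
setMethod("arcLength", "Centerline", function(object) object@arcLength)

#' @rdname Centerline-class
#' @aliases centerPoints,Centerline-method
#' @export
setMethod("centerPoints", "Centerline", function(object) object@points)

#' @rdname Centerline-class
#' @aliases tangents,Centerline-method
#' @export
setMethod("tangents", "Centerline", function(object) object@tangents)

#' @rdname ContourStack-class
#' @aliases contours,ContourStack-method
#' @export
setMethod("contours", "ContourStack", function(object) object@contours)

#' @rdname ContourStack-class
#' @aliases arcPositions,ContourStack-method
#' @export
setMethod("arcPositions", "ContourStack", function(object) object@s)

#' @rdname ThresholdProfile-class
#' @aliases localThreshold,ThresholdProfile-method
#' @export
setMethod("localThreshold", "ThresholdProfile", function(object) object@local)

#' @rdname ThresholdProfile-class
#' @aliases globalThreshold,ThresholdProfile-method
#' @export
setMethod("globalThreshold", "ThresholdProfile",
          function(object) object@global)

#' @rdname VesselSurface-class
#' @aliases vertices,VesselSurface-method
#' @export
setMethod("vertices", "VesselSurface", function(object) object@vertices)

#' @rdname VesselSurface-class
#' @aliases faces,VesselSurface-method
#' @export
setMethod("faces", "VesselSurface", function(object) object@faces)

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@hu)
  cat(sprintf("ImageVolume: %d x %d x %d voxels, %.0f um spacing\n",
              d[1], d[2], d[3], object@voxelSize * 1000))
  cat(sprintf("  HU range [%d, %d]\n", round(min(object@hu)),
              round(max(object@hu))))
})

setMethod("show", "Centerline", function(object) {
  n <- nrow(object@points)
  cat(sprintf("Centerline: %d samples, arc length %.3f mm\n",
              n, object@arcLength[n]))
})

setMethod("show", "Contour", function(object) {
  cat(sprintf("Contour at s = %.3f mm: K = %d, r = %.1f +/- %.1f um\n",
              object@s, length(object@theta), mean(object@radius),
              stats::sd(object@radius)))
})

setMethod("show", "ContourStack", function(object) {
  cat(sprintf("ContourStack: %d contours over s = [%.3f, %.3f] mm\n",
              length(object@contours), min(object@s), max(object@s)))
  if (!is.null(object@metadata$mode))
    cat(sprintf("  segmentation mode: %s\n", object@metadata$mode))
})

setMethod("show", "RegionStats", function(object) {
  cat(sprintf("RegionStats: %d slices\n", length(object@s)))
  if (length(object@s))
    cat(sprintf("  lumen %.0f +/- %.0f HU, background %.0f +/- %.0f HU\n",
                mean(object@lumenMean), stats::sd(object@lumenMean),
                mean(object@bgMean), stats::sd(object@bgMean)))
})

setMethod("show", "ThresholdProfile", function(object) {
  cat(sprintf(
    "ThresholdProfile: %d local thresholds, global = %.1f HU\n",
    length(object@local), object@global))
})

setMethod("show", "DiameterProfile", function(object) {
  cat(sprintf(
    "DiameterProfile: %d slices, D = [%.0f, %.0f] um\n",
    length(object@s), min(object@diameter), max(object@diameter)))
})

setMethod("show", "VesselSurface", function(object) {
  cat(sprintf("VesselSurface: %d vertices, %d faces, volume %.4f mm^3\n",
              nrow(object@vertices), nrow(object@faces),
              enclosedVolume(object)))
})

setMethod("show", "FlowWaveform", function(object) {
  unit <- if (object@kind == "velocity") "m/s" else "mm^3/s"
  cat(sprintf("FlowWaveform (%s): %d samples over T = %.4f s, mean %.3g %s\n",
              object@kind, length(object@time), max(object@time),
              mean(object@value[-length(object@value)]), unit))
})

setMethod("show", "WSSField", function(object) {
  cat(sprintf("WSSField: %d arc positions x %d time samples, |tau| max %.2f Pa\n",
              length(object@s), length(object@time), max(abs(object@tau))))
})

setMethod("show", "CastSpec", function(object) {
  cat(sprintf(
    "CastSpec: %g -> %g um over %g mm (outer %g um), start s = %g mm\n",
    object@proximalDiameter, object@distalDiameter, object@castLength,
    object@outerDiameter, object@castStart))
})
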