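# Accessor generics for the package's S4 containers.

#' @rdname ImageVolume-class
#' @param object,x an object.
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))

#' @rdname ImageVolume-class
#' @export
setGeneric("worldOrigin", function(object) standardGeneric("worldOrigin"))

#' @rdname ImageVolume-class
#' @export
setGeneric("voxelData", function(object) standardGeneric("voxelData"))

#' @rdname Centerline-class
#' @param object an object.
#' @export
setGeneric("arcLength", function(object) standardGeneric("arcLength"))

#' @rdname Centerline-class
#' @export
setGeneric("centerPoints", function(object) standardGeneric("centerPoints"))

#' @rdname Centerline-class
#' @export
setGeneric("tangents", function(object) standardGeneric("tangents"))

#' @rdname ContourStack-class
#' @export
setGeneric("contours", function(object) standardGeneric("contours"))

#' @rdname ContourStack-class
#' @export
setGeneric("arcPositions", function(object) standardGeneric("arcPositions"))

#' @rdname ThresholdProfile-class
#' @export
setGeneric("localThreshold", function(object) standardGeneric("localThreshold"))

#' @rdname ThresholdProfile-class
#' @export
setGeneric("globalThreshold",
           function(object) standardGeneric("globalThreshold"))

#' @rdname VesselSurface-class
#' @export
setGeneric("vertices", function(object) standardGeneric("vertices"))

#' @rdname VesselSurface-class
#' @export
setGeneric("faces", function(object) standardGeneric("faces"))

#' @rdname VesselSurface-class
#' @export
setGeneric("enclosedVolume", function(object) standardGeneric("enclosedVolume"))
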