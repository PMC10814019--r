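#' @rdname accessors
#' @export
setGeneric("pixelPitch", function(object) standardGeneric("pixelPitch"))

#' @rdname accessors
#' @export
setGeneric("occupancy", function(object) standardGeneric("occupancy"))

#' @rdname accessors
#' @export
setGeneric("axialVelocity", function(object) standardGeneric("axialVelocity"))

#' @rdname accessors
#' @export
setGeneric("iqData", function(object) standardGeneric("iqData"))

#' @rdname accessors
#' @export
setGeneric("frameRate", function(object) standardGeneric("frameRate"))

#' @rdname accessors
#' @export
setGeneric("centerFrequency", function(object) standardGeneric("centerFrequency"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setGeneric("vesselMask", function(object) standardGeneric("vesselMask"))

#' @rdname accessors
#' @export
setGeneric("roiMask", function(object) standardGeneric("roiMask"))

#' @rdname accessors
#' @export
setGeneric("skeletonNodes", function(object) standardGeneric("skeletonNodes"))

#' @rdname accessors
#' @export
setGeneric("skeletonSegments", function(object) standardGeneric("skeletonSegments"))

#' @rdname accessors
#' @export
setGeneric("nSegments", function(object) standardGeneric("nSegments"))

#' @rdname accessors
#' @export
setGeneric("nBranchPoints", function(object) standardGeneric("nBranchPoints"))

#' @rdname accessors
#' @export
setGeneric("nBifurcations", function(object) standardGeneric("nBifurcations"))
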