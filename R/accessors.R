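#' Accessors for choromvq data classes
#'
#' Small read-only accessors for the S4 containers; prefer these over direct
#' slot access.
#'
#' @param object a choromvq S4 object.
#' @return The requested component: matrices for image-like slots, scalars
#'   for metadata, data.frames/lists for graph structure.
#' @name accessors
#' @aliases pixelPitch occupancy axialVelocity iqData frameRate
#'   centerFrequency nFrames intensity provenance vesselMask roiMask
#'   skeletonNodes skeletonSegments nSegments nBranchPoints nBifurcations
NULL

#' @rdname accessors
setMethod("pixelPitch", "RasterMap", function(object) object@pixelPitch)
#' @rdname accessors
setMethod("pixelPitch", "IQEnsemble", function(object) object@pixelPitch)
#' @rdname accessors
setMethod("pixelPitch", "HDMIImage", function(object) object@pixelPitch)
#' @rdname accessors
setMethod("pixelPitch", "BinaryVesselMask", function(object) object@pixelPitch)
#' @rdname accessors
setMethod("pixelPitch", "Skeleton", function(object) object@pixelPitch)

#' @rdname accessors
setMethod("occupancy", "RasterMap", function(object) object@occupancy)
#' @rdname accessors
setMethod("axialVelocity", "RasterMap", function(object) object@axialVelocity)

#' @rdname accessors
setMethod("iqData", "IQEnsemble", function(object) object@data)
#' @rdname accessors
setMethod("frameRate", "IQEnsemble", function(object) object@frameRate)
#' @rdname accessors
setMethod("centerFrequency", "IQEnsemble", function(object) object@centerFrequency)
#' @rdname accessors
setMethod("nFrames", "IQEnsemble", function(object) dim(object@data)[3])

#' @rdname accessors
setMethod("intensity", "HDMIImage", function(object) object@intensity)
#' @rdname accessors
setMethod("provenance", "HDMIImage", function(object) object@provenance)

#' @rdname accessors
setMethod("vesselMask", "BinaryVesselMask", function(object) object@mask)
#' @rdname accessors
setMethod("roiMask", "BinaryVesselMask", function(object) object@roi)

#' @rdname accessors
setMethod("skeletonNodes", "Skeleton", function(object) object@nodes)
#' @rdname accessors
setMethod("skeletonSegments", "Skeleton", function(object) object@segments)
#' @rdname accessors
setMethod("nSegments", "Skeleton", function(object) length(object@segments))
#' @rdname accessors
setMethod("nBranchPoints", "Skeleton", function(object) {
  if (!nrow(object@nodes)) return(0L)
  sum(object@nodes$type == "branch_point")
})

#' @rdname accessors
setMethod("nSegments", "VesselTree", function(object) length(object@segments))
#' @rdname accessors
setMethod("nBifurcations", "VesselTree", function(object) length(object@bifurcations))

setMethod("show", "VesselTree", function(object) {
  cat("VesselTree with", length(object@segments), "segments and",
      length(object@bifurcations), "bifurcations\n")
  d <- vapply(object@segments, function(s) s$diameter_um, numeric(1))
  if (length(d))
    cat(sprintf("  diameters: %.0f-%.0f um; field %.1f x %.1f mm\n",
                min(d), max(d), object@fieldSize[1], object@fieldSize[2]))
})

setMethod("show", "RasterMap", function(object) {
  cat(sprintf("RasterMap %d x %d px @ %.1f um/px; lumen fraction %.3f\n",
              nrow(object@occupancy), ncol(object@occupancy),
              object@pixelPitch, mean(object@occupancy != 0)))
})

setMethod("show", "IQEnsemble", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "IQEnsemble %d x %d px, %d frames @ %.0f Hz (fc %.1f MHz, c %.0f m/s, %.1f um/px)\n",
    d[1], d[2], d[3], object@frameRate, object@centerFrequency,
    object@soundSpeed, object@pixelPitch))
})

setMethod("show", "HDMIImage", function(object) {
  cat(sprintf("HDMIImage %d x %d px @ %.1f um/px\n",
              nrow(object@intensity), ncol(object@intensity), object@pixelPitch))
  steps <- vapply(object@provenance, function(p) p$step, character(1))
  if (length(steps)) cat("  provenance:", paste(steps, collapse = " -> "), "\n")
})

setMethod("show", "BinaryVesselMask", function(object) {
  cat(sprintf("BinaryVesselMask %d x %d px; %d vessel px in %d ROI px\n",
              nrow(object@mask), ncol(object@mask),
              sum(object@mask != 0), sum(object@roi != 0)))
})

setMethod("show", "Skeleton", function(object) {
  cat(sprintf("Skeleton: %d segments, %d branch points, %d endpoints\n",
              nSegments(object), nBranchPoints(object),
              if (nrow(object@nodes)) sum(object@nodes$type == "endpoint") else 0L))
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: %d malignant / %d benign; P(NB=0) = %.2f / %.2f\n",
              object@malignant$n, object@benign$n,
              object@malignant$pNB0, object@benign$pNB0))
})

setMethod("show", "FirthFit", function(object) {
  cat("FirthFit:", if (object@converged) "converged" else "NOT converged",
      "in", object@iterations, "iterations\n")
  print(round(object@coefficients, 4))
  cat(sprintf("  penalized logLik %.4f", object@logLik))
  if (!is.na(object@lrt))
    cat(sprintf("; LRT %.3f on %d df, p = %.4g", object@lrt, object@df,
                object@pValue))
  cat("\n")
})

setMethod("show", "GroupAnalysis", function(object) {
  cat("GroupAnalysis of", object@params$nMalignant, "malignant vs",
      object@params$nBenign, "benign\n")
  cat("-- always-measurable biomarkers --\n")
  print(object@comparison, digits = 3)
  cat("-- branching biomarkers (2-df Firth LRT) --\n")
  print(object@branching, digits = 3)
  if (!is.null(object@subsetComparison)) {
    cat(sprintf("-- thickness <= %.1f mm subset --\n", object@params$cutoff))
    print(object@subsetComparison, digits = 3)
  }
})
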