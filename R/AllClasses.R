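#' VesselTree: ground-truth synthetic vasculature
#'
#' A binary branching vascular tree in physical (mm) coordinates.  Each
#' segment carries an ordered 2-D centerline polyline, a constant diameter
#' (micrometres) and a mean flow speed (mm/s).  Bifurcations record the
#' parent/daughter segment ids and the planned angle between the daughters.
#'
#' @slot segments list; each element a list with \code{points} (n x 2 matrix,
#'   columns \code{x} = lateral mm and \code{z} = depth mm), \code{diameter_um},
#'   \code{flow_mm_s}.
#' @slot parents integer vector, \code{NA} for the root; \code{parents[i]} is
#'   the segment whose distal endpoint segment \code{i} starts from.
#' @slot bifurcations list of lists with \code{parent}, \code{daughters}
#'   (integer ids) and \code{angle_deg}, the planned daughter-daughter angle.
#' @slot fieldSize numeric length-2, field of view (mm) the tree was grown in.
#'
#' @seealso \code{\link{generateVesselTree}}, \code{\link{rasterizeTree}}
#' @exportClass VesselTree
setClass("VesselTree",
  representation(
    segments = "list",
    parents = "integer",
    bifurcations = "list",
    fieldSize = "numeric"
  )
)

setValidity("VesselTree", function(object) {
  msg <- character()
  ns <- length(object@segments)
  if (length(object@parents) != ns)
    msg <- c(msg, "parents must have one entry per segment")
  for (s in object@segments) {
    if (!is.matrix(s$points) || ncol(s$points) != 2L || nrow(s$points) < 2L)
      msg <- c(msg, "each centerline needs an n x 2 matrix with n >= 2")
    if (!is.null(s$diameter_um) && s$diameter_um <= 0)
      msg <- c(msg, "segment diameters must be positive")
  }
  for (b in object@bifurcations) {
    if (b$angle_deg <= 0 || b$angle_deg >= 180)
      msg <- c(msg, "planned bifurcation angles must lie in (0, 180) degrees")
  }
  # every non-root segment starts at its parent's distal endpoint
  for (i in seq_len(ns)) {
    p <- object@parents[i]
    if (!is.na(p)) {
      child0 <- object@segments[[i]]$points[1L, ]
      parEnd <- object@segments[[p]]$points[nrow(object@segments[[p]]$points), ]
      if (max(abs(child0 - parEnd)) > 1e-9)
        msg <- c(msg, "child segments must start at the parent's distal endpoint")
    }
  }
  if (length(msg)) msg else TRUE
})

#' RasterMap: pixel rendering of a vessel tree
#'
#' Binary lumen occupancy plus the axial (depth-direction) blood velocity
#' field on an isotropic grid.  Row 1 is the shallowest depth; pixel centers
#' sit at \code{(i - 0.5) * pitch} for 1-based index \code{i}.
#'
#' @slot occupancy integer/logical matrix (depth x lateral), 1 inside lumens.
#' @slot axialVelocity numeric matrix, mm/s, nonzero only where occupancy is 1;
#'   positive values flow away from the transducer (increasing depth).
#' @slot pixelPitch numeric, micrometres per pixel (isotropic).
#'
#' @exportClass RasterMap
setClass("RasterMap",
  representation(
    occupancy = "matrix",
    axialVelocity = "matrix",
    pixelPitch = "numeric"
  )
)

setValidity("RasterMap", function(object) {
  msg <- character()
  if (!identical(dim(object@occupancy), dim(object@axialVelocity)))
    msg <- c(msg, "occupancy and axialVelocity must share a shape")
  if (object@pixelPitch <= 0) msg <- c(msg, "pixelPitch must be positive")
  if (any(object@axialVelocity[object@occupancy == 0] != 0))
    msg <- c(msg, "axial velocity must vanish outside the lumen occupancy")
  if (length(msg)) msg else TRUE
})

#' IQEnsemble: complex spatiotemporal ultrasound data cube
#'
#' Post-beamformed in-phase/quadrature data, depth x lateral x slow-time,
#' with the acquisition metadata needed to interpret Doppler shifts.
#'
#' @slot data complex 3-D array (depth x lateral x frames).
#' @slot frameRate numeric, slow-time frame rate in Hz.
#' @slot centerFrequency numeric, transmit center frequency in MHz.
#' @slot soundSpeed numeric, speed of sound in m/s.
#' @slot pixelPitch numeric, micrometres per pixel.
#'
#' @exportClass IQEnsemble
setClass("IQEnsemble",
  representation(
    data = "array",
    frameRate = "numeric",
    centerFrequency = "numeric",
    soundSpeed = "numeric",
    pixelPitch = "numeric"
  )
)

setValidity("IQEnsemble", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3-D array (depth x lateral x frames)")
  else if (dim(object@data)[3] < 2L)
    msg <- c(msg, "an ensemble needs at least 2 slow-time frames")
  if (!is.complex(object@data)) msg <- c(msg, "data must be complex")
  if (any(!is.finite(object@data))) msg <- c(msg, "data must be finite")
  for (nm in c("frameRate", "centerFrequency", "soundSpeed", "pixelPitch"))
    if (slot(object, nm) <= 0) msg <- c(msg, paste(nm, "must be positive"))
  if (length(msg)) msg else TRUE
})

#' HDMIImage: reconstructed microvessel image
#'
#' Nonnegative power-Doppler or vessel-enhanced intensity on the ensemble's
#' spatial grid, with an ordered provenance of the processing steps applied.
#'
#' @slot intensity numeric matrix, finite and >= 0 (arbitrary units).
#' @slot pixelPitch numeric, micrometres per pixel.
#' @slot provenance list of steps, each a list with \code{step} and parameters.
#'
#' @exportClass HDMIImage
setClass("HDMIImage",
  representation(
    intensity = "matrix",
    pixelPitch = "numeric",
    provenance = "list"
  )
)

setValidity("HDMIImage", function(object) {
  msg <- character()
  if (any(!is.finite(object@intensity)))
    msg <- c(msg, "intensity must be finite")
  else if (any(object@intensity < 0))
    msg <- c(msg, "intensity must be nonnegative")
  if (object@pixelPitch <= 0) msg <- c(msg, "pixelPitch must be positive")
  if (length(msg)) msg else TRUE
})

#' BinaryVesselMask: ROI-restricted vessel segmentation
#'
#' @slot mask integer/logical matrix, detected vessel pixels (subset of roi).
#' @slot roi integer/logical matrix of the same shape, region of interest.
#' @slot pixelPitch numeric, micrometres per pixel.
#'
#' @exportClass BinaryVesselMask
setClass("BinaryVesselMask",
  representation(
    mask = "matrix",
    roi = "matrix",
    pixelPitch = "numeric"
  )
)

setValidity("BinaryVesselMask", function(object) {
  msg <- character()
  if (!identical(dim(object@mask), dim(object@roi)))
    msg <- c(msg, "mask and roi must share a shape")
  if (any(object@mask == 1 & object@roi == 0))
    msg <- c(msg, "mask must be contained in the ROI")
  if (object@pixelPitch <= 0) msg <- c(msg, "pixelPitch must be positive")
  if (length(msg)) msg else TRUE
})

#' Skeleton: segmented one-pixel centerline graph
#'
#' The thinned centerline of a binary vessel mask, decomposed into maximal
#' node-free segments between typed nodes.  A branch point is a clustered
#' junction connected to three or more segments; an endpoint terminates a
#' single segment.  Each segment carries a per-pixel diameter profile in
#' micrometres (twice the Euclidean distance transform of the source mask).
#'
#' @slot nodes data.frame with columns \code{id}, \code{row}, \code{col},
#'   \code{type} (\code{"branch_point"} or \code{"endpoint"}).
#' @slot segments list; each element a list with \code{path} (ordered n x 2
#'   matrix of row/col pixel coordinates), \code{diam_um} (numeric per-pixel
#'   diameters), \code{node_from}, \code{node_to} (node ids or \code{NA}).
#' @slot mask integer matrix, the skeleton pixels themselves.
#' @slot pixelPitch numeric, micrometres per pixel.
#'
#' @exportClass Skeleton
setClass("Skeleton",
  representation(
    nodes = "data.frame",
    segments = "list",
    mask = "matrix",
    pixelPitch = "numeric"
  )
)

setValidity("Skeleton", function(object) {
  msg <- character()
  for (s in object@segments) {
    if (nrow(s$path) < 2L) msg <- c(msg, "segments need >= 2 pixels")
    if (length(s$diam_um) != nrow(s$path))
      msg <- c(msg, "diameter profile must match the path length")
  }
  if (nrow(object@nodes) &&
      !all(object@nodes$type %in% c("branch_point", "endpoint")))
    msg <- c(msg, "node types must be branch_point or endpoint")
  if (length(msg)) msg else TRUE
})

#' CohortSpec: generative description of a two-arm biomarker cohort
#'
#' Per-arm sample size, thickness moments, marginal family and moments for
#' each biomarker, and the probability of having no branch point (which
#' drives the structural missingness of the branching biomarkers).
#'
#' @slot malignant list with \code{n}, \code{thickness} (mean, sd),
#'   \code{markers} (data.frame: name, family, mean, sd), \code{pNB0}.
#' @slot benign same structure as \code{malignant}.
#'
#' @seealso \code{\link{cohortSpec}}, \code{\link{defaultCohortSpec}},
#'   \code{\link{generateCohort}}
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(
    malignant = "list",
    benign = "list"
  )
)

.validGroupSpec <- function(g, label) {
  msg <- character()
  if (is.null(g$n) || g$n < 0) msg <- c(msg, paste(label, "n must be >= 0"))
  if (any(g$markers$sd < 0)) msg <- c(msg, paste(label, "SDs must be >= 0"))
  if (g$pNB0 < 0 || g$pNB0 > 1)
    msg <- c(msg, paste(label, "pNB0 must lie in [0, 1]"))
  if (any(g$thickness < 0)) msg <- c(msg, paste(label, "thickness moments must be >= 0"))
  msg
}

setValidity("CohortSpec", function(object) {
  msg <- c(.validGroupSpec(object@malignant, "malignant"),
           .validGroupSpec(object@benign, "benign"))
  if (length(msg)) msg else TRUE
})

#' FirthFit: Firth penalized logistic regression fit
#'
#' @slot coefficients numeric, named coefficient vector.
#' @slot logLik numeric, penalized log-likelihood at the optimum.
#' @slot converged logical.
#' @slot iterations integer.
#' @slot lrt numeric, likelihood-ratio statistic vs the null model (NA if
#'   no comparison was requested).
#' @slot df integer, LRT degrees of freedom.
#' @slot pValue numeric, LRT p-value.
#'
#' @exportClass FirthFit
setClass("FirthFit",
  representation(
    coefficients = "numeric",
    logLik = "numeric",
    converged = "logical",
    iterations = "integer",
    lrt = "numeric",
    df = "integer",
    pValue = "numeric"
  ),
  prototype(lrt = NA_real_, df = NA_integer_, pValue = NA_real_)
)

setValidity("FirthFit", function(object) {
  msg <- character()
  if (any(!is.finite(object@coefficients)))
    msg <- c(msg, "Firth coefficients must be finite")
  if (!is.na(object@lrt) && object@lrt < -1e-8)
    msg <- c(msg, "LRT statistic must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' GroupAnalysis: full statistical comparison of a labeled cohort
#'
#' @slot comparison data.frame, one row per always-measurable biomarker with
#'   group moments, Wilcoxon p, AUC and bootstrap CI.
#' @slot branching data.frame, one row per branching biomarker with
#'   measurability counts, observed-subset moments and the 2-df LRT.
#' @slot subsetComparison data.frame or NULL, the comparison restricted to
#'   thickness <= cutoff.
#' @slot correlations matrix, pairwise-complete Pearson correlations.
#' @slot params list (cutoff, bootstrap B, seed, n per arm).
#'
#' @exportClass GroupAnalysis
setClass("GroupAnalysis",
  representation(
    comparison = "data.frame",
    branching = "data.frame",
    subsetComparison = "ANY",
    correlations = "matrix",
    params = "list"
  )
)
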