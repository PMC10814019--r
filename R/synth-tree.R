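#' Generate a ground-truth synthetic vascular tree
#'
#' Grows a binary branching tree from a root placed near the top of the
#' field of view.  Segments are straight chords perturbed by one period of a
#' perpendicular sinusoid (so the arc length has a closed quadrature form),
#' daughters leave the parent heading at plus/minus half the planned
#' bifurcation angle, and daughter diameters satisfy Murray's law
#' \eqn{d_p^\gamma = d_1^\gamma + d_2^\gamma} exactly for the requested
#' exponent.  Malignant-like trees are emulated with many bifurcations and a
#' large tortuosity amplitude; nevus-like trees with few and small.
#'
#' @param seed integer RNG seed; identical seeds give identical trees.
#' @param nBifurcations number of branch points to grow (>= 0); the tree then
#'   has \code{2 * nBifurcations + 1} segments.
#' @param tortuosityAmplitude amplitude (mm) of the sinusoidal centerline
#'   perturbation, applied exactly to every segment; 0 gives straight chords.
#' @param murrayExponent exponent \eqn{\gamma > 0} of the diameter branching
#'   law (3 = Murray's law).
#' @param rootDiameterUm diameter of the root segment, micrometres.
#' @param rootLengthMm chord length of the root segment, mm; lengths shrink
#'   by \code{lengthDecay} per generation.
#' @param lengthDecay per-generation chord-length decay factor.
#' @param angleRangeDeg range the planned daughter-daughter angle is drawn
#'   uniformly from, degrees (open interval of (0, 180)).
#' @param fieldSizeMm numeric length-2, lateral x depth field of view (mm);
#'   growth is steered back toward the field center near the boundary.
#' @param rootFlowMmS mean blood speed of the root segment (mm/s); daughter
#'   speeds scale with their diameter relative to the root.
#' @param daughterAsymmetry range of the Murray flow split drawn per
#'   bifurcation; 0.5 is a symmetric bifurcation.
#' @return A \linkS4class{VesselTree}.
#' @examples
#' tr <- generateVesselTree(seed = 1, nBifurcations = 4)
#' nSegments(tr)       # 9
#' nBifurcations(tr)   # 4
#' @export
generateVesselTree <- function(seed, nBifurcations = 0L,
                               tortuosityAmplitude = 0.1,
                               murrayExponent = 3,
                               rootDiameterUm = 600,
                               rootLengthMm = 3,
                               lengthDecay = 0.75,
                               angleRangeDeg = c(60, 120),
                               fieldSizeMm = c(12.8, 12.8),
                               rootFlowMmS = 10,
                               daughterAsymmetry = c(0.4, 0.6)) {
  if (nBifurcations < 0) stop("nBifurcations must be >= 0")
  if (tortuosityAmplitude < 0) stop("tortuosityAmplitude must be >= 0")
  if (rootDiameterUm <= 0) stop("rootDiameterUm must be positive")
  if (murrayExponent <= 0) stop("murrayExponent must be positive")
  if (rootLengthMm <= 0) stop("rootLengthMm must be positive")

  withSeed(seed, {
    margin <- tortuosityAmplitude + rootDiameterUm / 2000 + 0.2
    center <- fieldSizeMm / 2

    makeSegment <- function(start, headingRad, lengthMm, diameterUm, flow) {
      # steer back toward the field center if the chord would leave the field
      endp <- start + lengthMm * c(sin(headingRad), cos(headingRad))
      lo <- margin; hiX <- fieldSizeMm[1] - margin; hiZ <- fieldSizeMm[2] - margin
      if (endp[1] < lo || endp[1] > hiX || endp[2] < lo || endp[2] > hiZ) {
        toCenter <- atan2(center[1] - start[1], center[2] - start[2])
        headingRad <- toCenter + runif(1, -pi / 12, pi / 12)
        endp <- start + lengthMm * c(sin(headingRad), cos(headingRad))
        endp[1] <- clamp(endp[1], lo, hiX)
        endp[2] <- clamp(endp[2], lo, hiZ)
      }
      chord <- endp - start
      L <- sqrt(sum(chord^2))
      npts <- max(32L, ceiling(L / 0.04))
      s <- seq(0, 1, length.out = npts)
      u <- chord / L                       # unit chord direction
      v <- c(-u[2], u[1])                  # unit perpendicular
      disp <- tortuosityAmplitude * sin(2 * pi * s)
      pts <- cbind(start[1] + s * chord[1] + disp * v[1],
                   start[2] + s * chord[2] + disp * v[2])
      colnames(pts) <- c("x", "z")
      list(points = pts, diameter_um = diameterUm, flow_mm_s = flow,
           heading = atan2(chord[1], chord[2]))
    }

    rootStart <- c(center[1] + runif(1, -0.1, 0.1) * fieldSizeMm[1], margin)
    rootHeading <- runif(1, -pi / 10, pi / 10)  # roughly straight down
    segments <- list(makeSegment(rootStart, rootHeading, rootLengthMm,
                                 rootDiameterUm, rootFlowMmS))
    parents <- NA_integer_
    depth <- 0L
    bifurcations <- list()
    tips <- 1L  # FIFO queue of segment ids available for branching

    for (b in seq_len(nBifurcations)) {
      tip <- tips[1L]; tips <- tips[-1L]
      par <- segments[[tip]]
      angle <- runif(1, angleRangeDeg[1], angleRangeDeg[2])
      f <- runif(1, daughterAsymmetry[1], daughterAsymmetry[2])
      dPar <- par$diameter_um
      d1 <- dPar * f^(1 / murrayExponent)
      d2 <- dPar * (1 - f)^(1 / murrayExponent)
      childLen <- rootLengthMm * lengthDecay^(depth[tip] + 1L)
      start <- par$points[nrow(par$points), ]
      half <- angle * pi / 360
      ids <- integer(2)
      for (k in 1:2) {
        hd <- par$heading + if (k == 1) half else -half
        dk <- if (k == 1) d1 else d2
        seg <- makeSegment(start, hd, childLen, dk,
                           rootFlowMmS * dk / rootDiameterUm)
        segments[[length(segments) + 1L]] <- seg
        parents <- c(parents, tip)
        depth <- c(depth, depth[tip] + 1L)
        ids[k] <- length(segments)
      }
      tips <- c(tips, ids)
      bifurcations[[length(bifurcations) + 1L]] <-
        list(parent = tip, daughters = ids, angle_deg = angle)
    }

    new("VesselTree", segments = segments, parents = parents,
        bifurcations = bifurcations, fieldSize = fieldSizeMm)
  })
}

#' Deviation of a tree's true diameters from Murray's law
#'
#' For each recorded bifurcation, \eqn{|d_p^\gamma - \sum_i d_i^\gamma| /
#' d_p^\gamma} on the generated (noise-free) diameters.  Trees grown with
#' the same exponent deviate by 0 to machine precision.
#'
#' @param tree a \linkS4class{VesselTree}.
#' @param exponent branching-law exponent (default 3).
#' @return Numeric vector, one deviation per bifurcation.
#' @export
treeMurrayDeviation <- function(tree, exponent = 3) {
  vapply(tree@bifurcations, function(b) {
    dp <- tree@segments[[b$parent]]$diameter_um
    dd <- vapply(b$daughters, function(i) tree@segments[[i]]$diameter_um,
                 numeric(1))
    abs(dp^exponent - sum(dd^exponent)) / dp^exponent
  }, numeric(1))
}
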