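#' Vessel tortuosity per skeleton segment
#'
#' The distance-metric tortuosity: actual path length along the skeleton
#' divided by the straight (Euclidean) distance between the segment's
#' endpoints, floored at its theoretical minimum of 1.  The default path
#' length is the bias-corrected chain-code estimator of Vossepoel-Smeulders
#' (0.980 per orthogonal step, 1.406 per diagonal step, -0.091 per
#' direction change), which removes the ~5\% overestimate the raw
#' 1/sqrt(2) step metric incurs on curved digital lines;
#' \code{method = "chain"} gives the raw step sum.  Closed loops
#' (chord ~ 0) are excluded and reported via a message.
#'
#' @param skeleton a \linkS4class{Skeleton} with >= 1 segment.
#' @param method \code{"corrected"} (default) or \code{"chain"}.
#' @return List with \code{tau} (per segment, NA for excluded loops),
#'   \code{taumean}, \code{taumax}.
#' @export
tortuosity <- function(skeleton, method = c("corrected", "chain")) {
  method <- match.arg(method)
  segs <- skeletonSegments(skeleton)
  if (!length(segs)) stop("tortuosity needs at least one segment")
  pitch <- pixelPitch(skeleton)
  chainLength <- function(p) {
    d <- diff(p)
    if (method == "chain") return(sum(sqrt(rowSums(d^2))))
    manh <- abs(d[, 1]) + abs(d[, 2])      # 1 = orthogonal, 2 = diagonal
    ne <- sum(manh == 1L); nd <- sum(manh == 2L)
    dirs <- atan2(d[, 1], d[, 2])
    ncorn <- sum(abs(diff(dirs)) > 1e-9)
    0.980 * ne + 1.406 * nd - 0.091 * ncorn
  }
  tau <- vapply(segs, function(s) {
    p <- s$path
    # closed or nearly closed loops (including segments that start and end
    # at the same node) have no meaningful chord
    if (!is.na(s$node_from) && !is.na(s$node_to) &&
        s$node_from == s$node_to) return(NA_real_)
    chord <- sqrt(sum((p[nrow(p), ] - p[1, ])^2)) * pitch
    if (chord < 2 * pitch) return(NA_real_)
    max(1, chainLength(p) * pitch / chord)
  }, numeric(1))
  if (anyNA(tau))
    message(sum(is.na(tau)), " closed-loop segment(s) excluded from tortuosity")
  ok <- tau[!is.na(tau)]
  list(tau = tau,
       taumean = if (length(ok)) mean(ok) else NA_real_,
       taumax = if (length(ok)) max(ok) else NA_real_)
}

# incident segments of a node: list of (segment index, attached end)
.incidentSegments <- function(skeleton, nodeId) {
  segs <- skeletonSegments(skeleton)
  out <- list()
  for (i in seq_along(segs)) {
    nf <- segs[[i]]$node_from; nt <- segs[[i]]$node_to
    if (!is.na(nf) && nf == nodeId)
      out[[length(out) + 1L]] <- list(seg = i, end = 1L)
    if (!is.na(nt) && nt == nodeId)
      out[[length(out) + 1L]] <- list(seg = i, end = 2L)
  }
  out
}

# mean diameter of the k skeleton pixels nearest the attached end
.endDiameter <- function(seg, end, k = 5L) {
  d <- seg$diam_um
  n <- length(d)
  idx <- if (end == 1L) seq_len(min(k, n)) else seq(max(1L, n - k + 1L), n)
  mean(d[idx])
}

#' Murray's deviation at each bifurcation
#'
#' At each branch point the incident segment with the largest near-junction
#' mean diameter is taken as the parent and the others as daughters;
#' the deviation from Murray's law is
#' \eqn{|d_p^\gamma - \sum_i d_i^\gamma| / d_p^\gamma} with diameters
#' averaged over the \code{k} skeleton pixels nearest the junction.
#' When the skeleton has no branch point the biomarker is structurally
#' unmeasurable.
#'
#' @param skeleton a \linkS4class{Skeleton}.
#' @param exponent branching-law exponent \eqn{\gamma} (3 = Murray's law).
#' @param k number of near-junction skeleton pixels averaged per diameter.
#' @return List with \code{md} (per bifurcation), \code{MDmean},
#'   \code{MDmax}, \code{measurable}.
#' @export
murrayDeviation <- function(skeleton, exponent = 3, k = 5L) {
  nodes <- skeletonNodes(skeleton)
  bp <- if (nrow(nodes)) nodes$id[nodes$type == "branch_point"] else integer()
  if (!length(bp))
    return(list(md = numeric(), MDmean = NA_real_, MDmax = NA_real_,
                measurable = FALSE))
  segs <- skeletonSegments(skeleton)
  md <- vapply(bp, function(nid) {
    inc <- .incidentSegments(skeleton, nid)
    dd <- vapply(inc, function(x) .endDiameter(segs[[x$seg]], x$end, k),
                 numeric(1))
    dp <- max(dd)
    dsum <- sum(dd[-which.max(dd)]^exponent)
    abs(dp^exponent - dsum) / dp^exponent
  }, numeric(1))
  list(md = md, MDmean = mean(md), MDmax = max(md), measurable = TRUE)
}

#' Bifurcation angle at each branch point
#'
#' Daughter directions are unit vectors from the junction along each
#' daughter's first \code{k} skeleton pixels; the bifurcation angle is the
#' angle between the two daughters (for more than two daughters, the
#' maximum pairwise daughter angle).  The parent is the incident segment
#' with the largest near-junction diameter.  Structurally unmeasurable
#' when there is no branch point.
#'
#' @inheritParams murrayDeviation
#' @return List with \code{ba} (degrees, per bifurcation), \code{BAmean},
#'   \code{BAmax}, \code{measurable}.
#' @export
bifurcationAngle <- function(skeleton, k = 5L) {
  nodes <- skeletonNodes(skeleton)
  bp <- if (nrow(nodes)) nodes$id[nodes$type == "branch_point"] else integer()
  if (!length(bp))
    return(list(ba = numeric(), BAmean = NA_real_, BAmax = NA_real_,
                measurable = FALSE))
  segs <- skeletonSegments(skeleton)
  ba <- vapply(bp, function(nid) {
    inc <- .incidentSegments(skeleton, nid)
    dd <- vapply(inc, function(x) .endDiameter(segs[[x$seg]], x$end, k),
                 numeric(1))
    daughters <- inc[-which.max(dd)]
    jc <- as.numeric(nodes[nodes$id == nid, c("row", "col")])
    dirs <- lapply(daughters, function(x) {
      p <- segs[[x$seg]]$path
      n <- nrow(p)
      tgt <- if (x$end == 1L) p[min(k, n), ] else p[max(1L, n - k + 1L), ]
      v <- as.numeric(tgt) - jc
      nv <- sqrt(sum(v^2))
      if (nv < 1e-12) c(0, 0) else v / nv
    })
    if (length(dirs) < 2L) return(NA_real_)
    best <- 0
    for (a in seq_len(length(dirs) - 1L))
      for (b in (a + 1L):length(dirs)) {
        ang <- acos(clamp(sum(dirs[[a]] * dirs[[b]]), -1, 1)) * 180 / pi
        best <- max(best, ang)
      }
    best
  }, numeric(1))
  ba <- ba[!is.na(ba)]
  if (!length(ba))
    return(list(ba = numeric(), BAmean = NA_real_, BAmax = NA_real_,
                measurable = FALSE))
  list(ba = ba, BAmean = mean(ba), BAmax = max(ba), measurable = TRUE)
}

#' Box-counting fractal dimension of a vascular network
#'
#' Counts the number \eqn{N(\epsilon)} of \eqn{\epsilon \times \epsilon}
#' grid boxes containing at least one foreground pixel over a dyadic range
#' of box sizes, and returns the least-squares slope of
#' \eqn{\log N} versus \eqn{\log(1/\epsilon)}.
#'
#' @param x a \linkS4class{Skeleton} (its skeleton mask is used) or a
#'   binary matrix.
#' @param boxSizes box edge lengths in pixels; default dyadic
#'   \code{1, 2, 4, ...} up to a quarter of the smaller image dimension.
#'   At least 4 sizes are required.
#' @return The fractal dimension (slope), or \code{NA} with a warning for
#'   an empty mask.
#' @export
fractalDimension <- function(x, boxSizes = NULL) {
  m <- if (is(x, "Skeleton")) x@mask else (x != 0) * 1L
  idx <- which(m == 1L)
  if (!length(idx)) {
    warning("empty mask: fractal dimension undefined")
    return(NA_real_)
  }
  if (is.null(boxSizes)) {
    kmax <- floor(log2(min(dim(m)) / 4))
    boxSizes <- 2^(0:max(kmax, 3))
  }
  if (length(boxSizes) < 4L) stop("need at least 4 box sizes")
  nr <- nrow(m)
  rr <- ((idx - 1L) %% nr)
  cc <- ((idx - 1L) %/% nr)
  N <- vapply(boxSizes, function(eps) {
    length(unique((rr %/% eps) * 1e6 + (cc %/% eps)))
  }, numeric(1))
  unname(coef(lm(log(N) ~ log(1 / boxSizes)))[2])
}

#' Compute the twelve microvessel biomarkers from an image and ROI
#'
#' Composition of \code{\link{binarizeVessels}},
#' \code{\link{skeletonizeVessels}} and the metric operations.  Diameter
#' aggregates are the mean and maximum over per-segment mean diameters;
#' tortuosity is aggregated over segments; Murray's deviation and
#' bifurcation angle over branch points, with structural missingness when
#' the network has no branch point.
#'
#' @param image an \linkS4class{HDMIImage} or numeric matrix.
#' @param roi binary ROI matrix (default: whole image).
#' @param config named list of overrides: \code{binarize_method},
#'   \code{min_object_px}, \code{prune_px}, \code{murray_exponent},
#'   \code{fd_source} (\code{"skeleton"} or \code{"mask"}),
#'   \code{junction_k}.
#' @param pixelPitchUm pitch when \code{image} is a bare matrix.
#' @return One-row data.frame with the 12 biomarkers and
#'   \code{measurable_MD_BA}.
#' @examples
#' m <- matrix(0, 48, 48); m[20:24, 5:44] <- 1
#' computeBiomarkers(m, pixelPitchUm = 50)
#' @export
computeBiomarkers <- function(image, roi = NULL, config = list(),
                              pixelPitchUm = NULL) {
  mask <- binarizeVessels(image, roi,
                          method = config$binarize_method %||% "otsu",
                          minObjectPx = config$min_object_px %||% 4L,
                          quantile = config$binarize_quantile %||% 0.9,
                          hysteresisRatio = config$hysteresis_ratio %||% (1 / 3),
                          closeRadiusPx = config$close_radius_px %||% 2L,
                          maxHolePx = config$max_hole_px %||% 16L,
                          thresholdFloor = config$threshold_floor %||% 0.1,
                          pixelPitchUm = pixelPitchUm)
  skel <- skeletonizeVessels(mask, prunePx = config$prune_px %||% 4)
  rec <- data.frame(VD = vesselDensity(mask),
                    Dmean = NA_real_, Dmax = NA_real_,
                    NV = nSegments(skel), mvFD = NA_real_,
                    NB = nBranchPoints(skel),
                    taumean = NA_real_, taumax = NA_real_,
                    MDmean = NA_real_, MDmax = NA_real_,
                    BAmean = NA_real_, BAmax = NA_real_,
                    measurable_MD_BA = 0L)
  if (nSegments(skel) == 0L) return(rec)

  segD <- vapply(skeletonSegments(skel), function(s) mean(s$diam_um),
                 numeric(1))
  rec$Dmean <- mean(segD); rec$Dmax <- max(segD)
  tau <- tortuosity(skel)
  rec$taumean <- tau$taumean; rec$taumax <- tau$taumax
  fdSrc <- config$fd_source %||% "skeleton"
  rec$mvFD <- fractalDimension(if (fdSrc == "mask") vesselMask(mask) else skel)
  kJ <- config$junction_k %||% 5L
  md <- murrayDeviation(skel, exponent = config$murray_exponent %||% 3,
                        k = kJ)
  baA <- bifurcationAngle(skel, k = kJ)
  if (md$measurable) { rec$MDmean <- md$MDmean; rec$MDmax <- md$MDmax }
  if (baA$measurable) { rec$BAmean <- baA$BAmean; rec$BAmax <- baA$BAmax }
  rec$measurable_MD_BA <- as.integer(md$measurable && baA$measurable)
  rec
}
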