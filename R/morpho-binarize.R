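#' Binarize a microvessel image within a region of interest
#'
#' The threshold is computed from ROI pixels only (default: Otsu's method on
#' the ROI histogram); connected components smaller than \code{minObjectPx}
#' are removed and the result is intersected with the ROI.  A constant ROI
#' (no contrast) yields an empty mask.
#'
#' Because vesselness responses are sparse and right-skewed, a plain Otsu
#' cut tends to land inside the vessel's own brightness distribution and
#' truncate dim stretches; with \code{hysteresisRatio < 1} the Otsu
#' threshold therefore only seeds the mask, which is grown into connected
#' pixels above \code{hysteresisRatio * threshold} (hysteresis
#' thresholding; set the ratio to 1 to disable).
#'
#' @param image an \linkS4class{HDMIImage} or numeric matrix.
#' @param roi logical/integer matrix of the same shape; must be nonempty.
#' @param method \code{"otsu"} or \code{"quantile"}.
#' @param minObjectPx minimum connected-component size kept (8-connectivity).
#' @param quantile threshold quantile when \code{method = "quantile"}.
#' @param hysteresisRatio low-to-high threshold ratio for hysteresis
#'   growing (1 = single threshold).
#' @param closeRadiusPx disk radius of a morphological closing applied to
#'   the thresholded mask before small-object removal; bridges small
#'   speckle dropouts and junction gaps left by the tubularity filter
#'   (0 disables).
#' @param thresholdFloor minimum threshold as a fraction of the ROI
#'   dynamic range (guards the Otsu cut against very sparse foregrounds).
#' @param maxHolePx largest interior hole (in pixels) filled after
#'   thresholding; speckle nulls inside lumens would otherwise yield
#'   spurious closed-loop skeletons (0 disables).
#' @param pixelPitchUm pixel pitch when \code{image} is a bare matrix.
#' @return A \linkS4class{BinaryVesselMask}.
#' @export
binarizeVessels <- function(image, roi = NULL, method = c("otsu", "quantile"),
                            minObjectPx = 4L, quantile = 0.9,
                            hysteresisRatio = 1 / 3, closeRadiusPx = 2L,
                            maxHolePx = 16L, thresholdFloor = 0.1,
                            pixelPitchUm = NULL) {
  method <- match.arg(method)
  if (is(image, "HDMIImage")) {
    img <- intensity(image)
    pitch <- pixelPitch(image)
  } else {
    img <- image
    pitch <- pixelPitchUm %||% 50
  }
  if (any(!is.finite(img))) stop("image must be finite")
  if (is.null(roi)) roi <- matrix(1L, nrow(img), ncol(img))
  roi <- (roi != 0) * 1L
  if (!identical(dim(roi), dim(img))) stop("roi shape must match the image")
  if (!sum(roi)) stop("ROI is empty")

  vals <- img[roi == 1L]
  rng <- range(vals)
  if (diff(rng) == 0) {
    # degenerate (constant) ROI: nothing separable
    mask <- matrix(0L, nrow(img), ncol(img))
    return(new("BinaryVesselMask", mask = mask, roi = roi,
               pixelPitch = pitch))
  }
  thr <- if (method == "otsu") {
    v <- (vals - rng[1]) / diff(rng)
    rng[1] + diff(rng) * otsu(Image(matrix(v, nrow = 1)), range = c(0, 1))
  } else {
    stats::quantile(vals, quantile, names = FALSE)
  }
  # floor: with very sparse foreground Otsu can split the background
  # (noise) cluster instead; never threshold below thresholdFloor of the
  # ROI dynamic range
  thr <- max(thr, rng[1] + thresholdFloor * diff(rng))
  dropSmall <- function(mask, minPx) {
    if (minPx > 1L && any(mask == 1L)) {
      lab <- label8(mask)
      sizes <- tabulate(lab[lab > 0L])
      small <- which(sizes < minPx)
      if (length(small)) mask[lab %in% small] <- 0L
    }
    mask
  }
  mask <- (img > thr & roi == 1L) * 1L
  if (hysteresisRatio < 1 && any(mask == 1L)) {
    lowThr <- rng[1] + (thr - rng[1]) * hysteresisRatio
    weak <- (img > lowThr & roi == 1L) * 1L
    lab <- label8(weak)
    keep <- unique(lab[mask == 1L])
    mask <- (weak == 1L & lab %in% keep) * 1L
  }
  # drop isolated speckle/noise blobs BEFORE closing so that closing
  # cannot weld them into spurious networks
  mask <- dropSmall(mask, minObjectPx)
  if (closeRadiusPx > 0L && any(mask == 1L)) {
    closed <- EBImage::closing(Image(mask),
                               makeBrush(2L * closeRadiusPx + 1L, "disc"))
    mask <- matrix(as.integer(EBImage::imageData(closed) > 0),
                   nrow(mask), ncol(mask))
    mask <- mask * roi
  }
  if (maxHolePx > 0L && any(mask == 1L)) {
    # interior speckle nulls punch small holes in lumens; their ring
    # skeletons would show up as spurious closed loops.  Only small holes
    # are filled: large enclosed regions are genuine background.
    filled <- matrix(as.integer(
      EBImage::imageData(EBImage::fillHull(Image(mask))) > 0),
      nrow(mask), ncol(mask))
    holes <- (filled == 1L & mask == 0L) * 1L
    if (any(holes == 1L)) {
      lab <- label8(holes)
      sizes <- tabulate(lab[lab > 0L])
      small <- which(sizes <= maxHolePx)
      if (length(small)) mask[holes == 1L & lab %in% small] <- 1L
    }
  }
  mask <- dropSmall(mask, minObjectPx)
  new("BinaryVesselMask", mask = mask, roi = roi, pixelPitch = pitch)
}

# 8-connected component labeling of a binary matrix (igraph-backed).
label8 <- function(mask) {
  idx <- which(mask == 1L)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (!length(idx)) return(lab)
  nr <- nrow(mask)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  pos <- match(idx, idx)
  lut <- integer(length(mask)); lut[idx] <- seq_along(idx)
  edges <- NULL
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- rr + off[1]; c2 <- cc + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(mask)
    j <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- lut[j] > 0L
    if (any(hit))
      edges <- rbind(edges, cbind(pos[ok][hit], lut[j][hit]))
  }
  if (is.null(edges)) {
    comp <- seq_along(idx)
  } else {
    g <- graph_from_edgelist(edges, directed = FALSE)
    # isolated pixels may be missing from the edge list
    nv <- length(idx)
    if (igraph::vcount(g) < nv) g <- igraph::add_vertices(g, nv - igraph::vcount(g))
    comp <- components(g)$membership
  }
  lab[idx] <- comp
  lab
}

#' Vessel density of a binary mask
#'
#' Fraction of the ROI area occupied by detected vessel pixels.
#'
#' @param mask a \linkS4class{BinaryVesselMask}.
#' @return Numeric in [0, 1].
#' @export
vesselDensity <- function(mask) {
  nRoi <- sum(roiMask(mask) != 0)
  if (!nRoi) stop("ROI is empty")
  sum(vesselMask(mask) != 0) / nRoi
}
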