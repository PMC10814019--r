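#' SVD clutter filter on the Casorati matrix
#'
#' Reshapes the ensemble to its Casorati form (pixels x frames), takes the
#' singular value decomposition, and zeroes the singular components with
#' index \code{<= rankLow} (slow, high-energy tissue clutter) and
#' \code{> rankHigh} (noise subspace).  By Parseval, the retained energy is
#' the sum of the retained squared singular values.
#'
#' @param ensemble an \linkS4class{IQEnsemble}.
#' @param rankLow number of leading (tissue) components to discard;
#'   \code{0} keeps everything from the top.
#' @param rankHigh last retained component; defaults to the full rank.
#' @return A filtered \linkS4class{IQEnsemble}.
#' @examples
#' tr <- generateVesselTree(seed = 4, nBifurcations = 0)
#' iq <- simulateIQ(rasterizeTree(tr, 50), nFrames = 8, seed = 5)
#' flt <- svdClutterFilter(iq, rankLow = 1)
#' @export
svdClutterFilter <- function(ensemble, rankLow = 2L, rankHigh = NULL) {
  d <- dim(iqData(ensemble))
  full <- min(d[1] * d[2], d[3])
  if (is.null(rankHigh)) rankHigh <- full
  rankLow <- as.integer(rankLow); rankHigh <- as.integer(rankHigh)
  if (rankLow < 0 || rankHigh > full || rankLow >= rankHigh)
    stop("rank bounds must satisfy 0 <= rankLow < rankHigh <= min(Npix, Nt)")

  X <- matrix(iqData(ensemble), d[1] * d[2], d[3])
  sv <- svd(X)
  keep <- sv$d
  keep[seq_len(rankLow)] <- 0
  if (rankHigh < length(keep)) keep[(rankHigh + 1L):length(keep)] <- 0
  Xf <- sv$u %*% (keep * Conj(t(sv$v)))
  new("IQEnsemble", data = array(Xf, d), frameRate = frameRate(ensemble),
      centerFrequency = centerFrequency(ensemble),
      soundSpeed = ensemble@soundSpeed, pixelPitch = pixelPitch(ensemble))
}

#' Power-Doppler image of a (filtered) IQ ensemble
#'
#' Per-pixel mean of the squared signal magnitude over slow time; after
#' clutter filtering this is proportional to moving-scatterer (blood)
#' energy.
#'
#' @param ensemble an \linkS4class{IQEnsemble}.
#' @return An \linkS4class{HDMIImage}.
#' @export
powerDoppler <- function(ensemble) {
  arr <- iqData(ensemble)
  d <- dim(arr)
  img <- matrix(rowMeans(matrix(Mod(arr)^2, d[1] * d[2], d[3])), d[1], d[2])
  new("HDMIImage", intensity = img, pixelPitch = pixelPitch(ensemble),
      provenance = list(list(step = "power_doppler",
                             n_frames = dim(arr)[3])))
}

# Hessian of a smoothed image at one scale, gamma = 2 normalized (x sigma^2).
.hessianAtScale <- function(img, sigma) {
  g <- gaussSmooth(img, sigma)
  pad <- function(m) m[c(1, seq_len(nrow(m)), nrow(m)),
                       c(1, seq_len(ncol(m)), ncol(m))]
  gp <- pad(g)
  n <- nrow(g); m <- ncol(g)
  ctr <- gp[2:(n + 1), 2:(m + 1)]
  drr <- gp[3:(n + 2), 2:(m + 1)] + gp[1:n, 2:(m + 1)] - 2 * ctr
  dcc <- gp[2:(n + 1), 3:(m + 2)] + gp[2:(n + 1), 1:m] - 2 * ctr
  drc <- (gp[3:(n + 2), 3:(m + 2)] + gp[1:n, 1:m] -
          gp[3:(n + 2), 1:m] - gp[1:n, 3:(m + 2)]) / 4
  list(rr = drr * sigma^2, cc = dcc * sigma^2, rc = drc * sigma^2)
}

#' Morphological background suppression and multiscale vessel enhancement
#'
#' A white top-hat with a disk structuring element removes slowly varying
#' background, then a multiscale Hessian tubularity filter highlights
#' bright ridges: at each scale \eqn{\sigma} the eigenvalues
#' \eqn{|\lambda_1| \le |\lambda_2|} of the \eqn{\sigma}-smoothed,
#' \eqn{\sigma^2}-normalized Hessian give the blobness ratio
#' \eqn{R_b = \lambda_1/\lambda_2} and structureness
#' \eqn{S = \sqrt{\lambda_1^2 + \lambda_2^2}}; the response is
#' \eqn{\exp(-R_b^2/2\beta^2)(1 - \exp(-S^2/2c^2))}, zero where
#' \eqn{\lambda_2 > 0} (not a bright ridge), maximized over scales.
#' \eqn{\beta = 0.5} and \eqn{c} is half the maximal structureness at that
#' scale, so the response is invariant to additive intensity offsets.
#'
#' @param image an \linkS4class{HDMIImage}.
#' @param scalesPx Gaussian scales in pixels.
#' @param tophatRadiusPx disk radius of the top-hat background suppression;
#'   \code{0} disables it.
#' @param beta blobness sensitivity (default 0.5).
#' @return An \linkS4class{HDMIImage} with the vesselness response.
#' @export
enhanceVessels <- function(image, scalesPx = c(1, 1.5, 2, 3, 4),
                           tophatRadiusPx = 8, beta = 0.5) {
  if (!length(scalesPx) || any(scalesPx <= 0))
    stop("scalesPx must be a nonempty set of positive scales")
  img <- intensity(image)
  if (tophatRadiusPx > 0) {
    brush <- makeBrush(2 * round(tophatRadiusPx) + 1, shape = "disc")
    img <- matrix(EBImage::imageData(whiteTopHat(Image(img), brush)),
                  nrow(img), ncol(img))
  }
  # first pass: eigenvalues at every scale, for the image-wide S maximum
  eig <- lapply(scalesPx, function(sg) {
    H <- .hessianAtScale(img, sg)
    tr <- H$rr + H$cc
    disc <- sqrt(pmax((H$rr - H$cc)^2 + 4 * H$rc^2, 0))
    e1 <- (tr + disc) / 2
    e2 <- (tr - disc) / 2
    big <- ifelse(abs(e1) >= abs(e2), e1, e2)   # lambda2: larger magnitude
    small <- ifelse(abs(e1) >= abs(e2), e2, e1) # lambda1
    list(big = big, small = small, S = sqrt(big^2 + small^2))
  })
  cpar <- max(vapply(eig, function(e) max(e$S), numeric(1))) / 2
  resp <- matrix(0, nrow(img), ncol(img))
  if (cpar > 0) {
    for (e in eig) {
      Rb <- ifelse(e$big != 0, e$small / e$big, 0)
      v <- exp(-Rb^2 / (2 * beta^2)) * (1 - exp(-e$S^2 / (2 * cpar^2)))
      v[e$big > 0] <- 0                         # dark ridges rejected
      resp <- pmax(resp, v)
    }
  }
  new("HDMIImage", intensity = resp, pixelPitch = pixelPitch(image),
      provenance = c(provenance(image),
                     list(list(step = "tophat", radius_px = tophatRadiusPx),
                          list(step = "vesselness", scales_px = scalesPx,
                               beta = beta))))
}

#' Full microvessel image formation chain
#'
#' Composes \code{\link{svdClutterFilter}}, \code{\link{powerDoppler}},
#' logarithmic compression and \code{\link{enhanceVessels}}; every step and
#' its parameters are recorded in the image provenance.  Log compression
#' (standard display-domain processing for ultrasound) equalizes the
#' speckle-induced brightness variation along vessels so that the
#' image-wide structureness normalization of the tubularity filter does
#' not suppress dim vessel stretches; disable with
#' \code{config$log_compress = FALSE}.
#'
#' @param ensemble an \linkS4class{IQEnsemble}.
#' @param config named list; recognized keys \code{rank_low},
#'   \code{rank_high}, \code{scales_px}, \code{tophat_radius_px},
#'   \code{log_compress} (see \code{\link{defaultRunConfig}} for defaults).
#' @return An \linkS4class{HDMIImage}.
#' @export
runHDMI <- function(ensemble, config = list()) {
  rankLow <- config$rank_low %||% 2L
  full <- min(prod(dim(iqData(ensemble))[1:2]), nFrames(ensemble))
  rankHigh <- config$rank_high %||% max(rankLow + 1L, floor(full * 0.9))
  scales <- config$scales_px %||% c(1, 1.5, 2, 3, 4)
  tophat <- config$tophat_radius_px %||% 8
  logCompress <- config$log_compress %||% TRUE
  flt <- svdClutterFilter(ensemble, rankLow, rankHigh)
  pd <- powerDoppler(flt)
  pd@provenance <- c(list(list(step = "svd_clutter_filter",
                               rank_low = rankLow, rank_high = rankHigh)),
                     pd@provenance)
  if (logCompress) {
    # display-domain dB compression with dynamic-range clipping: equalizes
    # speckle brightness along vessels without amplifying the (much
    # dimmer) noise floor, which is clipped to zero
    dr <- config$dynamic_range_db %||% 25
    ref <- max(pd@intensity)
    if (is.finite(ref) && ref > 0) {
      db <- 10 * log10(pmax(pd@intensity / ref, 10^(-dr / 10 - 2)))
      pd@intensity <- pmax(db + dr, 0) / dr
      pd@provenance <- c(pd@provenance,
                         list(list(step = "log_compression",
                                   dynamic_range_db = dr)))
    }
  }
  enhanceVessels(pd, scalesPx = scales, tophatRadiusPx = tophat)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
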