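#' Rasterize a vessel tree onto an isotropic pixel grid
#'
#' Lumen occupancy is the union of stadium-shaped dilations of the segment
#' centerlines by half their diameter: a pixel is occupied when its center
#' lies within \code{diameter/2} of a densely resampled centerline point.
#' Each occupied pixel also receives the axial (depth-direction) velocity
#' component \code{flow * cos(angle to depth axis)} of the local centerline
#' tangent; where vessels overlap the first-rasterized segment wins.
#'
#' @param tree a \linkS4class{VesselTree}.
#' @param pixelPitchUm isotropic pixel pitch, micrometres per pixel.
#' @param gridShape integer length-2 (rows = depth, cols = lateral); default
#'   covers the tree's field of view.
#' @return A \linkS4class{RasterMap}.
#' @examples
#' tr <- generateVesselTree(seed = 2, nBifurcations = 2)
#' rm <- rasterizeTree(tr, pixelPitchUm = 50)
#' mean(occupancy(rm))
#' @export
rasterizeTree <- function(tree, pixelPitchUm = 50, gridShape = NULL) {
  if (pixelPitchUm <= 0) stop("pixelPitchUm must be positive")
  pitchMm <- pixelPitchUm / 1000
  if (is.null(gridShape))
    gridShape <- c(ceiling(tree@fieldSize[2] / pitchMm),
                   ceiling(tree@fieldSize[1] / pitchMm))
  nr <- gridShape[1]; nc <- gridShape[2]
  occ <- matrix(0L, nr, nc)
  vel <- matrix(0, nr, nc)

  for (seg in tree@segments) {
    rUm <- seg$diameter_um / 2
    rPx <- rUm / pixelPitchUm
    # bounding-box check: the dilated segment must fit on the grid
    bb <- rbind(apply(seg$points, 2, min) - rUm / 1000,
                apply(seg$points, 2, max) + rUm / 1000)
    if (bb[1, 1] < 0 || bb[1, 2] < 0 ||
        bb[2, 1] > nc * pitchMm || bb[2, 2] > nr * pitchMm)
      stop("tree (with dilation) falls outside the raster grid")

    pts <- resamplePolyline(seg$points, pitchMm / 3)
    if (nrow(pts) < 2) next
    tang <- rbind(diff(pts), diff(pts)[nrow(pts) - 1L, , drop = FALSE])
    tang <- tang / pmax(sqrt(rowSums(tang^2)), 1e-12)
    vAx <- seg$flow_mm_s * tang[, 2]          # z (depth) component, signed

    # continuous pixel coordinates: pixel i covers (i-1, i], center i - 0.5
    pr <- pts[, 2] / pitchMm                  # row coordinate (depth)
    pc <- pts[, 1] / pitchMm                  # col coordinate (lateral)
    R <- ceiling(rPx) + 1L
    off <- as.matrix(expand.grid(dr = -R:R, dc = -R:R))
    for (i in seq_len(nrow(pts))) {
      rows <- round(pr[i] + 0.5) + off[, 1]
      cols <- round(pc[i] + 0.5) + off[, 2]
      ok <- rows >= 1L & rows <= nr & cols >= 1L & cols <= nc
      if (!any(ok)) next
      rows <- rows[ok]; cols <- cols[ok]
      d2 <- ((rows - 0.5) - pr[i])^2 + ((cols - 0.5) - pc[i])^2
      inside <- d2 <= rPx^2
      if (!any(inside)) next
      idx <- cbind(rows[inside], cols[inside])
      fresh <- occ[idx] == 0L
      occ[idx] <- 1L
      if (any(fresh)) vel[idx[fresh, , drop = FALSE]] <- vAx[i]
    }
  }
  new("RasterMap", occupancy = occ, axialVelocity = vel,
      pixelPitch = pixelPitchUm)
}
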