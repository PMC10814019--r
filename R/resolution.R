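#' Minimum detectable vessel diameter of the reconstruction chain
#'
#' Simulates straight single-vessel phantoms (diagonal, so the flow has an
#' axial Doppler component) over a range of diameters at the ultrafast
#' acquisition parameters, runs the full chain — rank-1 tissue-clutter
#' removal by SVD, power Doppler, vessel enhancement, binarization,
#' skeletonization — and declares a diameter detected when the single
#' largest skeleton segment covers at least \code{coverageMin} of the true
#' centerline length.
#'
#' @param diametersUm vessel diameters to scan, micrometres.
#' @param pitchUm pixel pitch, micrometres.
#' @param frameRate,centerFrequency,nFrames,soundSpeed acquisition
#'   parameters (defaults: 1000 Hz, 16.5 MHz, 1000 frames, 1540 m/s).
#' @param clutterToBloodDb rank-1 tissue clutter level, dB relative to
#'   blood power.
#' @param snrDb blood-to-noise ratio, dB.
#' @param seed integer RNG seed.
#' @param coverageMin centerline coverage fraction required for detection.
#' @param reconConfig overrides for \code{\link{runHDMI}}; the default
#'   removes one (tissue) singular component.
#' @return List with \code{table} (diameter, coverage, nSegments, detected)
#'   and \code{minDetectableUm} (NA if none detected).
#' @export
resolutionScan <- function(diametersUm = c(400, 300, 200, 150, 100),
                           pitchUm = 50, frameRate = 1000,
                           centerFrequency = 16.5, nFrames = 1000L,
                           soundSpeed = 1540, clutterToBloodDb = 30,
                           snrDb = 20, seed = 1L, coverageMin = 0.8,
                           reconConfig = list(rank_low = 1L,
                                              tophat_radius_px = 6)) {
  pitchMm <- pitchUm / 1000
  nr <- 64L; nc <- 48L                      # 3.2 x 2.4 mm field
  p0 <- c(x = 0.6, z = 0.5)
  p1 <- c(x = 1.8, z = 2.7)                 # diagonal: axial flow component
  L <- sqrt(sum((p1 - p0)^2))
  u <- (p1 - p0) / L
  seeds <- deriveSeeds(seed, length(diametersUm))

  rows <- lapply(seq_along(diametersUm), function(i) {
    d <- diametersUm[i]
    pts <- cbind(x = seq(p0["x"], p1["x"], length.out = 64L),
                 z = seq(p0["z"], p1["z"], length.out = 64L))
    tree <- new("VesselTree",
                segments = list(list(points = pts, diameter_um = d,
                                     flow_mm_s = 10, heading = atan2(u[1], u[2]))),
                parents = NA_integer_, bifurcations = list(),
                fieldSize = c(nc, nr) * pitchMm)
    raster <- rasterizeTree(tree, pitchUm, c(nr, nc))
    iq <- simulateIQ(raster, frameRate = frameRate,
                     centerFrequency = centerFrequency, nFrames = nFrames,
                     clutterToBloodDb = clutterToBloodDb, snrDb = snrDb,
                     psfSigmaPx = 1, seed = seeds[i],
                     soundSpeed = soundSpeed)
    img <- runHDMI(iq, reconConfig)
    mask <- binarizeVessels(img)
    skel <- skeletonizeVessels(mask)
    cov <- 0
    if (nSegments(skel)) {
      # largest connected skeleton component (segments joined at nodes)
      segs <- skeletonSegments(skel)
      lens <- vapply(segs, function(s) polylineLength(s$path), numeric(1))
      comp <- .skeletonComponents(skel)
      compLen <- tapply(lens, comp, sum)
      mainComp <- as.integer(names(compLen)[which.max(compLen)])
      main <- do.call(rbind, lapply(segs[comp == mainComp],
                                    function(s) s$path))
      # pixel centers in mm: (index - 0.5) * pitch
      pz <- (main[, 1] - 0.5) * pitchMm
      px <- (main[, 2] - 0.5) * pitchMm
      dx <- px - p0["x"]; dz <- pz - p0["z"]
      proj <- dx * u["x"] + dz * u["z"]
      perp <- abs(dx * u["z"] - dz * u["x"])
      near <- perp <= max(2 * pitchMm, d / 1000)
      if (sum(near) >= 2L)
        cov <- (max(proj[near]) - min(proj[near])) / L
    }
    data.frame(diameter_um = d, coverage = cov,
               n_segments = nSegments(skel),
               detected = cov >= coverageMin)
  })
  tab <- do.call(rbind, rows)
  det <- tab$diameter_um[tab$detected]
  list(table = tab,
       minDetectableUm = if (length(det)) min(det) else NA_real_)
}

# component membership of skeleton segments (segments joined at shared nodes)
.skeletonComponents <- function(skel) {
  segs <- skeletonSegments(skel)
  ns <- length(segs)
  if (!ns) return(integer())
  nodeOf <- lapply(segs, function(s) c(s$node_from, s$node_to))
  g <- igraph::make_empty_graph(ns, directed = FALSE)
  for (i in seq_len(ns - 1L)) for (j in (i + 1L):ns) {
    shared <- intersect(nodeOf[[i]][!is.na(nodeOf[[i]])],
                        nodeOf[[j]][!is.na(nodeOf[[j]])])
    if (length(shared)) g <- igraph::add_edges(g, c(i, j))
  }
  components(g)$membership
}
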