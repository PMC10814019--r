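#' Simulate an ultrafast Doppler IQ ensemble over a rasterized vessel map
#'
#' Post-beamformed IQ is modeled as tissue + blood + noise, each convolved
#' with a Gaussian point-spread function:
#' \itemize{
#'   \item \emph{tissue clutter}: one spatially smooth complex random field
#'     modulated by a slow temporal phase drift (a rank-1 Casorati
#'     component), with mean power set by \code{clutterToBloodDb} relative
#'     to the blood power inside the lumens;
#'   \item \emph{blood}: Rayleigh-amplitude speckle confined to the lumen
#'     occupancy, each pixel rotating at its Doppler frequency
#'     \eqn{f_D = 2 v_{axial} f_c / c};
#'   \item \emph{noise}: circular complex white noise at \code{snrDb} below
#'     the blood power.
#' }
#' If any lumen pixel exceeds the Nyquist limit \code{frameRate/2} a
#' warning reports aliasing; the ensemble is still produced.
#'
#' @param raster a \linkS4class{RasterMap}.
#' @param frameRate slow-time frame rate, Hz.
#' @param centerFrequency transmit center frequency, MHz.
#' @param nFrames number of slow-time frames (>= 2).
#' @param clutterToBloodDb tissue-to-blood mean power ratio, dB
#'   (\code{-Inf} disables clutter).
#' @param snrDb blood-to-noise mean power ratio, dB (\code{Inf} disables
#'   noise).
#' @param psfSigmaPx Gaussian point-spread standard deviation, pixels.
#' @param seed integer RNG seed; fixed seeds reproduce the ensemble exactly.
#' @param soundSpeed speed of sound, m/s.
#' @param clutterDriftHz temporal frequency of the tissue phase drift, Hz.
#' @return An \linkS4class{IQEnsemble}.
#' @examples
#' tr <- generateVesselTree(seed = 3, nBifurcations = 1)
#' rm <- rasterizeTree(tr, 50)
#' iq <- simulateIQ(rm, frameRate = 1000, centerFrequency = 16.5,
#'                  nFrames = 16, clutterToBloodDb = 20, snrDb = 20,
#'                  psfSigmaPx = 1, seed = 11)
#' @export
simulateIQ <- function(raster, frameRate = 1000, centerFrequency = 16.5,
                       nFrames = 1000, clutterToBloodDb = 30, snrDb = 20,
                       psfSigmaPx = 1, seed = 1L, soundSpeed = 1540,
                       clutterDriftHz = 2) {
  if (nFrames < 2) stop("nFrames must be >= 2")
  if (frameRate <= 0) stop("frameRate must be positive")
  occ <- occupancy(raster) != 0
  nr <- nrow(occ); nc <- ncol(occ)

  # Doppler shift per pixel (Hz): f_D = 2 v f_c / c, v in mm/s -> m/s
  fD <- 2 * (axialVelocity(raster) / 1000) * (centerFrequency * 1e6) /
    soundSpeed
  if (any(abs(fD[occ]) > frameRate / 2))
    warning("Doppler aliasing: |f_D| exceeds frameRate/2 for some lumen pixels")

  withSeed(seed, {
    bloodPower <- 2  # E[A^2] for Rayleigh(sigma = 1) speckle amplitudes
    amp <- matrix(0, nr, nc)
    amp[occ] <- sqrt(-2 * log(runif(sum(occ))))  # Rayleigh(1)
    phi0 <- matrix(runif(nr * nc, 0, 2 * pi), nr, nc)

    # rank-1 tissue: smooth spatial pattern x slow unit-modulus drift
    useClutter <- is.finite(clutterToBloodDb)
    if (useClutter) {
      g <- complex(real = rnorm(nr * nc), imaginary = rnorm(nr * nc))
      tis <- matrix(g, nr, nc)
      tis <- complex(real = gaussSmooth(Re(tis), 8),
                     imaginary = gaussSmooth(Im(tis), 8))
      tis <- tis / sqrt(mean(Mod(tis)^2)) *
        sqrt(bloodPower * 10^(clutterToBloodDb / 10))
      drift0 <- runif(1, 0, 2 * pi)
    }

    useNoise <- is.finite(snrDb)
    if (useNoise)
      noiseSd <- sqrt(bloodPower * 10^(-snrDb / 10) / 2)

    tt <- (seq_len(nFrames) - 1L) / frameRate
    arr <- array(complex(real = 0, imaginary = 0), dim = c(nr, nc, nFrames))
    for (k in seq_len(nFrames)) {
      fr <- amp * exp(1i * (phi0 + 2 * pi * fD * tt[k]))
      fr[!occ] <- 0
      if (useClutter)
        fr <- fr + tis * exp(1i * (drift0 + 2 * pi * clutterDriftHz * tt[k]))
      if (useNoise)
        fr <- fr + complex(real = rnorm(nr * nc, sd = noiseSd),
                           imaginary = rnorm(nr * nc, sd = noiseSd))
      arr[, , k] <- fr
    }
    arr <- blurFrames(arr, psfSigmaPx)
    new("IQEnsemble", data = arr, frameRate = frameRate,
        centerFrequency = centerFrequency, soundSpeed = soundSpeed,
        pixelPitch = pixelPitch(raster))
  })
}
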