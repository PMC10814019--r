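# constructed rank-1 tissue + confined blood phantom (no PSF, no noise)
tissueBloodPhantom <- function(nr = 24L, nc = 20L, nt = 32L, tissueAmp = 100) {
  set.seed(42)
  g <- matrix(complex(real = rnorm(nr * nc), imaginary = rnorm(nr * nc)),
              nr, nc)
  tis <- tissueAmp * g / sqrt(mean(Mod(g)^2))
  drift <- exp(1i * 2 * pi * 2 * (0:(nt - 1)) / 1000)
  occ <- matrix(0L, nr, nc); occ[10:14, 8:12] <- 1L
  blood <- matrix(0, nr, nc)
  blood[occ == 1] <- sqrt(-2 * log(runif(sum(occ))))
  phase <- exp(1i * 2 * pi * 200 * (0:(nt - 1)) / 1000)
  arr <- array(0i, dim = c(nr, nc, nt))
  for (t in seq_len(nt))
    arr[, , t] <- tis * drift[t] + blood * phase[t]
  list(iq = new("IQEnsemble", data = arr, frameRate = 1000,
                centerFrequency = 16.5, soundSpeed = 1540, pixelPitch = 50),
       occ = occ, tissueEnergy = sum(Mod(tis)^2) * nt)
}

test_that("the identity-rank filter reproduces the ensemble", {
  ph <- tissueBloodPhantom()
  d <- dim(iqData(ph$iq))
  out <- svdClutterFilter(ph$iq, rankLow = 0, rankHigh = min(d[1] * d[2], d[3]))
  expect_equal(iqData(out), iqData(ph$iq), tolerance = 1e-10)
})

test_that("rank-1 tissue is removed almost completely at rankLow = 1", {
  ph <- tissueBloodPhantom()
  out <- svdClutterFilter(ph$iq, rankLow = 1)
  resid <- sum(Mod(iqData(out)[ph$occ == 0])^2)
  expect_lt(resid / ph$tissueEnergy, 1e-6)
})

test_that("retained energy obeys the Parseval identity", {
  ph <- tissueBloodPhantom()
  d <- dim(iqData(ph$iq))
  X <- matrix(iqData(ph$iq), d[1] * d[2], d[3])
  sv <- svd(X)$d
  out <- svdClutterFilter(ph$iq, rankLow = 2, rankHigh = 10)
  expect_equal(sum(Mod(iqData(out))^2), sum(sv[3:10]^2), tolerance = 1e-8)
})

test_that("the clutter filter is linear and monotone in tissue rejection", {
  ph <- tissueBloodPhantom()
  f1 <- svdClutterFilter(ph$iq, rankLow = 1)
  scaled <- new("IQEnsemble", data = iqData(ph$iq) * (2 + 0i),
                frameRate = 1000, centerFrequency = 16.5, soundSpeed = 1540,
                pixelPitch = 50)
  f2 <- svdClutterFilter(scaled, rankLow = 1)
  expect_equal(iqData(f2), iqData(f1) * (2 + 0i), tolerance = 1e-8)
  resid <- vapply(0:3, function(rl) {
    out <- svdClutterFilter(ph$iq, rankLow = rl)
    sum(Mod(iqData(out)[ph$occ == 0])^2)
  }, numeric(1))
  expect_true(all(diff(resid) <= 1e-8))
})

test_that("rank bounds are validated", {
  ph <- tissueBloodPhantom()
  expect_error(svdClutterFilter(ph$iq, rankLow = -1), "rank")
  expect_error(svdClutterFilter(ph$iq, rankLow = 5, rankHigh = 5), "rank")
  expect_error(svdClutterFilter(ph$iq, rankLow = 0, rankHigh = 1e6), "rank")
})

test_that("power Doppler reduces to known closed forms", {
  z <- array(0i, dim = c(4, 4, 8))
  expect_true(all(intensity(powerDoppler(
    new("IQEnsemble", data = z, frameRate = 1000, centerFrequency = 16.5,
        soundSpeed = 1540, pixelPitch = 50))) == 0))
  ones <- array(complex(modulus = 1, argument = runif(4 * 4 * 8)),
                dim = c(4, 4, 8))
  expect_equal(intensity(powerDoppler(
    new("IQEnsemble", data = ones, frameRate = 1000, centerFrequency = 16.5,
        soundSpeed = 1540, pixelPitch = 50))), matrix(1, 4, 4))
  # white noise: mean ~ variance with relative SD ~ 1/sqrt(n)
  set.seed(3)
  n <- 1000L
  noise <- array(complex(real = rnorm(16 * 16 * n, sd = sqrt(0.5)),
                         imaginary = rnorm(16 * 16 * n, sd = sqrt(0.5))),
                 dim = c(16, 16, n))
  img <- intensity(powerDoppler(
    new("IQEnsemble", data = noise, frameRate = 1000, centerFrequency = 16.5,
        soundSpeed = 1540, pixelPitch = 50)))
  expect_equal(mean(img), 1, tolerance = 0.02)
  expect_equal(sd(img) / mean(img) * sqrt(n), 1, tolerance = 0.2)
})

test_that("vesselness vanishes on constant images and ignores offsets", {
  const <- new("HDMIImage", intensity = matrix(3, 32, 32), pixelPitch = 50,
               provenance = list())
  expect_true(all(intensity(enhanceVessels(const, tophatRadiusPx = 0)) == 0))
  set.seed(4)
  img <- matrix(rexp(32 * 32), 32, 32)
  a <- enhanceVessels(new("HDMIImage", intensity = img, pixelPitch = 50,
                          provenance = list()), tophatRadiusPx = 0)
  b <- enhanceVessels(new("HDMIImage", intensity = img + 7, pixelPitch = 50,
                          provenance = list()), tophatRadiusPx = 0)
  expect_equal(intensity(a), intensity(b), tolerance = 1e-10)
})

test_that("normalized ridge structureness selects the matching scale", {
  # gamma = 2 scale normalization peaks at sqrt(2) * sigma_true for a
  # Gaussian-profile ridge
  n <- 64L
  for (sigTrue in c(1.5, 2.5)) {
    img <- matrix(rep(exp(-((1:n) - 32)^2 / (2 * sigTrue^2)), n), n, n)
    scales <- c(1, 1.5, 2, 3, 4, 5, 6)
    S <- vapply(scales, function(sg) {
      H <- choromvq:::.hessianAtScale(img, sg)
      max(sqrt((H$rr + H$cc)^2))  # structureness at the ridge dominates
    }, numeric(1))
    best <- scales[which.max(S)]
    expected <- sqrt(2) * sigTrue
    steps <- abs(which.max(S) - which.min(abs(scales - expected)))
    expect_lte(steps, 1)
  }
})

test_that("vesselness localizes on vessels across the diameter range", {
  for (d in c(150, 450, 900)) {
    rm <- singleVesselRaster(diameterUm = d, vertical = TRUE,
                             nr = 64L, nc = 48L)
    iq <- simulateIQ(rm, nFrames = 48, clutterToBloodDb = 30, snrDb = 20,
                     psfSigmaPx = 1, seed = 100 + d)
    img <- runHDMI(iq, list(rank_low = 1L, tophat_radius_px = 6))
    ctr <- choromvq:::thinMask(occupancy(rm))
    medC <- median(intensity(img)[ctr == 1])
    medB <- median(intensity(img)[occupancy(rm) == 0])
    expect_gte(medC, 10 * medB)
  }
})

test_that("the full chain concentrates response inside the PSF-dilated lumen", {
  tr <- generateVesselTree(seed = 31, nBifurcations = 2,
                           tortuosityAmplitude = 0.1, rootLengthMm = 1.2,
                           lengthDecay = 0.72, rootDiameterUm = 500,
                           fieldSizeMm = c(6.4, 6.4))
  rm <- rasterizeTree(tr, 50, c(128L, 128L))
  iq <- simulateIQ(rm, nFrames = 32, clutterToBloodDb = -Inf, snrDb = Inf,
                   psfSigmaPx = 1, seed = 32)
  img <- runHDMI(iq, list(rank_low = 0L, rank_high = 32L,
                          tophat_radius_px = 6))
  dil <- EBImage::imageData(EBImage::dilate(EBImage::Image(occupancy(rm)),
                                            EBImage::makeBrush(15, "disc")))
  v <- intensity(img)
  pos <- v[v > 0]
  top <- v > quantile(pos, 0.9)   # brightest decile of the response
  expect_gte(mean(dil[top] == 1), 0.95)
  # determinism of the whole chain
  img2 <- runHDMI(simulateIQ(rm, nFrames = 32, clutterToBloodDb = -Inf,
                             snrDb = Inf, psfSigmaPx = 1, seed = 32),
                  list(rank_low = 0L, rank_high = 32L, tophat_radius_px = 6))
  expect_identical(intensity(img), intensity(img2))
})

test_that("a 150 um vessel survives reconstruction and binarization", {
  rm <- singleVesselRaster(diameterUm = 150, vertical = TRUE,
                           nr = 64L, nc = 48L)
  iq <- simulateIQ(rm, frameRate = 1000, centerFrequency = 16.5,
                   nFrames = 300, clutterToBloodDb = 30, snrDb = 20,
                   psfSigmaPx = 1, seed = 33)
  img <- runHDMI(iq, list(rank_low = 1L, tophat_radius_px = 6))
  mask <- binarizeVessels(img)
  m <- vesselMask(mask)
  # the largest connected detection covers most of the true lumen
  lab <- choromvq:::label8(m)
  main <- lab == which.max(tabulate(lab[lab > 0]))
  expect_gte(sum(main & occupancy(rm) == 1) / sum(occupancy(rm)), 0.5)
})
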