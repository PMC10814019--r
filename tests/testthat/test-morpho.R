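test_that("binarization separates a two-level image exactly", {
  band <- drawBand(64, 64, 8, cols = 1:64)
  mask <- binarizeVessels(band * 1.0, pixelPitchUm = 50)
  expect_identical(vesselMask(mask), band)
  expect_equal(vesselDensity(mask), 8 / 64)
})

test_that("a constant ROI yields an empty mask, not an error", {
  mask <- binarizeVessels(matrix(5, 32, 32), pixelPitchUm = 50)
  expect_true(all(vesselMask(mask) == 0))
  expect_error(binarizeVessels(matrix(1, 4, 4), roi = matrix(0, 4, 4)),
               "ROI")
})

test_that("binarization recovers a noisy band with high Dice", {
  set.seed(7)
  band <- drawBand(64, 64, 8)
  noisy <- band + matrix(rnorm(64 * 64, sd = sqrt(mean(band^2) / 100)),
                         64, 64)  # 20 dB SNR
  m <- vesselMask(binarizeVessels(noisy, pixelPitchUm = 50))
  dice <- 2 * sum(m == 1 & band == 1) / (sum(m) + sum(band))
  expect_gte(dice, 0.9)
})

test_that("skeleton topology matches drawn fixtures", {
  skB <- skeletonizeVessels(drawBand(), pixelPitchUm = 50)
  expect_identical(nSegments(skB), 1L)
  expect_identical(nBranchPoints(skB), 0L)
  skY <- skeletonizeVessels(drawY(), pixelPitchUm = 50)
  expect_identical(nSegments(skY), 3L)
  expect_identical(nBranchPoints(skY), 1L)
  # crossing bands: one clustered junction, four arms
  skX <- skeletonizeVessels(drawX(), pixelPitchUm = 50)
  expect_identical(nSegments(skX), 4L)
  expect_identical(nBranchPoints(skX), 1L)
  # empty mask: empty skeleton, no error
  sk0 <- skeletonizeVessels(matrix(0L, 16, 16), pixelPitchUm = 50)
  expect_identical(nSegments(sk0), 0L)
  expect_identical(nBranchPoints(sk0), 0L)
})

test_that("vessel density is the mask fraction of the ROI", {
  full <- new("BinaryVesselMask", mask = matrix(1L, 8, 8),
              roi = matrix(1L, 8, 8), pixelPitch = 50)
  expect_equal(vesselDensity(full), 1)
  none <- new("BinaryVesselMask", mask = matrix(0L, 8, 8),
              roi = matrix(1L, 8, 8), pixelPitch = 50)
  expect_equal(vesselDensity(none), 0)
})

test_that("tortuosity is exact on straight segments and on half circles", {
  skB <- skeletonizeVessels(drawBand(), pixelPitchUm = 50)
  expect_identical(tortuosity(skB)$taumean, 1)
  for (r in c(40L, 60L)) {
    skC <- skeletonizeVessels(drawHalfCircle(r, 5), pixelPitchUm = 50)
    expect_identical(nSegments(skC), 1L)
    expect_equal(tortuosity(skC)$taumax, pi / 2, tolerance = 0.02)
  }
})

test_that("tortuosity aggregates respect max >= mean >= 1", {
  for (s in 1:5) {
    tr <- generateVesselTree(seed = s, nBifurcations = 3,
                             tortuosityAmplitude = 0.15, rootLengthMm = 1.5,
                             fieldSizeMm = c(6.4, 6.4))
    sk <- skeletonizeVessels(occupancy(rasterizeTree(tr, 50)),
                             pixelPitchUm = 50)
    tau <- suppressMessages(tortuosity(sk))
    expect_gte(tau$taumax, tau$taumean)
    expect_gte(tau$taumean, 1)
  }
})

test_that("Murray's deviation follows its closed forms at a junction", {
  skGood <- threeArmSkeleton(c(2^(1 / 3), 1, 1))
  md <- murrayDeviation(skGood)
  expect_true(md$measurable)
  expect_equal(md$MDmean, 0, tolerance = 1e-12)
  skBad <- threeArmSkeleton(c(1, 1, 1))
  expect_equal(murrayDeviation(skBad)$MDmean, 1, tolerance = 1e-12)
  # no branch point -> structurally unmeasurable
  skB <- skeletonizeVessels(drawBand(), pixelPitchUm = 50)
  expect_false(murrayDeviation(skB)$measurable)
  expect_true(is.na(murrayDeviation(skB)$MDmean))
})

test_that("bifurcation angles recover drawn geometry", {
  skY <- skeletonizeVessels(drawY(), pixelPitchUm = 50)
  ba <- bifurcationAngle(skY)
  expect_true(ba$measurable)
  expect_equal(ba$BAmean, 90, tolerance = 5 / 90)
  # T junction: collinear daughter arms approach 180 degrees
  skT <- threeArmSkeleton(c(2, 1, 1))
  skT@segments[[2]]$path <- cbind(rep(20, 10), 20 - (1:10))
  skT@segments[[3]]$path <- cbind(rep(20, 10), 20 + (1:10))
  baT <- bifurcationAngle(skT)
  expect_gte(baT$BAmax, 170)
  skB <- skeletonizeVessels(drawBand(), pixelPitchUm = 50)
  expect_false(bifurcationAngle(skB)$measurable)
})

test_that("box counting recovers analytic dimensions", {
  line <- matrix(0L, 520, 520); line[260, 1:512] <- 1L
  expect_equal(fractalDimension(line), 1, tolerance = 0.05)
  block <- matrix(0L, 256, 256); block[1:128, 1:128] <- 1L
  expect_equal(fractalDimension(block), 2, tolerance = 0.05)
  vic <- vicsekFractal(5)
  expect_equal(fractalDimension(vic, boxSizes = 3^(0:4)), log(5) / log(3),
               tolerance = 0.1)
  expect_warning(fd <- fractalDimension(matrix(0L, 8, 8)), "empty")
  expect_true(is.na(fd))
  expect_error(fractalDimension(line, boxSizes = c(1, 2, 4)), "4 box sizes")
})

test_that("biomarker records handle empty masks and keep their invariants", {
  rec <- computeBiomarkers(matrix(0, 32, 32), pixelPitchUm = 50)
  expect_equal(rec$VD, 0)
  expect_identical(rec$NV, 0L)
  expect_identical(rec$NB, 0L)
  expect_identical(rec$measurable_MD_BA, 0L)
  expect_true(is.na(rec$MDmean) && is.na(rec$BAmax))
})

test_that("record invariants hold across random phantoms", {
  for (s in 1:12) {
    nb <- s %% 4
    tr <- generateVesselTree(seed = s, nBifurcations = nb,
                             tortuosityAmplitude = 0.05 * (s %% 3),
                             rootLengthMm = 1.3, lengthDecay = 0.72,
                             rootDiameterUm = 300 + 40 * (s %% 5),
                             fieldSizeMm = c(6.4, 6.4))
    occ <- occupancy(rasterizeTree(tr, 50))
    rec <- suppressMessages(computeBiomarkers(occ * 1.0, pixelPitchUm = 50))
    expect_gte(rec$Dmax, rec$Dmean)
    if (!is.na(rec$taumax)) {
      expect_gte(rec$taumax, rec$taumean)
      expect_gte(rec$taumean, 1)
    }
    expect_identical(rec$measurable_MD_BA == 1L, rec$NB > 0)
    expect_identical(is.na(rec$MDmean), rec$NB == 0)
  }
})

test_that("noise-free rasterized trees are recovered exactly", {
  for (s in 1:3) {
    tr <- generateVesselTree(seed = s, nBifurcations = 4,
                             rootDiameterUm = 600)
    sk <- skeletonizeVessels(occupancy(rasterizeTree(tr, 50)),
                             pixelPitchUm = 50)
    expect_identical(nBranchPoints(sk), 4L)
    segD <- vapply(skeletonSegments(sk), function(x) mean(x$diam_um),
                   numeric(1))
    # widest measured segment within one pixel pitch of the root diameter
    expect_lt(abs(max(segD) - 600), 50)
  }
})

test_that("counts are rotation invariant and tortuosity nearly so", {
  tr <- generateVesselTree(seed = 6, nBifurcations = 3,
                           tortuosityAmplitude = 0.12, rootLengthMm = 1.4,
                           fieldSizeMm = c(6.4, 6.4))
  occ <- occupancy(rasterizeTree(tr, 50))
  rot90 <- function(m) t(m)[, nrow(m):1]
  sk1 <- skeletonizeVessels(occ, pixelPitchUm = 50)
  sk2 <- skeletonizeVessels(rot90(occ), pixelPitchUm = 50)
  expect_identical(nSegments(sk1), nSegments(sk2))
  expect_identical(nBranchPoints(sk1), nBranchPoints(sk2))
  t1 <- suppressMessages(tortuosity(sk1))$taumean
  t2 <- suppressMessages(tortuosity(sk2))$taumean
  expect_equal(t1, t2, tolerance = 0.05)
})

test_that("micron-scale measurements are pitch equivariant", {
  tr <- generateVesselTree(seed = 8, nBifurcations = 2,
                           tortuosityAmplitude = 0.1, rootLengthMm = 1.4,
                           rootDiameterUm = 500, fieldSizeMm = c(6.4, 6.4))
  recs <- lapply(c(50, 25), function(pitch) {
    occ <- occupancy(rasterizeTree(tr, pitch))
    suppressMessages(computeBiomarkers(occ * 1.0, pixelPitchUm = pitch))
  })
  expect_equal(recs[[1]]$Dmax, recs[[2]]$Dmax, tolerance = 0.05)
  expect_equal(recs[[1]]$Dmean, recs[[2]]$Dmean, tolerance = 0.08)
  expect_equal(recs[[1]]$taumean, recs[[2]]$taumean, tolerance = 0.05)
})

test_that("melanoma-like phantoms dominate nevus-like ones on six biomarkers", {
  mel <- generateVesselTree(seed = 13, nBifurcations = 8,
                            tortuosityAmplitude = 0.25, rootDiameterUm = 900,
                            fieldSizeMm = c(12.8, 12.8))
  nev <- generateVesselTree(seed = 14, nBifurcations = 1,
                            tortuosityAmplitude = 0.05, rootDiameterUm = 600,
                            fieldSizeMm = c(12.8, 12.8))
  rMel <- suppressMessages(computeBiomarkers(
    occupancy(rasterizeTree(mel, 50)) * 1.0, pixelPitchUm = 50))
  rNev <- suppressMessages(computeBiomarkers(
    occupancy(rasterizeTree(nev, 50)) * 1.0, pixelPitchUm = 50))
  for (nm in c("VD", "NV", "NB", "Dmax", "taumax", "mvFD"))
    expect_gt(rMel[[nm]], rNev[[nm]])
})
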