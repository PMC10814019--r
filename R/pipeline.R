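#' Default end-to-end run configuration
#'
#' Acquisition follows the study's ultrafast protocol: 1000 slow-time
#' frames at a 1000 Hz effective frame rate, 16.5 MHz center frequency,
#' 1540 m/s sound speed, on a 256 x 256 px grid at 50 um/pixel (12.8 mm
#' field).  Phantom arms mirror the study design: 21 malignant-like trees
#' (many bifurcations, strong tortuosity, wide root) versus 15 nevus-like
#' trees (few bifurcations, nearly straight, narrower), with branch-point
#' counts drawn from zero-inflated Poissons matched to the observed group
#' means and no-branch probabilities, and thickness from log-normals
#' matched to the observed moments.
#'
#' \code{demoRunConfig} is a reduced-size variant (128 x 128 px, 64
#' frames, shorter trees) for examples, vignettes and smoke tests.
#'
#' @return Nested named list of configuration blocks.
#' @export
defaultRunConfig <- function() {
  list(
    seed = 7L,
    acquisition = list(frame_rate_hz = 1000, fc_mhz = 16.5,
                       n_frames = 1000L, c_mps = 1540, pitch_um = 50,
                       psf_sigma_px = 1, clutter_to_blood_db = 30,
                       snr_db = 20),
    grid = list(n_px = 256L),
    recon = list(rank_low = 2L, rank_high = NULL,
                 scales_px = c(1, 1.5, 2, 3, 4), tophat_radius_px = 8),
    morpho = list(prune_px = 4, min_object_px = 4, murray_exponent = 3,
                  fd_source = "skeleton", junction_k = 5L),
    phantoms = list(
      malignant = list(n = 21L, nb_mean = 8.9, nb_p0 = 0,
                       amplitude_mm = 0.25, root_diameter_um = 900,
                       root_length_mm = 3, length_decay = 0.75,
                       thickness = c(3.81, 2.63)),
      benign = list(n = 15L, nb_mean = 3.07, nb_p0 = 7 / 15,
                    amplitude_mm = 0.06, root_diameter_um = 620,
                    root_length_mm = 3, length_decay = 0.75,
                    thickness = c(1.70, 0.40))),
    stats = list(cutoff_mm = 2.5, bootstrap_B = 2000L)
  )
}

#' @rdname defaultRunConfig
#' @export
demoRunConfig <- function() {
  cfg <- defaultRunConfig()
  cfg$acquisition$n_frames <- 64L
  cfg$grid$n_px <- 128L
  # the synthetic tissue model is exactly rank-1, so one clutter component
  # suffices; real acquisitions need more (default 2)
  cfg$recon$rank_low <- 1L
  cfg$recon$tophat_radius_px <- 6
  cfg$phantoms$malignant$root_length_mm <- 1.2
  cfg$phantoms$malignant$length_decay <- 0.72
  cfg$phantoms$malignant$root_diameter_um <- 550
  cfg$phantoms$malignant$amplitude_mm <- 0.18
  cfg$phantoms$benign$root_length_mm <- 1.2
  cfg$phantoms$benign$length_decay <- 0.72
  cfg$phantoms$benign$root_diameter_um <- 420
  cfg$phantoms$benign$amplitude_mm <- 0.05
  cfg$stats$bootstrap_B <- 400L
  cfg
}

.mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- .mergeConfig(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a YAML run configuration
#'
#' Unknown top-level or block-level keys are rejected with a field-level
#' message; recognized keys override the defaults.
#'
#' @param path YAML file.
#' @param base configuration to merge into (default
#'   \code{\link{defaultRunConfig}()}).
#' @return Merged configuration list.
#' @export
readRunConfig <- function(path, base = defaultRunConfig()) {
  usr <- read_yaml(path)
  checkKeys <- function(u, b, prefix) {
    bad <- setdiff(names(u), names(b))
    if (length(bad))
      stop("unknown config key(s): ",
           paste0(prefix, bad, collapse = ", "))
    for (nm in names(u))
      if (is.list(u[[nm]]) && is.list(b[[nm]]))
        checkKeys(u[[nm]], b[[nm]], paste0(prefix, nm, "."))
  }
  checkKeys(usr, base, "")
  .mergeConfig(base, usr)
}

.simulatePhantom <- function(groupCfg, acq, gridPx, reconCfg, morphoCfg,
                             seeds) {
  nb <- rzip(1L, max(groupCfg$nb_mean, 1e-9), groupCfg$nb_p0)
  fieldMm <- gridPx * acq$pitch_um / 1000
  tree <- generateVesselTree(seed = seeds[1], nBifurcations = nb,
                             tortuosityAmplitude = groupCfg$amplitude_mm,
                             rootDiameterUm = groupCfg$root_diameter_um,
                             rootLengthMm = groupCfg$root_length_mm,
                             lengthDecay = groupCfg$length_decay,
                             fieldSizeMm = c(fieldMm, fieldMm))
  raster <- rasterizeTree(tree, acq$pitch_um, c(gridPx, gridPx))
  iq <- simulateIQ(raster, frameRate = acq$frame_rate_hz,
                   centerFrequency = acq$fc_mhz, nFrames = acq$n_frames,
                   clutterToBloodDb = acq$clutter_to_blood_db,
                   snrDb = acq$snr_db, psfSigmaPx = acq$psf_sigma_px,
                   seed = seeds[2], soundSpeed = acq$c_mps)
  img <- runHDMI(iq, reconCfg)
  rec <- computeBiomarkers(img, config = c(morphoCfg,
    list(binarize_method = "otsu")))
  rec$true_NB <- nb
  rec
}

#' Run the full in-silico study
#'
#' For each arm, generates phantom vascular trees, simulates ultrafast IQ
#' ensembles, reconstructs microvessel images, extracts the twelve
#' biomarkers, attaches arm-specific thickness draws, and runs the full
#' group statistics.  With \code{outDir} set, writes \code{table2.csv}
#' (always-measurable comparison), \code{table3.csv} (branching
#' biomarkers), \code{table4.csv} (thickness-restricted subset),
#' \code{correlations.csv} and a provenance \code{manifest.json} (seed,
#' config hash, package version).  Fixed seeds make reruns byte-identical.
#'
#' @param config configuration list (see \code{\link{defaultRunConfig}}).
#' @param seed master seed; overrides \code{config$seed} when given.
#' @param outDir output directory, created if needed; \code{NULL} writes
#'   nothing.
#' @return List with \code{cohort} (data.frame), \code{analysis}
#'   (\linkS4class{GroupAnalysis}) and \code{manifest}.
#' @export
runEndToEnd <- function(config = demoRunConfig(), seed = NULL,
                        outDir = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  acq <- config$acquisition
  stage <- function(tag, expr) {
    tryCatch(expr, error = function(e)
      stop("[", tag, "] ", conditionMessage(e), call. = FALSE))
  }
  nTot <- config$phantoms$malignant$n + config$phantoms$benign$n
  seeds <- deriveSeeds(config$seed, 3L * nTot + 2L)
  rows <- list()
  k <- 0L
  for (grp in c("malignant", "benign")) {
    gc <- config$phantoms[[grp]]
    tp <- lnormParams(gc$thickness[1], gc$thickness[2])
    for (i in seq_len(gc$n)) {
      k <- k + 1L
      rec <- stage(paste0("phantom:", grp, ":", i),
        withSeed(seeds[3L * k], .simulatePhantom(
          gc, acq, config$grid$n_px, config$recon, config$morpho,
          seeds[c(3L * k - 2L, 3L * k - 1L)])))
      rec$id <- sprintf("%s%03d", substr(grp, 1, 1), k)
      rec$label <- grp
      rec$thickness_mm <- withSeed(seeds[3L * k] + 1L,
                                   rlnorm(1, tp["meanlog"], tp["sdlog"]))
      rows[[k]] <- rec
    }
  }
  cohort <- do.call(rbind, rows)
  cohort <- cohort[, c("id", "label", "thickness_mm", .BIOMARKERS,
                       "measurable_MD_BA", "true_NB")]
  analysis <- stage("stats",
    runGroupAnalysis(cohort, thicknessCutoffMm = config$stats$cutoff_mm,
                     B = config$stats$bootstrap_B,
                     seed = seeds[3L * nTot + 1L]))

  manifest <- list(seed = config$seed,
                   package_version = as.character(packageVersion("choromvq")),
                   n_malignant = config$phantoms$malignant$n,
                   n_benign = config$phantoms$benign$n,
                   acquisition = acq, grid = config$grid)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    cfgPath <- file.path(outDir, "config.json")
    write_json(config, cfgPath, auto_unbox = TRUE, digits = NA,
               null = "null")
    manifest$config_md5 <- unname(tools::md5sum(cfgPath))
    write.csv(analysis@comparison, file.path(outDir, "table2.csv"),
              row.names = FALSE)
    write.csv(analysis@branching, file.path(outDir, "table3.csv"),
              row.names = FALSE)
    if (!is.null(analysis@subsetComparison))
      write.csv(analysis@subsetComparison, file.path(outDir, "table4.csv"),
                row.names = FALSE)
    write.csv(as.data.frame(analysis@correlations),
              file.path(outDir, "correlations.csv"), row.names = TRUE)
    writeCohort(cohort[, setdiff(names(cohort), "true_NB")],
                file.path(outDir, "cohort.csv"))
    write_json(manifest, file.path(outDir, "manifest.json"),
               auto_unbox = TRUE, digits = NA)
  }
  list(cohort = cohort, analysis = analysis, manifest = manifest)
}
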