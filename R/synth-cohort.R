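.BIOMARKERS <- c("VD", "Dmean", "Dmax", "NV", "mvFD", "NB",
                 "taumean", "taumax", "MDmean", "MDmax", "BAmean", "BAmax")
.ALWAYS_MEASURABLE <- c("VD", "Dmean", "Dmax", "NV", "mvFD", "NB",
                        "taumean", "taumax")
.BRANCHING <- c("MDmean", "MDmax", "BAmean", "BAmax")

.groupSpec <- function(n, thickness, markers, pNB0) {
  stopifnot(is.data.frame(markers),
            all(c("name", "family", "mean", "sd") %in% names(markers)),
            setequal(markers$name, .BIOMARKERS))
  list(n = as.integer(n), thickness = thickness, markers = markers,
       pNB0 = pNB0)
}

#' Construct a cohort-generating specification
#'
#' @param nMalignant,nBenign arm sizes.
#' @param malignantMarkers,benignMarkers data.frames with columns
#'   \code{name}, \code{family} (\code{"gaussian"}, \code{"lognormal"} or
#'   \code{"zip"}), \code{mean}, \code{sd}, one row per biomarker.
#' @param malignantThickness,benignThickness length-2 (mean, SD) of tumor
#'   thickness in mm (log-normal marginal).
#' @param pNB0Malignant,pNB0Benign probability of having no branch point;
#'   the four branching biomarkers are unmeasurable exactly when NB = 0.
#' @return A \linkS4class{CohortSpec}.
#' @seealso \code{\link{defaultCohortSpec}} for the study-condition defaults.
#' @export
cohortSpec <- function(nMalignant, nBenign, malignantMarkers, benignMarkers,
                       malignantThickness, benignThickness,
                       pNB0Malignant = 0, pNB0Benign = 0) {
  new("CohortSpec",
      malignant = .groupSpec(nMalignant, malignantThickness,
                             malignantMarkers, pNB0Malignant),
      benign = .groupSpec(nBenign, benignThickness, benignMarkers,
                          pNB0Benign))
}

.markerTable <- function(means, sds, families) {
  data.frame(name = .BIOMARKERS, family = families, mean = means, sd = sds,
             stringsAsFactors = FALSE)
}

#' Study-condition cohort specification
#'
#' The default two-arm specification: 21 malignant vs 15 benign
#' participants, marginal (mean, SD) per biomarker taken from the observed
#' choroidal melanoma/nevus group summaries, log-normal marginals for the
#' right-skewed biomarkers (NV, tau-max) and thickness, a zero-inflated
#' Poisson for the branch-point count NB parameterized by its mean and
#' P(NB = 0), and a benign no-branch probability of 7/15 so that on average
#' 53\% of benign participants have measurable branching biomarkers.
#'
#' @return A \linkS4class{CohortSpec}.
#' @export
defaultCohortSpec <- function() {
  fam <- c(VD = "gaussian", Dmean = "gaussian", Dmax = "gaussian",
           NV = "lognormal", mvFD = "gaussian", NB = "zip",
           taumean = "gaussian", taumax = "lognormal",
           MDmean = "gaussian", MDmax = "gaussian",
           BAmean = "gaussian", BAmax = "gaussian")
  mal <- .markerTable(
    means = c(0.20, 459.89, 908.56, 16.57, 1.32, 8.90, 1.14, 1.91,
              0.40, 0.70, 99.53, 141.25),
    sds   = c(0.11, 174.46, 359.09, 11.84, 0.11, 8.33, 0.21, 1.81,
              0.18, 0.26, 17.72, 28.57),
    families = unname(fam))
  ben <- .markerTable(
    means = c(0.12, 381.83, 624.32, 6.73, 1.14, 3.07, 1.05, 1.18,
              0.40, 0.66, 99.74, 140.28),
    sds   = c(0.09, 176.38, 341.80, 5.74, 0.16, 3.81, 0.03, 0.21,
              0.18, 0.22, 32.92, 35.24),
    families = unname(fam))
  cohortSpec(nMalignant = 21L, nBenign = 15L,
             malignantMarkers = mal, benignMarkers = ben,
             malignantThickness = c(3.81, 2.63),
             benignThickness = c(1.70, 0.40),
             pNB0Malignant = 0, pNB0Benign = 7 / 15)
}

.drawMarker <- function(n, family, m, s) {
  switch(family,
    gaussian = rnorm(n, m, s),
    lognormal = {
      p <- lnormParams(m, s)
      rlnorm(n, p["meanlog"], p["sdlog"])
    },
    stop("unknown marginal family: ", family))
}

.drawGroup <- function(g, label, idOffset) {
  n <- g$n
  if (n == 0L) return(NULL)
  mk <- g$markers
  out <- data.frame(id = sprintf("%s%03d", substr(label, 1, 1),
                                 idOffset + seq_len(n)),
                    label = label, stringsAsFactors = FALSE)
  tp <- lnormParams(g$thickness[1], g$thickness[2])
  out$thickness_mm <- rlnorm(n, tp["meanlog"], tp["sdlog"])
  for (nm in .BIOMARKERS) {
    row <- mk[mk$name == nm, ]
    out[[nm]] <- if (row$family == "zip") {
      as.numeric(rzip(n, row$mean, g$pNB0))
    } else .drawMarker(n, row$family, row$mean, row$sd)
  }
  # NV is a count: round the log-normal draw up to at least 1 segment
  out$NV <- pmax(1, round(out$NV))
  # structural missingness: no branch point -> no branching biomarkers
  noBranch <- out$NB == 0
  for (nm in .BRANCHING) out[[nm]][noBranch] <- NA_real_
  out$measurable_MD_BA <- as.integer(!noBranch)
  out
}

#' Generate a labeled biomarker cohort from a specification
#'
#' Draws one biomarker record per participant from the per-arm marginal
#' distributions, couples the structural missingness of the branching
#' biomarkers (MD, BA mean/max) to the event NB = 0, and attaches tumor
#' thickness and the benign/malignant label.
#'
#' @param spec a \linkS4class{CohortSpec}.
#' @param seed integer RNG seed.
#' @return A data.frame with columns \code{id}, \code{label},
#'   \code{thickness_mm}, the 12 biomarkers and \code{measurable_MD_BA};
#'   unmeasurable branching cells are \code{NA}.
#' @examples
#' co <- generateCohort(defaultCohortSpec(), seed = 7)
#' table(co$label, co$measurable_MD_BA)
#' @export
generateCohort <- function(spec, seed = 1L) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  withSeed(seed, {
    mal <- .drawGroup(spec@malignant, "malignant", 0L)
    ben <- .drawGroup(spec@benign, "benign", 500L)
    out <- rbind(mal, ben)
    if (is.null(out)) {
      out <- data.frame(id = character(), label = character(),
                        thickness_mm = numeric())
      for (nm in .BIOMARKERS) out[[nm]] <- numeric()
      out$measurable_MD_BA <- integer()
    }
    rownames(out) <- NULL
    out
  })
}
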