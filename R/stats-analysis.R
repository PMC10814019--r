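.comparisonTable <- function(cohort, biomarkers, B, seed, level = 0.95) {
  mal <- cohort[cohort$label == "malignant", , drop = FALSE]
  ben <- cohort[cohort$label == "benign", , drop = FALSE]
  seeds <- deriveSeeds(seed, length(biomarkers))
  rows <- lapply(seq_along(biomarkers), function(i) {
    nm <- biomarkers[i]
    x <- mal[[nm]]; y <- ben[[nm]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    auc <- aucMW(x, y)
    ci <- aucCIBootstrap(x, y, B = B, seed = seeds[i], level = level)
    data.frame(biomarker = nm,
               malignant_mean = mean(x), malignant_sd = sd(x),
               benign_mean = mean(y), benign_sd = sd(y),
               n_malignant = length(x), n_benign = length(y),
               p_value = wilcoxonRankSum(x, y),
               AUC = auc, ci_lower = ci["lower"], ci_upper = ci["upper"],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full group comparison of a labeled biomarker cohort
#'
#' Reproduces the study's statistical layout on any cohort table:
#' \itemize{
#'   \item Wilcoxon rank-sum p, Mann-Whitney AUC and stratified percentile
#'     bootstrap 95\% CI for the eight always-measurable biomarkers
#'     (malignant as the positive class, orientation as-is);
#'   \item the 2-df Firth likelihood-ratio test of measurability and value
#'     for the four branching biomarkers with structural missingness;
#'   \item a pairwise-complete Pearson correlation matrix over all twelve;
#'   \item the Wilcoxon/AUC table restricted to tumors with thickness at or
#'     below \code{thicknessCutoffMm} (skipped with a warning if the cutoff
#'     empties a group).
#' }
#' P-values are reported unadjusted for multiple testing.
#'
#' @param cohort data.frame as produced by \code{\link{generateCohort}} or
#'   \code{\link{readCohort}} (columns \code{label}, \code{thickness_mm},
#'   the 12 biomarkers, \code{measurable_MD_BA}).
#' @param thicknessCutoffMm sensitivity-analysis cutoff, mm; \code{NULL}
#'   or \code{Inf} skips the subset analysis.
#' @param B bootstrap resamples for the AUC confidence intervals.
#' @param seed integer RNG seed for the bootstrap.
#' @return A \linkS4class{GroupAnalysis}.
#' @examples
#' co <- generateCohort(defaultCohortSpec(), seed = 7)
#' res <- runGroupAnalysis(co, B = 200, seed = 7)
#' res@comparison[, c("biomarker", "p_value", "AUC")]
#' @export
runGroupAnalysis <- function(cohort, thicknessCutoffMm = 2.5, B = 2000L,
                             seed = 1L) {
  stopifnot(all(c("label", .BIOMARKERS) %in% names(cohort)))
  if (!all(c("malignant", "benign") %in% cohort$label))
    stop("both labels must be present")
  comparison <- .comparisonTable(cohort, .ALWAYS_MEASURABLE, B, seed)

  y <- as.integer(cohort$label == "malignant")
  observed <- if ("measurable_MD_BA" %in% names(cohort))
    cohort$measurable_MD_BA else as.integer(!is.na(cohort$MDmean))
  branching <- do.call(rbind, lapply(.BRANCHING, function(nm) {
    fit <- missingnessLRT(y, cohort[[nm]], observed)
    mal <- cohort$label == "malignant"
    data.frame(biomarker = nm,
               malignant_n_measurable = sum(observed[mal]),
               benign_n_measurable = sum(observed[!mal]),
               malignant_mean = mean(cohort[[nm]][mal], na.rm = TRUE),
               malignant_sd = sd(cohort[[nm]][mal], na.rm = TRUE),
               benign_mean = mean(cohort[[nm]][!mal], na.rm = TRUE),
               benign_sd = sd(cohort[[nm]][!mal], na.rm = TRUE),
               lrt = fit@lrt, df = fit@df, p_value = fit@pValue,
               stringsAsFactors = FALSE)
  }))
  rownames(branching) <- NULL

  correlations <- pearsonPairwise(cohort[, .BIOMARKERS])

  subsetComparison <- NULL
  if (!is.null(thicknessCutoffMm) && is.finite(thicknessCutoffMm)) {
    sub <- cohort[cohort$thickness_mm <= thicknessCutoffMm, , drop = FALSE]
    if (all(c("malignant", "benign") %in% sub$label)) {
      subsetComparison <- .comparisonTable(sub, .ALWAYS_MEASURABLE, B, seed)
    } else {
      warning("thickness cutoff empties a group: subset analysis skipped")
    }
  }

  new("GroupAnalysis", comparison = comparison, branching = branching,
      subsetComparison = subsetComparison, correlations = correlations,
      params = list(cutoff = thicknessCutoffMm, B = B, seed = seed,
                    nMalignant = sum(cohort$label == "malignant"),
                    nBenign = sum(cohort$label == "benign")))
}
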