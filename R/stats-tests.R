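#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact permutation null when the pooled sample is small
#' (\code{n_x + n_y <= 20}) and tie-free, otherwise the normal
#' approximation with tie correction and continuity correction.  Two
#' identical constant samples give p = 1.
#'
#' @param x,y numeric samples (each nonempty).
#' @param mode \code{"auto"}, \code{"exact"} or \code{"normal"}.
#' @return Two-sided p-value.
#' @examples
#' wilcoxonRankSum(c(1, 2), c(3, 4))   # 1/3
#' @export
wilcoxonRankSum <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) return(1)
  ties <- anyDuplicated(pooled) > 0L
  exact <- switch(mode,
    auto = length(pooled) <= 20L && !ties,
    exact = TRUE,
    normal = FALSE)
  if (exact && ties) {
    warning("ties present: falling back to the tie-corrected normal approximation")
    exact <- FALSE
  }
  suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE)$p.value)
}

#' Mann-Whitney AUC
#'
#' Probability that a random value of \code{x} (positive class, e.g.
#' malignant) exceeds a random value of \code{y}, counting ties as 1/2:
#' the tie-adjusted Mann-Whitney U statistic divided by \code{n_x * n_y}.
#'
#' @param x positive-class values; \code{y} negative-class values.
#' @param y see \code{x}.
#' @return AUC in [0, 1].
#' @examples
#' aucMW(c(3, 1), c(2, 0))   # 0.75
#' @export
aucMW <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be nonempty")
  r <- rank(c(x, y))
  (sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2) /
    (length(x) * length(y))
}

#' Stratified percentile bootstrap confidence interval for the AUC
#'
#' Resamples within each group independently, recomputes the Mann-Whitney
#' AUC, and returns the percentile interval at the requested level.
#' Reproducible for a fixed seed.
#'
#' @param x,y positive/negative class values.
#' @param B number of bootstrap resamples (>= 200).
#' @param seed integer RNG seed.
#' @param level confidence level.
#' @return Named numeric \code{c(lower, upper)}.
#' @export
aucCIBootstrap <- function(x, y, B = 2000L, seed = 1L, level = 0.95) {
  if (B < 200L) stop("B must be >= 200")
  withSeed(seed, {
    nx <- length(x); ny <- length(y)
    stat <- vapply(seq_len(B), function(b) {
      aucMW(x[sample.int(nx, nx, replace = TRUE)],
            y[sample.int(ny, ny, replace = TRUE)])
    }, numeric(1))
    a <- (1 - level) / 2
    ci <- unname(quantile(stat, c(a, 1 - a), type = 7))
    c(lower = ci[1], upper = ci[2])
  })
}

#' Pairwise-complete Pearson correlation matrix
#'
#' Pearson correlations per biomarker pair over the rows where both values
#' are present; a pair with fewer than 3 complete observations or a
#' constant column is flagged as \code{NA}.
#'
#' @param table data.frame or matrix of numeric columns (NAs allowed).
#' @return Correlation matrix with unit diagonal.
#' @export
pearsonPairwise <- function(table) {
  m <- as.matrix(table)
  if (nrow(m) < 2L) stop("need at least 2 rows")
  p <- ncol(m)
  out <- matrix(NA_real_, p, p, dimnames = list(colnames(m), colnames(m)))
  diag(out) <- 1
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
    ok <- complete.cases(m[, c(i, j)])
    if (sum(ok) < 3L) next
    xi <- m[ok, i]; xj <- m[ok, j]
    if (sd(xi) == 0 || sd(xj) == 0) next
    out[i, j] <- out[j, i] <- cor(xi, xj)
  }
  out
}
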