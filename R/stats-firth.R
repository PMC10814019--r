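#' Firth penalized logistic regression
#'
#' Maximizes the Jeffreys-penalized log-likelihood
#' \eqn{l(\beta) + \frac{1}{2}\log\det I(\beta)} by Newton iterations on
#' the hat-value-corrected score
#' \eqn{U^*_j = \sum_i (y_i - p_i + h_i(1/2 - p_i)) x_{ij}}, with step
#' halving when a step would decrease the penalized likelihood.
#' Coefficients stay finite under complete separation.  Convergence is
#' declared when \eqn{\max_j |U^*_j| < } \code{tol}; non-convergence
#' within \code{maxit} iterations is flagged and the last iterate
#' returned.
#'
#' @param y binary 0/1 response.
#' @param X design matrix (including the intercept column), full rank.
#' @param maxit maximum Newton iterations.
#' @param tol score convergence tolerance.
#' @param penaltyX design matrix whose Fisher information defines the
#'   Jeffreys penalty and hat values (defaults to \code{X}).  A penalized
#'   likelihood-ratio test of nested Firth models must evaluate both fits
#'   under the \emph{same} penalty, so the constrained (null) fit passes
#'   the full design here; its extra columns contribute zero to the linear
#'   predictor but shape the penalty.
#' @return A \linkS4class{FirthFit}.
#' @examples
#' # intercept-only: p-hat = (k + 1/2) / (n + 1)
#' fit <- firthLogistic(c(1, 1, 0, 0, 0), matrix(1, 5))
#' plogis(fit@coefficients[1])  # (2 + 0.5) / (5 + 1)
#' @export
firthLogistic <- function(y, X, maxit = 50L, tol = 1e-9, penaltyX = X) {
  X <- as.matrix(X)
  penaltyX <- as.matrix(penaltyX)
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), nrow(X) == length(y),
            nrow(penaltyX) == length(y))
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  beta <- rep(0, ncol(X))

  penLogLik <- function(beta) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    W <- p * (1 - p)
    info <- crossprod(penaltyX, W * penaltyX)
    # numerically stable log(1 + e^eta)
    ll <- sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
    ll + 0.5 * determinant(info, logarithm = TRUE)$modulus
  }

  converged <- FALSE
  iter <- 0L
  llCur <- penLogLik(beta)
  while (iter < maxit) {
    iter <- iter + 1L
    p <- plogis(drop(X %*% beta))
    W <- p * (1 - p)
    info <- crossprod(X, W * X)
    infoInv <- solve(info)
    # hat values of the weighted penalty design
    infoP <- crossprod(penaltyX, W * penaltyX)
    h <- rowSums((penaltyX %*% solve(infoP)) * penaltyX) * W
    U <- drop(crossprod(X, y - p + h * (0.5 - p)))
    if (max(abs(U)) < tol) { converged <- TRUE; break }
    step <- drop(infoInv %*% U)
    # step halving against the penalized likelihood
    for (half in 0:10) {
      cand <- beta + step / 2^half
      llNew <- penLogLik(cand)
      if (is.finite(llNew) && llNew >= llCur - 1e-10) break
    }
    beta <- cand
    llCur <- llNew
  }
  if (!converged && iter >= maxit)
    warning("Firth logistic regression did not converge in ", maxit,
            " iterations")
  names(beta) <- colnames(X) %||% paste0("b", seq_along(beta) - 1L)
  new("FirthFit", coefficients = beta, logLik = as.numeric(llCur),
      converged = converged, iterations = iter)
}

#' Joint 2-df test of measurability and value under structural missingness
#'
#' Fits the Firth logistic model with linear predictor
#' \eqn{\beta_0 + \beta_1 X_1 + \beta_2 X_1 X_2}, where \eqn{X_1} indicates
#' measurability (1 = observed) and \eqn{X_2} is the biomarker value
#' (z-scored over the observed rows; the fill value for unobserved rows is
#' irrelevant because \eqn{X_2} only enters through \eqn{X_1 X_2}), and
#' compares it to the intercept-only null with a likelihood ratio test on
#' the penalized likelihoods, \eqn{\chi^2} with 2 degrees of freedom.
#' Redundant design columns (e.g. \eqn{X_1} constant at 1) are dropped and
#' the degrees of freedom adjusted, with a warning.
#'
#' @param y binary 0/1 outcome (1 = malignant).
#' @param value biomarker values; must be present wherever
#'   \code{observed == 1}.
#' @param observed 0/1 measurability indicator.
#' @param fill fill value for unobserved standardized \eqn{X_2}.
#' @return A \linkS4class{FirthFit} carrying the LRT statistic, df and
#'   p-value.
#' @export
missingnessLRT <- function(y, value, observed, fill = 0) {
  observed <- as.integer(observed != 0)
  if (any(observed == 1 & is.na(value)))
    stop("value must be present wherever observed = 1")
  z <- rep(fill, length(value))
  obsVals <- value[observed == 1]
  if (length(obsVals) >= 2L && sd(obsVals) > 0) {
    z[observed == 1] <- (obsVals - mean(obsVals)) / sd(obsVals)
  } else if (length(obsVals)) {
    z[observed == 1] <- 0
  }
  Xfull <- cbind(intercept = 1, X1 = observed, X1X2 = observed * z)
  qrF <- qr(Xfull)
  if (qrF$rank < ncol(Xfull)) {
    keep <- qrF$pivot[seq_len(qrF$rank)]
    warning("reduced-rank design: dropping ",
            paste(colnames(Xfull)[-keep], collapse = ", "),
            "; degrees of freedom adjusted")
    Xfull <- Xfull[, sort(keep), drop = FALSE]
  }
  # constrained (intercept-only) fit under the FULL model's penalty, so
  # the two penalized likelihoods are comparable
  fitNull <- firthLogistic(y, matrix(1, length(y), 1,
                                     dimnames = list(NULL, "intercept")),
                           penaltyX = Xfull)
  fitFull <- firthLogistic(y, Xfull)
  lrt <- max(0, 2 * (fitFull@logLik - fitNull@logLik))
  df <- ncol(Xfull) - 1L
  fitFull@lrt <- lrt
  fitFull@df <- as.integer(df)
  fitFull@pValue <- pchisq(lrt, df = df, lower.tail = FALSE)
  fitFull
}
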