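# Internal numerical helpers shared across modules.

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a stream of child seeds (< 2^31) from one master seed.
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Separable Gaussian smoothing with replicate (edge-clamped) padding.
# Operates on a numeric matrix; sigma in pixels.
gaussSmooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  convRows <- function(x) {
    xp <- x[c(rep(1L, r), seq_len(nrow(x)), rep(nrow(x), r)), , drop = FALSE]
    out <- matrix(0, nrow(x), ncol(x))
    for (j in seq_along(k))
      out <- out + k[j] * xp[j:(j + nrow(x) - 1L), , drop = FALSE]
    out
  }
  t(convRows(t(convRows(m))))
}

# Complex-aware Gaussian blur of each slow-time frame of a 3-D array.
blurFrames <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  for (t in seq_len(dim(arr)[3])) {
    fr <- arr[, , t]
    arr[, , t] <- complex(real = gaussSmooth(Re(fr), sigma),
                          imaginary = gaussSmooth(Im(fr), sigma))
  }
  arr
}

# Log-normal parameters (meanlog, sdlog) matched to an arithmetic mean/SD.
lnormParams <- function(m, s) {
  if (m <= 0) stop("log-normal moment matching needs a positive mean")
  if (s <= 0) return(c(meanlog = log(m), sdlog = 0))
  s2 <- log(1 + (s / m)^2)
  c(meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}

# Zero-inflated Poisson (pi, lambda) matching a target mean and P(X = 0).
# mean = (1 - pi) * lambda ; P0 = pi + (1 - pi) * exp(-lambda).
# When p0 <= exp(-mean) a plain Poisson already undershoots the zero mass,
# so pi is clamped at 0 and lambda = mean.
zipParams <- function(mean, p0) {
  if (mean <= 0) return(c(pi = 1, lambda = 0))
  if (p0 <= exp(-mean) + 1e-12) return(c(pi = 0, lambda = mean))
  f <- function(lam) 1 - mean / lam + (mean / lam) * exp(-lam) - p0
  # lambda must exceed the mean for any zero inflation
  lam <- uniroot(f, lower = mean + 1e-9, upper = mean + 50, tol = 1e-10)$root
  c(pi = 1 - mean / lam, lambda = lam)
}

rzip <- function(n, mean, p0) {
  par <- zipParams(mean, p0)
  structural <- rbinom(n, 1L, par["pi"]) == 1L
  x <- rpois(n, par["lambda"])
  x[structural] <- 0L
  x
}

# Resample a polyline (n x 2) to roughly equal arc-length spacing `step`.
resamplePolyline <- function(pts, step) {
  d <- sqrt(rowSums(diff(pts)^2))
  cum <- c(0, cumsum(d))
  L <- cum[length(cum)]
  if (L == 0) return(pts[1, , drop = FALSE])
  s <- seq(0, L, by = step)
  if (s[length(s)] < L) s <- c(s, L)
  x <- approx(cum, pts[, 1], xout = s)$y
  y <- approx(cum, pts[, 2], xout = s)$y
  cbind(x, y)
}

polylineLength <- function(pts) sum(sqrt(rowSums(diff(pts)^2)))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
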