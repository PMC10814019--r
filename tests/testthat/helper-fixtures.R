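# Programmatic fixtures shared across the suite.

# horizontal band of given height centered vertically
drawBand <- function(nr = 64L, nc = 64L, height = 8L,
                     cols = 5L:(nc - 4L)) {
  m <- matrix(0L, nr, nc)
  r0 <- (nr - height) %/% 2L
  m[(r0 + 1L):(r0 + height), cols] <- 1L
  m
}

# symmetric Y: vertical trunk splitting into two diagonal arms
drawY <- function(n = 96L, width = 5L) {
  m <- matrix(0L, n, n)
  half <- floor(width / 2)
  cx <- n %/% 2L
  jr <- n %/% 2L
  for (r in 8L:jr) m[r, (cx - half):(cx + half)] <- 1L
  for (k in 0L:(n %/% 3L)) {
    r <- jr + k
    if (r > n - 4L) break
    for (cc in c(cx - k, cx + k))
      if (cc - half >= 1L && cc + half <= n)
        m[r, (cc - half):(cc + half)] <- 1L
  }
  m
}

# X: two crossing diagonal bands
drawX <- function(n = 96L, width = 5L) {
  m <- matrix(0L, n, n)
  half <- floor(width / 2)
  for (k in 8L:(n - 8L)) {
    m[k, max(1L, k - half):min(n, k + half)] <- 1L
    m[k, max(1L, n - k - half):min(n, n - k + half)] <- 1L
  }
  m
}

# half-circle arc band of radius r (pixels), thickness w
drawHalfCircle <- function(r = 40L, w = 5L) {
  n <- 2L * r + 2L * w + 8L
  m <- matrix(0L, n, n)
  cx <- n / 2; cy <- w + 4
  th <- seq(0, pi, length.out = ceiling(pi * r * 4))
  for (t in th) {
    x <- cx + r * cos(t); y <- cy + r * sin(t)
    rows <- round(y + (-w:w) / 2); cols <- round(x + (-w:w) / 2)
    for (dr in -floor(w / 2):floor(w / 2))
      for (dc in -floor(w / 2):floor(w / 2))
        if ((dr^2 + dc^2) <= (w / 2)^2) {
          rr <- round(y) + dr; cc <- round(x) + dc
          if (rr >= 1 && rr <= n && cc >= 1 && cc <= n) m[rr, cc] <- 1L
        }
  }
  m
}

# quadratic Koch ("Minkowski sausage") prefractal, dimension log8/log4 = 1.5
minkowskiCurve <- function(level = 3L, step = 4L) {
  # turtle program: F -> F+F-F-FF+F+F-F, 90 degree turns
  prog <- "F"
  for (i in seq_len(level))
    prog <- paste(vapply(strsplit(prog, "")[[1]], function(ch)
      if (ch == "F") "F+F-F-FF+F+F-F" else ch, character(1)), collapse = "")
  dirs <- list(c(0L, 1L), c(1L, 0L), c(0L, -1L), c(-1L, 0L))
  d <- 1L
  pos <- c(0L, 0L)
  pts <- list(pos)
  for (ch in strsplit(prog, "")[[1]]) {
    if (ch == "F") {
      for (s in seq_len(step)) {
        pos <- pos + dirs[[d]]
        pts[[length(pts) + 1L]] <- pos
      }
    } else if (ch == "+") d <- (d %% 4L) + 1L
    else if (ch == "-") d <- ((d + 2L) %% 4L) + 1L
  }
  P <- do.call(rbind, pts)
  P[, 1] <- P[, 1] - min(P[, 1]) + 1L
  P[, 2] <- P[, 2] - min(P[, 2]) + 1L
  m <- matrix(0L, max(P[, 1]) + 1L, max(P[, 2]) + 1L)
  m[P] <- 1L
  m
}

# single straight-vessel ensemble for recon tests
singleVesselRaster <- function(diameterUm = 300, pitchUm = 50,
                               nr = 48L, nc = 40L, vertical = TRUE,
                               flow = 10) {
  pitchMm <- pitchUm / 1000
  margin <- diameterUm / 2000 + 0.1   # keep the dilated lumen on the grid
  if (vertical) {
    pts <- cbind(x = rep(nc / 2 * pitchMm, 32),
                 z = seq(max(0.4, margin), nr * pitchMm - margin,
                         length.out = 32))
  } else {
    pts <- cbind(x = seq(max(0.4, margin), nc * pitchMm - margin,
                         length.out = 32),
                 z = rep(nr / 2 * pitchMm, 32))
  }
  tree <- new("VesselTree",
              segments = list(list(points = pts, diameter_um = diameterUm,
                                   flow_mm_s = flow, heading = 0)),
              parents = NA_integer_, bifurcations = list(),
              fieldSize = c(nc, nr) * pitchMm)
  rasterizeTree(tree, pitchUm, c(nr, nc))
}

emptyTree <- function(fieldMm = c(3.2, 3.2)) {
  new("VesselTree", segments = list(), parents = integer(0),
      bifurcations = list(), fieldSize = fieldMm)
}

# Vicsek cross prefractal on a 3^level grid; box-counting dimension log5/log3
vicsekFractal <- function(level = 5L) {
  m <- matrix(1L, 1L, 1L)
  for (i in seq_len(level)) {
    n <- nrow(m)
    out <- matrix(0L, 3L * n, 3L * n)
    for (cell in list(c(0, 1), c(1, 0), c(1, 1), c(1, 2), c(2, 1)))
      out[cell[1] * n + seq_len(n), cell[2] * n + seq_len(n)] <- m
    m <- out
  }
  m
}

# brute-force two-sided rank-sum p-value by enumerating all group splits
enumWilcoxP <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  r <- rank(pooled)
  uObs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  splits <- combn(n, nx)
  u <- apply(splits, 2, function(ix) sum(r[ix]) - nx * (nx + 1) / 2)
  min(1, 2 * min(mean(u <= uObs), mean(u >= uObs)))
}

# synthetic Skeleton with three straight arms meeting at one node,
# constant diameter per arm: exercises junction metrics in isolation
threeArmSkeleton <- function(diams, pitch = 1) {
  arm <- function(dr, dc, d) {
    path <- cbind(20 + dr * (1:10), 20 + dc * (1:10))
    list(path = path, diam_um = rep(d, 10), node_from = 1L, node_to = NA)
  }
  segs <- list(arm(-1, 0, diams[1]), arm(1, -1, diams[2]),
               arm(1, 1, diams[3]))
  nodes <- data.frame(id = 1L, row = 20, col = 20, type = "branch_point",
                      stringsAsFactors = FALSE)
  new("Skeleton", nodes = nodes, segments = segs,
      mask = matrix(0L, 40, 40), pixelPitch = pitch)
}
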