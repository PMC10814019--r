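# Topological thinning and skeleton-graph segmentation.

.shift <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Guo-Hall topological thinning of a binary matrix to a 1-px skeleton
# (unit-width diagonals, unlike Zhang-Suen which leaves staircases).
thinMask <- function(mask) {
  m <- (mask != 0) * 1L
  repeat {
    changed <- FALSE
    for (sub in 0:1) {
      # neighbors clockwise from north: P2..P9
      p2 <- .shift(m, -1L, 0L); p3 <- .shift(m, -1L, 1L)
      p4 <- .shift(m, 0L, 1L);  p5 <- .shift(m, 1L, 1L)
      p6 <- .shift(m, 1L, 0L);  p7 <- .shift(m, 1L, -1L)
      p8 <- .shift(m, 0L, -1L); p9 <- .shift(m, -1L, -1L)
      C <- (p2 == 0L & (p3 == 1L | p4 == 1L)) +
           (p4 == 0L & (p5 == 1L | p6 == 1L)) +
           (p6 == 0L & (p7 == 1L | p8 == 1L)) +
           (p8 == 0L & (p9 == 1L | p2 == 1L))
      N1 <- (p9 == 1L | p2 == 1L) + (p3 == 1L | p4 == 1L) +
            (p5 == 1L | p6 == 1L) + (p7 == 1L | p8 == 1L)
      N2 <- (p2 == 1L | p3 == 1L) + (p4 == 1L | p5 == 1L) +
            (p6 == 1L | p7 == 1L) + (p8 == 1L | p9 == 1L)
      N <- pmin(N1, N2)
      mm <- if (sub == 0L) {
        ((p6 == 1L | p7 == 1L | p9 == 0L) & p8 == 1L)
      } else {
        ((p2 == 1L | p3 == 1L | p5 == 0L) & p4 == 1L)
      }
      del <- m == 1L & C == 1L & N >= 2L & N <= 3L & !mm
      if (any(del)) { m[del] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

# Decompose a 1-px skeleton into typed nodes and ordered node-free segments.
# Branch pixels (>= 3 skeleton neighbors) within `mergeRadius` (Chebyshev)
# are clustered into single branch points.
.segmentTopology <- function(sk, mergeRadius = 2L) {
  nb <- .shift(sk, -1L, 0L) + .shift(sk, -1L, 1L) + .shift(sk, 0L, 1L) +
        .shift(sk, 1L, 1L) + .shift(sk, 1L, 0L) + .shift(sk, 1L, -1L) +
        .shift(sk, 0L, -1L) + .shift(sk, -1L, -1L)
  branch <- sk == 1L & nb >= 3L
  bIdx <- which(branch)
  nr <- nrow(sk)
  bR <- ((bIdx - 1L) %% nr) + 1L
  bC <- ((bIdx - 1L) %/% nr) + 1L
  # cluster branch pixels within the merge radius
  if (length(bIdx)) {
    if (length(bIdx) == 1L) {
      bClust <- 1L
    } else {
      ad <- outer(bR, bR, function(a, b) abs(a - b)) <= mergeRadius &
            outer(bC, bC, function(a, b) abs(a - b)) <= mergeRadius
      g <- igraph::graph_from_adjacency_matrix(ad, mode = "undirected",
                                               diag = FALSE)
      bClust <- components(g)$membership
    }
    nClust <- max(bClust)
    clustPix <- split(seq_along(bIdx), bClust)
  } else {
    nClust <- 0L
    clustPix <- list()
  }
  clustAt <- matrix(0L, nr, ncol(sk))
  clustAt[bIdx] <- bClust0 <- if (length(bIdx)) bClust else integer()

  # path pixels = skeleton minus branch pixels; 8-connected components
  pathMask <- sk
  pathMask[branch] <- 0L
  lab <- label8(pathMask)
  nLab <- max(lab)

  segs <- list()
  segEnds <- list()   # per segment: cluster id touched by each end (0 = free)
  for (li in seq_len(nLab)) {
    pIdx <- which(lab == li)
    if (length(pIdx) < 2L) next
    pr <- ((pIdx - 1L) %% nr) + 1L
    pc <- ((pIdx - 1L) %/% nr) + 1L
    n <- length(pIdx)
    # adjacency inside the component
    ad <- outer(pr, pr, function(a, b) abs(a - b)) <= 1L &
          outer(pc, pc, function(a, b) abs(a - b)) <= 1L
    diag(ad) <- FALSE
    w <- sqrt(outer(pr, pr, "-")^2 + outer(pc, pc, "-")^2)
    g <- igraph::graph_from_adjacency_matrix(ad * w, mode = "undirected",
                                             weighted = TRUE)
    deg <- degree(g)
    ends <- which(deg <= 1L)
    if (length(ends) >= 2L) {
      ord <- as.integer(shortest_paths(g, from = ends[1], to = ends[2],
                                       output = "vpath")$vpath[[1]])
    } else {
      # cycle (or blob): walk a spanning path from an arbitrary vertex
      far <- as.integer(igraph::dfs(g, root = 1)$order)
      ord <- far
    }
    path <- cbind(row = pr[ord], col = pc[ord])
    # cluster attachment of each end: any branch cluster in the 8-neighborhood
    endCl <- integer(2)
    for (e in 1:2) {
      px <- path[if (e == 1) 1L else nrow(path), ]
      rs <- clamp((px[1] - 1L):(px[1] + 1L), 1L, nr)
      cs <- clamp((px[2] - 1L):(px[2] + 1L), 1L, ncol(sk))
      cl <- clustAt[rs, cs]
      cl <- cl[cl > 0L]
      endCl[e] <- if (length(cl)) cl[1] else 0L
    }
    segs[[length(segs) + 1L]] <- path
    segEnds[[length(segEnds) + 1L]] <- endCl
  }
  list(segments = segs, segEnds = segEnds, nClust = nClust,
       clustPix = clustPix, bIdx = bIdx, bR = bR, bC = bC,
       branchMask = branch)
}

#' Skeletonize a binary vessel mask and segment it into a vessel graph
#'
#' Topological (Zhang-Suen) thinning to a one-pixel skeleton; junction
#' pixels with three or more skeleton neighbors are clustered
#' (8-connectivity, merge radius 2 px) into single branch points; spur
#' segments shorter than \code{prunePx} hanging off a junction are removed
#' and the topology rebuilt; the remaining maximal node-free paths become
#' segments.  Each segment carries a diameter profile: twice the Euclidean
#' distance transform of the source mask sampled along the skeleton, in
#' micrometres.  An empty mask yields an empty skeleton (0 segments, 0
#' branch points) rather than an error.
#'
#' @param mask a \linkS4class{BinaryVesselMask} (or binary matrix).
#' @param prunePx spur-pruning length threshold in pixels.
#' @param mergeRadius junction clustering radius in pixels (Chebyshev).
#' @param pixelPitchUm pixel pitch when \code{mask} is a bare matrix.
#' @return A \linkS4class{Skeleton}.
#' @examples
#' m <- matrix(0L, 32, 32); m[14:18, 4:28] <- 1L
#' sk <- skeletonizeVessels(m, pixelPitchUm = 50)
#' nSegments(sk); nBranchPoints(sk)
#' @export
skeletonizeVessels <- function(mask, prunePx = 4, mergeRadius = 2L,
                               pixelPitchUm = NULL) {
  if (is(mask, "BinaryVesselMask")) {
    m <- vesselMask(mask)
    pitch <- pixelPitch(mask)
  } else {
    m <- (mask != 0) * 1L
    pitch <- pixelPitchUm %||% 50
  }
  emptySkel <- function() new("Skeleton",
    nodes = data.frame(id = integer(), row = integer(), col = integer(),
                       type = character(), stringsAsFactors = FALSE),
    segments = list(), mask = matrix(0L, nrow(m), ncol(m)),
    pixelPitch = pitch)
  if (!any(m == 1L)) return(emptySkel())

  sk <- thinMask(m)
  # iterative spur pruning: drop short junction-attached dead ends, rebuild
  for (it in seq_len(10L)) {
    topo <- .segmentTopology(sk, mergeRadius)
    if (!length(topo$segments)) break
    drop <- logical(length(topo$segments))
    for (i in seq_along(topo$segments)) {
      ec <- topo$segEnds[[i]]
      isSpur <- xor(ec[1] > 0L, ec[2] > 0L)
      if (isSpur) {
        len <- polylineLength(topo$segments[[i]])
        if (len < prunePx) drop[i] <- TRUE
      }
    }
    if (!any(drop)) break
    for (i in which(drop)) {
      p <- topo$segments[[i]]
      sk[cbind(p[, 1], p[, 2])] <- 0L
    }
  }
  if (!any(sk == 1L)) return(emptySkel())

  topo <- .segmentTopology(sk, mergeRadius)
  if (!length(topo$segments) && !topo$nClust) return(emptySkel())

  # nodes: branch clusters kept only if >= 3 incident segment ends
  endClusters <- unlist(topo$segEnds)
  incid <- tabulate(endClusters[endClusters > 0L], nbins = max(1L, topo$nClust))
  nodes <- data.frame(id = integer(), row = integer(), col = integer(),
                      type = character(), stringsAsFactors = FALSE)
  clustNode <- integer(topo$nClust)
  for (ci in seq_len(topo$nClust)) {
    pix <- topo$clustPix[[ci]]
    nid <- nrow(nodes) + 1L
    clustNode[ci] <- nid
    nodes[nid, c("id", "row", "col")] <-
      c(nid, round(mean(topo$bR[pix])), round(mean(topo$bC[pix])))
    nodes$type[nid] <- if (topo$nClust && incid[ci] >= 3L)
      "branch_point" else "endpoint"
  }
  # distance-transform diameters from the source mask
  dt <- as.matrix(distmap(Image(m)))
  segments <- list()
  for (i in seq_along(topo$segments)) {
    p <- topo$segments[[i]]
    ec <- topo$segEnds[[i]]
    nf <- if (ec[1] > 0L) clustNode[ec[1]] else NA_integer_
    nt <- if (ec[2] > 0L) clustNode[ec[2]] else NA_integer_
    for (e in which(ec == 0L)) {
      nid <- nrow(nodes) + 1L
      px <- p[if (e == 1) 1L else nrow(p), ]
      nodes[nid, c("id", "row", "col")] <- c(nid, px[1], px[2])
      nodes$type[nid] <- "endpoint"
      if (e == 1) nf <- nid else nt <- nid
    }
    segments[[i]] <- list(path = p,
                          diam_um = 2 * dt[cbind(p[, 1], p[, 2])] * pitch,
                          node_from = nf, node_to = nt)
  }
  new("Skeleton", nodes = nodes, segments = segments, mask = sk,
      pixelPitch = pitch)
}
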