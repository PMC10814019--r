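# Artifact I/O: IQ ensembles (flat binary + JSON header), images (32-bit
# float TIFF + JSON sidecar), cohort CSVs, ROI polygons (JSON).

.IQ_MAGIC <- "CMVQIQ1"

#' Write / read an IQ ensemble
#'
#' Ensembles are stored as a single file: a magic string, a JSON header
#' (dimensions, frame rate Hz, center frequency MHz, sound speed m/s,
#' pixel pitch um) and the little-endian float64 real/imaginary stream in
#' column-major order.  The round trip is lossless.
#'
#' @param ensemble an \linkS4class{IQEnsemble}.
#' @param path file path.
#' @return \code{writeIQEnsemble} returns \code{path} invisibly;
#'   \code{readIQEnsemble} returns the \linkS4class{IQEnsemble}.
#' @export
writeIQEnsemble <- function(ensemble, path) {
  stopifnot(is(ensemble, "IQEnsemble"))
  hdr <- toJSON(list(dims = dim(iqData(ensemble)),
                     frame_rate_hz = frameRate(ensemble),
                     fc_mhz = centerFrequency(ensemble),
                     c_mps = ensemble@soundSpeed,
                     pitch_um = pixelPitch(ensemble)),
                auto_unbox = TRUE, digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(.IQ_MAGIC), con)
  hraw <- charToRaw(as.character(hdr))
  writeBin(length(hraw), con, size = 4L, endian = "little")
  writeBin(hraw, con)
  v <- as.vector(iqData(ensemble))
  writeBin(as.double(rbind(Re(v), Im(v))), con, size = 8L,
           endian = "little")
  invisible(path)
}

#' @rdname writeIQEnsemble
#' @export
readIQEnsemble <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", nchar(.IQ_MAGIC)))
  if (!identical(magic, .IQ_MAGIC)) stop("not a choromvq IQ ensemble file")
  hlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  hdr <- fromJSON(rawToChar(readBin(con, "raw", hlen)))
  n <- prod(hdr$dims)
  raw <- readBin(con, "double", 2L * n, size = 8L, endian = "little")
  v <- complex(real = raw[seq(1L, 2L * n, 2L)],
               imaginary = raw[seq(2L, 2L * n, 2L)])
  new("IQEnsemble", data = array(v, hdr$dims),
      frameRate = as.numeric(hdr$frame_rate_hz),
      centerFrequency = as.numeric(hdr$fc_mhz),
      soundSpeed = as.numeric(hdr$c_mps),
      pixelPitch = as.numeric(hdr$pitch_um))
}

#' Write / read a microvessel image as 32-bit float TIFF
#'
#' Intensities are affinely mapped to [0, 1] for TIFF storage; the mapping,
#' pixel pitch and provenance go to a JSON sidecar (\code{<path>.json}) and
#' are restored on read.  The round trip is exact to 32-bit float
#' precision.
#'
#' @param image an \linkS4class{HDMIImage}.
#' @param path TIFF file path.
#' @return \code{writeHDMIImage} returns \code{path} invisibly;
#'   \code{readHDMIImage} the restored \linkS4class{HDMIImage}.
#' @export
writeHDMIImage <- function(image, path) {
  stopifnot(is(image, "HDMIImage"))
  img <- intensity(image)
  lo <- min(img); hi <- max(img)
  scaled <- if (hi > lo) (img - lo) / (hi - lo) else img * 0
  writeTIFF(scaled, path, bits.per.sample = 32L, compression = "none")
  write_json(list(pitch_um = pixelPitch(image), min = lo, max = hi,
                  provenance = provenance(image)),
             paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeHDMIImage
#' @export
readHDMIImage <- function(path) {
  meta <- read_json(paste0(path, ".json"), simplifyVector = TRUE)
  v <- readTIFF(path)
  img <- meta$min + v * (meta$max - meta$min)
  prov <- meta$provenance
  if (is.data.frame(prov)) prov <- split(prov, seq_len(nrow(prov)))
  if (is.null(prov)) prov <- list()
  new("HDMIImage", intensity = pmax(img, 0),
      pixelPitch = as.numeric(meta$pitch_um), provenance = as.list(prov))
}

#' Write / read a cohort table as CSV
#'
#' Unmeasurable branching-biomarker cells are written as empty strings and
#' reconstructed as \code{NA} with the \code{measurable_MD_BA} flag; the
#' flag is re-derived and checked for consistency on read.
#'
#' @param cohort cohort data.frame (see \code{\link{generateCohort}}).
#' @param path CSV path.
#' @return \code{writeCohort} returns \code{path} invisibly;
#'   \code{readCohort} the cohort data.frame.
#' @export
writeCohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path) {
  co <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "label", "thickness_mm", .BIOMARKERS, "measurable_MD_BA")
  miss <- setdiff(need, names(co))
  if (length(miss))
    stop("cohort CSV is missing columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(co$label), c("benign", "malignant"))
  if (length(bad)) stop("invalid labels: ", paste(bad, collapse = ", "))
  flagged <- co$measurable_MD_BA == 0L
  empty <- apply(is.na(co[, .BRANCHING, drop = FALSE]), 1, all)
  if (any(flagged != empty))
    stop("measurable_MD_BA flags are inconsistent with empty MD/BA cells")
  co
}

# --- ROI polygons ----------------------------------------------------------

# proper segment-intersection predicate (shared endpoints allowed)
.segIntersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) -
                         (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

#' Read and validate an ROI polygon
#'
#' ROI polygons are JSON objects with a \code{vertices} array of
#' \code{[x, z]} coordinates in mm.  Polygons with fewer than 3 vertices or
#' with self-intersecting edges are rejected.
#'
#' @param path JSON file path.
#' @return n x 2 matrix of vertices (mm).
#' @export
readROIPolygon <- function(path) {
  obj <- read_json(path, simplifyVector = TRUE)
  v <- obj$vertices
  if (is.null(v)) stop("ROI JSON must contain a 'vertices' field")
  v <- matrix(as.numeric(unlist(v)), ncol = 2, byrow = is.list(v))
  validateROIPolygon(v)
  v
}

#' @rdname readROIPolygon
#' @param vertices n x 2 matrix of polygon vertices.
#' @export
validateROIPolygon <- function(vertices) {
  if (!is.matrix(vertices) || ncol(vertices) != 2 || nrow(vertices) < 3)
    stop("an ROI polygon needs at least 3 two-dimensional vertices")
  n <- nrow(vertices)
  edges <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    # skip adjacent edges (they share a vertex)
    if (abs(i - j) <= 1L || (i == 1L && j == n)) next
    if (.segIntersect(vertices[edges[i, 1], ], vertices[edges[i, 2], ],
                      vertices[edges[j, 1], ], vertices[edges[j, 2], ]))
      stop("ROI polygon is self-intersecting (edges ", i, " and ", j, ")")
  }
  invisible(TRUE)
}

#' Rasterize an ROI polygon to a binary mask
#'
#' Even-odd (ray casting) point-in-polygon test at pixel centers.
#'
#' @param vertices n x 2 matrix (x, z) in mm.
#' @param dim integer length-2 grid shape (rows = depth, cols = lateral).
#' @param pixelPitchUm pixel pitch, micrometres.
#' @return Integer matrix mask.
#' @export
roiFromPolygon <- function(vertices, dim, pixelPitchUm = 50) {
  validateROIPolygon(vertices)
  pitch <- pixelPitchUm / 1000
  cz <- (seq_len(dim[1]) - 0.5) * pitch   # depth of row centers
  cx <- (seq_len(dim[2]) - 0.5) * pitch   # lateral of col centers
  px <- rep(cx, each = dim[1])
  pz <- rep(cz, times = dim[2])
  inside <- rep(FALSE, length(px))
  n <- nrow(vertices)
  j <- n
  for (i in seq_len(n)) {
    xi <- vertices[i, 1]; zi <- vertices[i, 2]
    xj <- vertices[j, 1]; zj <- vertices[j, 2]
    cross <- ((zi > pz) != (zj > pz)) &
      (px < (xj - xi) * (pz - zi) / (zj - zi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  matrix(as.integer(inside), dim[1], dim[2])
}
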