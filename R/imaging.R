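#' @include geometry.R
NULL

#' Construct a multi-channel image stack
#'
#' @param channels a named list of 3D numeric arrays sharing dimensions
#'   (conventional names: \code{membrane}, \code{eggshell}, \code{dic}),
#'   or a single 3D array (stored as channel \code{"membrane"}).
#' @param spacing numeric length-3 voxel spacing in micrometres. Voxel
#'   centers sit at (index - 1 + 0.5) * spacing.
#' @export
ImageStack <- function(channels, spacing) {
  if (is.array(channels) && !is.list(channels))
    channels <- list(membrane = channels)
  new("ImageStack", channels = channels, spacing = as.numeric(spacing))
}

## separable Gaussian blur via FFT (sigma per axis, in voxels)
.gaussBlur3D <- function(img, sigmaVox) {
  d <- dim(img)
  kern1 <- function(n, s) {
    if (s <= 0) return(c(1, rep(0, n - 1)))
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    k <- exp(-x^2 / (2 * s^2))
    k / sum(k)
  }
  K <- outer(outer(kern1(d[1], sigmaVox[1]), kern1(d[2], sigmaVox[2])),
             kern1(d[3], sigmaVox[3]))
  out <- Re(stats::fft(stats::fft(img) * stats::fft(K), inverse = TRUE)) / prod(d)
  array(pmax(out, 0), d)
}

## trilinear resampling of a 3D array to a new spacing
.resample3D <- function(img, spacing, target) {
  d <- dim(img)
  nNew <- pmax(1L, round(d * spacing / target))
  idx <- function(k) {
    xphys <- ((seq_len(nNew[k]) - 0.5) * target)
    fi <- xphys / spacing[k] - 0.5 + 1      # fractional 1-based index
    i0 <- pmin(pmax(floor(fi), 1), d[k])
    i1 <- pmin(i0 + 1, d[k])
    w <- pmin(pmax(fi - i0, 0), 1)
    list(i0 = i0, i1 = i1, w = w)
  }
  g <- lapply(1:3, idx)
  out <- array(0, nNew)
  for (c1 in 0:1) for (c2 in 0:1) for (c3 in 0:1) {
    part <- img[if (c1) g[[1]]$i1 else g[[1]]$i0,
                if (c2) g[[2]]$i1 else g[[2]]$i0,
                if (c3) g[[3]]$i1 else g[[3]]$i0, drop = FALSE]
    w1 <- if (c1) g[[1]]$w else 1 - g[[1]]$w
    w2 <- if (c2) g[[2]]$w else 1 - g[[2]]$w
    w3 <- if (c3) g[[3]]$w else 1 - g[[3]]$w
    part <- sweep(part, 1, w1, "*")
    part <- sweep(part, 2, w2, "*")
    part <- sweep(part, 3, w3, "*")
    out <- out + part
  }
  out
}

#' Gaussian smoothing and cubic-voxel resampling
#'
#' Smooths every channel with an isotropic Gaussian of physical width
#' \code{sigma} and resamples the anisotropic stack to isotropic cubic
#' voxels (default 0.733 micrometres) by trilinear interpolation.
#'
#' @param s an \code{ImageStack} with known spacings.
#' @param sigma Gaussian sigma in micrometres (default 0.5).
#' @param targetSpacing cubic voxel edge in micrometres (default 0.733).
#' @return an isotropic \code{ImageStack}.
#' @export
preprocessStack <- function(s, sigma = 0.5, targetSpacing = 0.733) {
  stopifnot(is(s, "ImageStack"))
  if (any(!is.finite(s@spacing))) stop("missing spacing metadata")
  sigmaVox <- sigma / s@spacing
  ch <- lapply(s@channels, function(img) {
    b <- if (sigma > 0) .gaussBlur3D(img, sigmaVox) else img
    .resample3D(b, s@spacing, targetSpacing)
  })
  ImageStack(ch, rep(targetSpacing, 3))
}

#' Marker-based 3D watershed segmentation
#'
#' Meyer flooding on the membrane-intensity landscape (the bright
#' membrane forms the ridge between the dark basins, so the intensity is
#' used directly as topography) from three markers representing AB, P1
#' and the exterior. Voxels where two basins meet become a one-voxel
#' thick boundary label.
#'
#' @param v a preprocessed isotropic \code{ImageStack} (its
#'   \code{membrane} channel is used) or a 3D array plus \code{spacing}.
#' @param markers integer matrix of 1-based voxel indices (one row per
#'   marker); rows ordered AB, P1, exterior, or named via rownames with
#'   those region names. A two-marker variant (e.g. AB + exterior for a
#'   single digitized test body) is allowed.
#' @param spacing voxel spacing when \code{v} is a bare array.
#' @return a \code{\linkS4class{LabelVolume}} (0 = boundary, 1 = AB,
#'   2 = P1, 3 = exterior).
#' @export
watershedSegment <- function(v, markers, spacing = NULL) {
  if (is(v, "ImageStack")) {
    img <- v@channels[["membrane"]]
    spacing <- v@spacing[1]
  } else img <- v
  d <- dim(img)
  markers <- as.matrix(markers)
  if (!nrow(markers) %in% 2:3) stop("2 or 3 markers required")
  if (anyDuplicated(markers)) stop("coincident markers")
  labs <- if (!is.null(rownames(markers))) {
    code <- .LABEL_LEVELS[rownames(markers)]
    if (any(is.na(code)) || any(code == 0L)) stop("unknown marker region name")
    as.integer(code)
  } else if (nrow(markers) == 3) 1:3 else c(1L, 3L)
  lin <- (markers[, 1] - 1L) + d[1] * ((markers[, 2] - 1L) + d[2] * (markers[, 3] - 1L))
  lab <- cpp_watershed(as.integer(d), as.numeric(img), as.integer(lin), labs)
  lab[lab == -1L] <- 0L
  new("LabelVolume", labels = array(lab, d), spacing = spacing)
}

#' Voxel-count region volume
#'
#' The half-boundary-corrected voxel count V = N_cell + N_bnd / 2, where
#' N_cell is the number of voxels labeled as the region and N_bnd the
#' number of boundary-labeled voxels face-adjacent (6-connectivity) to
#' it, multiplied by the voxel volume. Accurate to better than 1% for
#' smooth regions whose minimum feature radius is at least ~8 voxels;
#' sharp-cornered regions (e.g. digitized cubes) fall outside this
#' contract because the boundary layer no longer straddles the true
#' surface evenly.
#'
#' @param lv a \code{LabelVolume}.
#' @param region \code{"AB"}, \code{"P1"} or \code{"exterior"}.
#' @return volume in cubic micrometres.
#' @export
regionVolume <- function(lv, region) {
  stopifnot(is(lv, "LabelVolume"))
  code <- .LABEL_LEVELS[[region]]
  if (is.null(code)) stop("unknown region '", region, "'")
  lab <- lv@labels
  cell <- lab == code
  if (!any(cell)) stop("region '", region, "' absent from label volume")
  adj <- .faceAdjacent(cell)
  nbnd <- sum(lab == 0L & adj)
  (sum(cell) + nbnd / 2) * lv@spacing^3
}

## voxels face-adjacent (6-connectivity) to a logical mask
.faceAdjacent <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  shift <- function(m, ax, k) {
    r <- array(FALSE, d)
    n <- d[ax]
    if (n < 2) return(r)
    src <- dst <- list(1:d[1], 1:d[2], 1:d[3])
    src[[ax]] <- if (k > 0) 1:(n - 1) else 2:n
    dst[[ax]] <- if (k > 0) 2:n else 1:(n - 1)
    r[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    r
  }
  for (ax in 1:3) for (k in c(-1, 1)) out <- out | shift(mask, ax, k)
  out
}

#' Physical coordinates of labeled voxels
#'
#' Voxel centers ((index - 0.5) * spacing) of all voxels carrying a
#' label code.
#'
#' @param lv a \code{LabelVolume}.
#' @param region region name, or \code{"boundary"} for the watershed
#'   lines (the membrane contour).
#' @export
labelCoordinates <- function(lv, region = "boundary") {
  code <- .LABEL_LEVELS[[region]]
  if (is.null(code)) stop("unknown region '", region, "'")
  idx <- which(lv@labels == code, arr.ind = TRUE)
  (idx - 0.5) * lv@spacing
}

#' Full segmentation of a two-channel stack
#'
#' Preprocesses (Gaussian smoothing + cubic resampling), runs the
#' marker-based watershed on the membrane channel, computes the
#' half-boundary-corrected cell volumes, extracts the eggshell contour
#' from the eggshell channel (voxels above half the channel maximum) and
#' fits the eggshell ellipsoid by least squares.
#'
#' @param s a raw \code{ImageStack} with channels \code{membrane} and
#'   \code{eggshell}.
#' @param markers 3 x 3 matrix of marker voxel indices *in the
#'   preprocessed (isotropic) stack*, rows AB, P1, exterior.
#' @param sigma,targetSpacing see \code{\link{preprocessStack}}.
#' @return a \code{\linkS4class{SegmentationResult}}.
#' @export
segmentStack <- function(s, markers, sigma = 0.5, targetSpacing = 0.733) {
  iso <- preprocessStack(s, sigma, targetSpacing)
  lv <- watershedSegment(iso, markers)
  vols <- c(AB = regionVolume(lv, "AB"), P1 = regionVolume(lv, "P1"))
  contour <- labelCoordinates(lv, "boundary")
  egg <- iso@channels[["eggshell"]]
  eggC <- matrix(numeric(0), 0, 3)
  ell <- NULL
  if (!is.null(egg)) {
    idx <- which(egg >= 0.5 * max(egg), arr.ind = TRUE)
    eggC <- (idx - 0.5) * targetSpacing
    ell <- tryCatch(fitEllipsoid(eggC), error = function(e) NULL)
  }
  new("SegmentationResult", labels = lv, volumes = vols,
      contour = contour, eggshellContour = eggC, ellipsoid = ell)
}

#' Signed 2D curve depth of a contact trace
#'
#' Maximal perpendicular distance from the endpoint-to-endpoint chord to
#' the contact trace, signed positive when the bulge points from AB
#' toward P1 (i.e. along \code{apAxis}).
#'
#' @param trace n x 2 matrix of contact-trace points in the mid-plane
#'   (micrometres); the first and last rows are the identified endpoints.
#' @param apAxis length-2 direction pointing from AB toward P1
#'   (posterior); need not be normalized.
#' @return signed depth in micrometres.
#' @export
curveDepth2D <- function(trace, apAxis) {
  X <- as.matrix(trace)
  if (nrow(X) < 3) stop("at least 3 trace points required")
  p0 <- X[1, ]; p1 <- X[nrow(X), ]
  chord <- p1 - p0
  len <- sqrt(sum(chord^2))
  if (len == 0) stop("coincident trace endpoints")
  u <- chord / len
  nrm <- c(-u[2], u[1])
  ap <- apAxis / sqrt(sum(apAxis^2))
  if (sum(nrm * ap) < 0) nrm <- -nrm       # normal points toward P1
  s <- sweep(X, 2, p0) %*% nrm
  s[which.max(abs(s))]
}

#' Classify a contact surface as flat or curved
#'
#' The angle formed by one endpoint, the middle point and the other
#' endpoint of the contact is measured; the contact is curved iff this
#' angle is strictly smaller than 160 degrees.
#'
#' @param endpoints 2 x 2 matrix (the two contact endpoints).
#' @param midpoint length-2 middle point of the contact.
#' @param threshold angle threshold in degrees (default 160).
#' @return \code{"curved"} or \code{"flat"}.
#' @export
classifyContact <- function(endpoints, midpoint, threshold = 160) {
  E <- as.matrix(endpoints)
  v1 <- E[1, ] - midpoint
  v2 <- E[2, ] - midpoint
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("coincident points")
  ang <- acos(max(-1, min(1, sum(v1 * v2) / (n1 * n2)))) * 180 / pi
  if (ang < threshold) "curved" else "flat"
}

#' Cell-size symmetry criterion
#'
#' Cells count as symmetric in size when their AP-axis lengths differ by
#' at most 10% (relative to the larger length, boundary inclusive).
#'
#' @param lenAB,lenP1 positive cell lengths along the AP axis
#'   (micrometres).
#' @param tol relative difference threshold (default 0.10).
#' @export
sizeSymmetry <- function(lenAB, lenP1, tol = 0.10) {
  if (lenAB <= 0 || lenP1 <= 0) stop("lengths must be positive")
  abs(lenAB - lenP1) / max(lenAB, lenP1) <= tol + 1e-12
}

#' Normalize cortical intensity traces
#'
#' Background-subtracted mean intensities I_AB(t) and I_P1(t) are
#' normalized, per sample, by the time average of the merged-region mean
#' (the area-weighted mean of the two traces). The normalized merged
#' trace then has time-average 1, making samples comparable despite
#' large inter-sample gain differences.
#'
#' @param IAB,IP1 numeric traces on a common time grid.
#' @param areas length-2 region sizes (weights of the merged mean); may
#'   also be two vectors over time as a 2-column matrix.
#' @param time optional time grid in minutes.
#' @return an \code{\linkS4class{IntensityTrace}}.
#' @export
normalizeIntensity <- function(IAB, IP1, areas, time = seq_along(IAB)) {
  stopifnot(length(IAB) == length(IP1))
  if (is.matrix(areas)) {
    aAB <- areas[, 1]; aP1 <- areas[, 2]
  } else {
    aAB <- areas[1]; aP1 <- areas[2]
  }
  merged <- (aAB * IAB + aP1 * IP1) / (aAB + aP1)
  divisor <- mean(merged)
  if (!is.finite(divisor) || divisor <= 0)
    stop("nonpositive normalization divisor")
  new("IntensityTrace", time = as.numeric(time),
      rawAB = as.numeric(IAB), rawP1 = as.numeric(IP1),
      normAB = as.numeric(IAB / divisor), normP1 = as.numeric(IP1 / divisor),
      divisor = divisor)
}

#' Cytoplasmic flow velocity from a kymograph
#'
#' Least-squares slope of each extracted path line (yolk-granule streak)
#' and the mean over the selected lines.
#'
#' @param k a \code{\linkS4class{Kymograph}} with extracted path lines.
#' @param nLines number of path lines to average (default 3).
#' @return mean velocity in micrometres/second.
#' @export
flowVelocity <- function(k, nLines = 3) {
  stopifnot(is(k, "Kymograph"))
  if (length(k@pathLines) < nLines)
    stop("need at least ", nLines, " path lines, found ", length(k@pathLines))
  slopes <- vapply(k@pathLines[seq_len(nLines)], function(pl)
    unname(coef(lm(x ~ t, data = pl))[2]), numeric(1))
  mean(slopes)
}

#' Fill watershed boundary lines by majority neighbour label
#'
#' Assigns every boundary voxel to the region owning the majority of its
#' face neighbours (ties broken toward the lower label code), iterating
#' until no boundary voxels remain. Used when a strict partition into
#' regions is needed, e.g. for overlap (Dice) scoring against
#' ground-truth digitizations that carry no boundary layer.
#'
#' @param lv a \code{LabelVolume}.
#' @return a \code{LabelVolume} without boundary voxels.
#' @export
fillBoundary <- function(lv) {
  lab <- lv@labels
  d <- dim(lab)
  shifts <- list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  while (any(lab == 0L)) {
    counts <- lapply(c(1L, 2L, 3L), function(code) {
      acc <- array(0L, d)
      for (s in shifts) {
        r <- array(0L, d)
        src <- dst <- list(1:d[1], 1:d[2], 1:d[3])
        for (ax in 1:3) {
          if (s[ax] > 0) { src[[ax]] <- 1:(d[ax]-1); dst[[ax]] <- 2:d[ax] }
          else if (s[ax] < 0) { src[[ax]] <- 2:d[ax]; dst[[ax]] <- 1:(d[ax]-1) }
        }
        r[dst[[1]], dst[[2]], dst[[3]]] <-
          (lab[src[[1]], src[[2]], src[[3]]] == code)
        acc <- acc + r
      }
      acc
    })
    mx <- pmax(counts[[1]], counts[[2]], counts[[3]])
    win <- array(0L, d)
    for (code in 3:1) win[counts[[code]] == mx & mx > 0L] <- code
    fill <- lab == 0L & win > 0L
    if (!any(fill)) break
    lab[fill] <- win[fill]
  }
  new("LabelVolume", labels = lab, spacing = lv@spacing)
}

#' Read and write image stacks as multi-page TIFF
#'
#' Each channel is written as its own 32-bit float multi-page TIFF (one
#' page per z slice, intensities scaled to [0, 1] by the recorded
#' maximum) next to a JSON sidecar holding the voxel spacing, channel
#' names and intensity scales. Requires the suggested \pkg{tiff}
#' package.
#'
#' @param s an \code{ImageStack}.
#' @param basePath path prefix; files are written as
#'   \code{<basePath>_<channel>.tif} plus \code{<basePath>.json}.
#' @name stack-io
#' @export
writeImageStack <- function(s, basePath) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF I/O")
  stopifnot(is(s, "ImageStack"))
  meta <- list(spacing = s@spacing, channels = names(s@channels),
               scale = vapply(s@channels, function(ch) max(ch, 1e-12), 1))
  for (nm in names(s@channels)) {
    ch <- s@channels[[nm]] / meta$scale[[nm]]
    pages <- lapply(seq_len(dim(ch)[3]), function(z) ch[, , z])
    tiff::writeTIFF(pages, sprintf("%s_%s.tif", basePath, nm),
                    bits.per.sample = 32L)
  }
  jsonlite::write_json(meta, paste0(basePath, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(basePath)
}

#' @rdname stack-io
#' @export
readImageStack <- function(basePath) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF I/O")
  meta <- jsonlite::read_json(paste0(basePath, ".json"), simplifyVector = TRUE)
  ch <- lapply(seq_along(meta$channels), function(i) {
    nm <- meta$channels[i]
    pages <- tiff::readTIFF(sprintf("%s_%s.tif", basePath, nm), all = TRUE)
    arr <- simplify2array(pages)
    arr * meta$scale[[i]]
  })
  names(ch) <- meta$channels
  ImageStack(ch, meta$spacing)
}
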