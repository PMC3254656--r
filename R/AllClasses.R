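#' @useDynLib embryoshape, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new validObject is slot setValidity show
#' @importFrom stats rnorm rpois runif lm coef sd setNames
#' @importFrom utils head tail write.csv read.csv
NULL

## patch codes shared by the R and C++ layers
.PATCH_LEVELS <- c(AB_outer = 1L, P1_outer = 2L, contact = 3L)
## label codes of a LabelVolume
.LABEL_LEVELS <- c(boundary = 0L, AB = 1L, P1 = 2L, exterior = 3L)

#' Labeled triangulated surface of the two-cell system
#'
#' A single shared vertex/triangle pool describing the two bodies (AB and
#' P1) of the two-cell embryo model. Each triangle carries a patch label:
#' \code{AB_outer}, \code{P1_outer} or \code{contact}. Contact triangles
#' are stored once, oriented outward from AB (normal pointing into P1);
#' the P1 body references them with the opposite orientation sense, so the
#' contact patch is physically one surface and the two bodies' volumes are
#' consistent. Single-body meshes (all triangles \code{AB_outer}) are
#' supported as a degenerate mode for testing against closed-form Laplace
#' solutions.
#'
#' @slot vertices numeric matrix (n x 3), coordinates in micrometres.
#' @slot triangles integer matrix (m x 3), 1-based vertex indices,
#'   consistently oriented per patch.
#' @slot patch integer vector of length m with values 1 (AB outer),
#'   2 (P1 outer), 3 (contact).
#' @export
setClass("TriSurfaceMesh", representation(
  vertices = "matrix", triangles = "matrix", patch = "integer"))

setValidity("TriSurfaceMesh", function(object) {
  v <- object@vertices; f <- object@triangles; p <- object@patch
  if (ncol(v) != 3) return("vertices must be an n x 3 matrix")
  if (ncol(f) != 3) return("triangles must be an m x 3 matrix")
  if (length(p) != nrow(f)) return("patch must have one label per triangle")
  if (!all(p %in% .PATCH_LEVELS)) return("unknown patch code")
  if (nrow(f) && (min(f) < 1 || max(f) > nrow(v)))
    return("triangle indices out of range")
  if (any(!is.finite(v))) return("non-finite vertex coordinates")
  for (body in bodiesPresent(object)) {
    chk <- cpp_check_closed(bodyTriangles(object, body) - 1L)
    if (!chk[["closed"]]) return(sprintf("body %s is not closed", body))
    if (!chk[["oriented"]]) return(sprintf("body %s is not consistently oriented", body))
  }
  TRUE
})

#' Ellipsoidal eggshell
#'
#' @slot center numeric length-3 center (micrometres).
#' @slot axes numeric length-3 semi-axes a >= b >= c (micrometres).
#' @slot orientation 3 x 3 proper rotation; column i is the direction of
#'   semi-axis i in world coordinates (column 1 = major axis).
#' @export
setClass("Ellipsoid", representation(
  center = "numeric", axes = "numeric", orientation = "matrix"))

setValidity("Ellipsoid", function(object) {
  if (length(object@center) != 3) return("center must have length 3")
  a <- object@axes
  if (length(a) != 3 || any(a <= 0)) return("semi-axes must be 3 positive numbers")
  if (a[1] < a[2] || a[2] < a[3]) return("semi-axes must satisfy a >= b >= c")
  R <- object@orientation
  if (!all(dim(R) == c(3, 3))) return("orientation must be 3 x 3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-8) return("orientation must be orthonormal")
  if (det(R) < 0) return("orientation must be a proper rotation (det +1)")
  TRUE
})

#' Surface tension parameters
#'
#' The three relative cortical tensions of the model. \code{gammaP1} is
#' the unit of tension and is fixed at 1 by convention. The contact can
#' neither detach nor engulf when the triangle inequality
#' \code{|gammaAB - gammaP1| <= gammaCnt <= gammaAB + gammaP1} holds;
#' \code{checkTensionValidity} tests it.
#'
#' @slot gammaAB,gammaP1,gammaCnt strictly positive tensions
#'   (dimensionless, relative to gammaP1).
#' @export
setClass("TensionParams", representation(
  gammaAB = "numeric", gammaP1 = "numeric", gammaCnt = "numeric"))

setValidity("TensionParams", function(object) {
  g <- c(object@gammaAB, object@gammaP1, object@gammaCnt)
  if (length(g) != 3 || any(!is.finite(g)) || any(g <= 0))
    return("all tensions must be finite and strictly positive")
  TRUE
})

#' Minimized equilibrium shape
#'
#' Result of \code{\link{minimizeShape}}: the relaxed mesh together with
#' the total surface energy, the two bodies' pressures (volume-constraint
#' multipliers, exterior pressure = 0, units tension/micrometre), the
#' target volumes, the relative volume residuals and convergence
#' diagnostics.
#'
#' @export
setClass("EquilibriumShape", representation(
  mesh = "TriSurfaceMesh", tensions = "TensionParams",
  energy = "numeric", pressures = "numeric",
  targetVolumes = "numeric", volumeResiduals = "numeric",
  converged = "logical", iterations = "integer",
  energyTrace = "numeric", ellipsoid = "ANY"))

setValidity("EquilibriumShape", function(object) {
  if (!is.null(object@ellipsoid) && !is(object@ellipsoid, "Ellipsoid"))
    return("ellipsoid must be NULL or an Ellipsoid")
  if (any(abs(object@volumeResiduals) >= 1e-4, na.rm = TRUE))
    return("volume residuals exceed 1e-4 at convergence")
  TRUE
})

#' Tension grid specification
#'
#' Grid over which \code{gammaAB} and \code{gammaCnt} are searched with
#' \code{gammaP1} fixed at 1. The default grid (0.2 to 10.0 in steps of
#' 0.2) contains 514 combinations after the contact-stability inequality
#' is applied. Grid membership is handled through integer indices
#' (gamma = min + k * step) so that the inequality comparisons at the
#' grid endpoints are immune to floating-point drift.
#'
#' @export
setClass("GridSpec", representation(
  min = "numeric", max = "numeric", step = "numeric"),
  prototype(min = 0.2, max = 10, step = 0.2))

setValidity("GridSpec", function(object) {
  if (object@min <= 0) return("min must be positive")
  if (object@step <= 0) return("step must be positive")
  if (object@max < object@min) return("max must be >= min")
  TRUE
})

#' Tension grid-search result
#'
#' @slot table data.frame with one row per valid grid combination:
#'   gamma_ab, gamma_cnt, rmse_um, pressure_ratio, depth_um, converged.
#' @slot best row index of the smallest-RMSE combination.
#' @slot rotation,translation the ICP transform of the best combination.
#' @export
setClass("FitResult", representation(
  table = "data.frame", best = "integer",
  rotation = "matrix", translation = "numeric", target = "character"))

#' Multi-channel image stack
#'
#' @slot channels named list of 3D numeric arrays (e.g. membrane,
#'   eggshell); all channels share dimensions.
#' @slot spacing numeric length-3 voxel spacing in micrometres (x, y, z).
#' @export
setClass("ImageStack", representation(channels = "list", spacing = "numeric"))

setValidity("ImageStack", function(object) {
  if (length(object@spacing) != 3 || any(object@spacing <= 0))
    return("spacing must be 3 positive numbers")
  if (!length(object@channels)) return("at least one channel required")
  d <- dim(object@channels[[1]])
  for (ch in object@channels) {
    if (length(dim(ch)) != 3) return("channels must be 3D arrays")
    if (!all(dim(ch) == d)) return("channels must share dimensions")
    if (any(!is.finite(ch)) || any(ch < -1e-9)) return("intensities must be finite and nonnegative")
  }
  TRUE
})

#' Labeled voxel volume
#'
#' Codes: 0 = boundary, 1 = AB, 2 = P1, 3 = exterior.
#' @slot labels integer 3D array.
#' @slot spacing isotropic voxel spacing in micrometres.
#' @export
setClass("LabelVolume", representation(labels = "array", spacing = "numeric"))

setValidity("LabelVolume", function(object) {
  if (length(dim(object@labels)) != 3) return("labels must be a 3D array")
  if (!all(object@labels %in% .LABEL_LEVELS)) return("unknown label code")
  if (length(object@spacing) != 1 || object@spacing <= 0)
    return("spacing must be a single positive number")
  TRUE
})

#' Segmentation result
#' @export
setClass("SegmentationResult", representation(
  labels = "LabelVolume", volumes = "numeric",
  contour = "matrix", eggshellContour = "matrix", ellipsoid = "ANY"))

#' Cortical intensity traces
#' @export
setClass("IntensityTrace", representation(
  time = "numeric", rawAB = "numeric", rawP1 = "numeric",
  normAB = "numeric", normP1 = "numeric", divisor = "numeric"))

#' Kymograph with extracted path lines
#'
#' @slot image numeric matrix, position (rows, micrometres) by time
#'   (columns, seconds); may have zero extent when only path lines exist.
#' @slot pathLines list of data.frames with columns \code{t} (s) and
#'   \code{x} (micrometres), each time-monotone.
#' @export
setClass("Kymograph", representation(
  image = "matrix", pathLines = "list", dt = "numeric", dx = "numeric"))

setValidity("Kymograph", function(object) {
  for (pl in object@pathLines) {
    if (!all(c("t", "x") %in% names(pl))) return("path lines need columns t and x")
    if (is.unsorted(pl$t, strictly = TRUE)) return("path lines must be time-monotone")
  }
  TRUE
})

#' Synthetic-data configuration
#'
#' Defaults emulate the imaging geometry of the real experiment: an
#' eggshell of roughly 50 x 30 x 30 micrometres, an AB volume fraction
#' drawn uniformly from 0.55-0.60 (AB is reproducibly the larger
#' blastomere), cells filling 95% of the shell, confocal-like anisotropic
#' voxels of 0.244 x 0.244 x 0.733 micrometres, and kymographs imaged at
#' 100-ms frame intervals.
#'
#' @export
setClass("SynthConfig", representation(
  seed = "integer", shellAxes = "numeric", shellJitter = "numeric",
  abFractionRange = "numeric", packing = "numeric",
  tensions = "TensionParams", voxelSpacing = "numeric",
  psfSigma = "numeric", photonScale = "numeric", readNoise = "numeric",
  kymoDt = "numeric", kymoNoise = "numeric", kymoLines = "integer",
  traceNoise = "numeric"))

setValidity("SynthConfig", function(object) {
  if (any(object@abFractionRange <= 0) || any(object@abFractionRange >= 1))
    return("abFractionRange must lie in (0,1)")
  if (object@packing <= 0 || object@packing >= 1) return("packing must lie in (0,1)")
  if (any(object@voxelSpacing <= 0)) return("voxel spacings must be positive")
  TRUE
})
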