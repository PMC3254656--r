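#' @include AllClasses.R
NULL

#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))
#' @export
setGeneric("triangles", function(x) standardGeneric("triangles"))
#' @export
setGeneric("patchLabels", function(x) standardGeneric("patchLabels"))
#' @export
setGeneric("surfaceArea", function(mesh, label) standardGeneric("surfaceArea"))
#' @export
setGeneric("enclosedVolume", function(mesh, body) standardGeneric("enclosedVolume"))
#' @export
setGeneric("subdivideMesh", function(mesh) standardGeneric("subdivideMesh"))
#' @export
setGeneric("tensions", function(x) standardGeneric("tensions"))
#' @export
setGeneric("pressures", function(x) standardGeneric("pressures"))
#' @export
setGeneric("energy", function(x) standardGeneric("energy"))

#' Accessors for mesh slots
#' @param x a \code{TriSurfaceMesh} or object containing one.
#' @return \code{vertices}: n x 3 matrix; \code{triangles}: m x 3 integer
#'   matrix; \code{patchLabels}: factor of patch names per triangle.
#' @export
setMethod("vertices", "TriSurfaceMesh", function(x) x@vertices)
#' @rdname vertices-TriSurfaceMesh-method
#' @export
setMethod("triangles", "TriSurfaceMesh", function(x) x@triangles)
#' @rdname vertices-TriSurfaceMesh-method
#' @export
setMethod("patchLabels", "TriSurfaceMesh", function(x)
  factor(names(.PATCH_LEVELS)[x@patch], levels = names(.PATCH_LEVELS)))

#' @export
setMethod("vertices", "EquilibriumShape", function(x) x@mesh@vertices)
#' @export
setMethod("tensions", "EquilibriumShape", function(x) x@tensions)
#' @export
setMethod("pressures", "EquilibriumShape", function(x) x@pressures)
#' @export
setMethod("energy", "EquilibriumShape", function(x) x@energy)

#' Extract the mesh of an equilibrium shape
#' @param x an \code{EquilibriumShape}.
#' @export
equilibriumMesh <- function(x) {
  stopifnot(is(x, "EquilibriumShape"))
  x@mesh
}

## ---- internal body helpers ----

## which bodies have bounding triangles
bodiesPresent <- function(mesh) {
  p <- mesh@patch
  out <- character(0)
  if (any(p == 1L) || any(p == 3L)) out <- c(out, "AB")
  if (any(p == 2L) || any(p == 3L)) out <- c(out, "P1")
  out
}

## triangle rows bounding one body, oriented outward from that body
bodyTriangles <- function(mesh, body) {
  p <- mesh@patch
  f <- mesh@triangles
  if (body == "AB") {
    rbind(f[p == 1L, , drop = FALSE], f[p == 3L, , drop = FALSE])
  } else if (body == "P1") {
    cnt <- f[p == 3L, , drop = FALSE]
    rbind(f[p == 2L, , drop = FALSE], cnt[, c(1, 3, 2), drop = FALSE])
  } else {
    stop("unknown body '", body, "' (use \"AB\" or \"P1\")")
  }
}

setMethod("show", "TriSurfaceMesh", function(object) {
  tab <- table(patchLabels(object))
  cat("TriSurfaceMesh:", nrow(object@vertices), "vertices,",
      nrow(object@triangles), "triangles\n")
  cat("  patches:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
})

setMethod("show", "Ellipsoid", function(object) {
  cat(sprintf("Ellipsoid: semi-axes (%.3g, %.3g, %.3g) um, center (%.3g, %.3g, %.3g)\n",
              object@axes[1], object@axes[2], object@axes[3],
              object@center[1], object@center[2], object@center[3]))
})

setMethod("show", "TensionParams", function(object) {
  cat(sprintf("TensionParams: gammaAB=%.3g gammaP1=%.3g gammaCnt=%.3g (valid: %s)\n",
              object@gammaAB, object@gammaP1, object@gammaCnt,
              checkTensionValidity(object)))
})

setMethod("show", "EquilibriumShape", function(object) {
  cat("EquilibriumShape\n")
  cat(sprintf("  energy: %.6g (tension um^2), converged: %s after %d accepted steps\n",
              object@energy, object@converged, object@iterations))
  cat(sprintf("  pressures: P_AB=%.5g P_P1=%.5g (tension/um)\n",
              object@pressures[["AB"]], object@pressures[["P1"]]))
  cat(sprintf("  volume residuals: %.3g / %.3g\n",
              object@volumeResiduals[1], object@volumeResiduals[2]))
})

setMethod("show", "FitResult", function(object) {
  b <- object@table[object@best, ]
  cat("FitResult:", nrow(object@table), "grid combinations\n")
  cat(sprintf("  best: gamma_ab=%.2f gamma_cnt=%.2f RMSE=%.4g um\n",
              b$gamma_ab, b$gamma_cnt, b$rmse_um))
})

setMethod("show", "LabelVolume", function(object) {
  tab <- table(factor(object@labels, levels = .LABEL_LEVELS,
                      labels = names(.LABEL_LEVELS)))
  cat("LabelVolume", paste(dim(object@labels), collapse = " x "),
      sprintf("@ %.3g um\n", object@spacing))
  cat(" ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
})

setMethod("show", "ImageStack", function(object) {
  cat("ImageStack", paste(dim(object@channels[[1]]), collapse = " x "),
      "voxels; channels:", paste(names(object@channels), collapse = ", "), "\n")
  cat(sprintf("  spacing: (%.3g, %.3g, %.3g) um\n",
              object@spacing[1], object@spacing[2], object@spacing[3]))
})
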