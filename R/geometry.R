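#' @include AllGenerics.R
NULL

#' Construct a labeled triangulated surface mesh
#'
#' @param vertices numeric n x 3 matrix of coordinates (micrometres).
#' @param triangles integer m x 3 matrix of 1-based vertex indices.
#' @param patch per-triangle labels: either integer codes (1 = AB outer,
#'   2 = P1 outer, 3 = contact) or the names \code{"AB_outer"},
#'   \code{"P1_outer"}, \code{"contact"}.
#' @return a validated \code{\linkS4class{TriSurfaceMesh}}.
#' @export
TriSurfaceMesh <- function(vertices, triangles, patch) {
  if (is.character(patch) || is.factor(patch)) {
    patch <- .PATCH_LEVELS[as.character(patch)]
    if (any(is.na(patch))) stop("unknown patch label")
  }
  new("TriSurfaceMesh", vertices = as.matrix(vertices),
      triangles = matrix(as.integer(as.matrix(triangles)), ncol = 3),
      patch = as.integer(patch))
}

#' Construct an ellipsoid
#'
#' Semi-axes are sorted into decreasing order (a >= b >= c) with the
#' orientation columns permuted to match; the rotation is made proper.
#'
#' @param center numeric length 3 (micrometres).
#' @param axes numeric length 3, strictly positive semi-axes.
#' @param orientation 3 x 3 rotation, column i = axis-i direction.
#' @export
Ellipsoid <- function(center = c(0, 0, 0), axes, orientation = diag(3)) {
  ord <- order(axes, decreasing = TRUE)
  axes <- axes[ord]
  orientation <- orientation[, ord, drop = FALSE]
  if (det(orientation) < 0) orientation[, 3] <- -orientation[, 3]
  new("Ellipsoid", center = as.numeric(center), axes = as.numeric(axes),
      orientation = orientation)
}

#' Ellipsoid volume
#' @param e an \code{Ellipsoid}.
#' @export
ellipsoidVolume <- function(e) 4 / 3 * pi * prod(e@axes)

## world <-> ellipsoid frame
.toLocal <- function(X, e) sweep(X, 2, e@center) %*% e@orientation
.toWorld <- function(X, e) sweep(X %*% t(e@orientation), 2, e@center, "+")

#' Patch surface area
#'
#' Sum of triangle areas of one patch of the mesh.
#'
#' @param mesh a \code{TriSurfaceMesh}.
#' @param label one of \code{"AB_outer"}, \code{"P1_outer"},
#'   \code{"contact"}.
#' @return area in square micrometres (0 for an empty patch).
#' @export
setMethod("surfaceArea", "TriSurfaceMesh", function(mesh, label) {
  if (!label %in% names(.PATCH_LEVELS)) stop("unknown patch label '", label, "'")
  A <- cpp_patch_areas(mesh@vertices, mesh@triangles - 1L, mesh@patch)
  A[.PATCH_LEVELS[[label]]]
})

#' Enclosed body volume
#'
#' Signed divergence-theorem volume of one body's closed bounding surface
#' (its outer patch plus the contact patch), returned positive for the
#' outward orientation the mesh stores.
#'
#' @param mesh a \code{TriSurfaceMesh}.
#' @param body \code{"AB"} or \code{"P1"}.
#' @return volume in cubic micrometres.
#' @export
setMethod("enclosedVolume", "TriSurfaceMesh", function(mesh, body) {
  if (!body %in% bodiesPresent(mesh)) stop("body '", body, "' absent from mesh")
  f <- bodyTriangles(mesh, body)
  chk <- cpp_check_closed(f - 1L)
  if (!chk[["closed"]]) stop("body '", body, "' is not closed")
  v <- cpp_body_volumes(mesh@vertices, f - 1L, rep(1L, nrow(f)))
  v[1]
})

#' Midpoint (1-to-4) triangle subdivision
#'
#' Splits each triangle at its edge midpoints; shared edges (including
#' contact/outer boundaries) are split once so the mesh stays conforming.
#' Patch labels are inherited. Geometry is unchanged, so polyhedral
#' volumes and planar patch areas are preserved exactly.
#'
#' @param mesh a \code{TriSurfaceMesh}.
#' @export
setMethod("subdivideMesh", "TriSurfaceMesh", function(mesh) {
  V <- mesh@vertices
  F <- mesh@triangles
  e1 <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- paste(pmin(e1[, 1], e1[, 2]), pmax(e1[, 1], e1[, 2]))
  uk <- unique(key)
  mid_id <- match(key, uk) + nrow(V)
  ue <- e1[!duplicated(key), , drop = FALSE]
  mids <- (V[ue[, 1], , drop = FALSE] + V[ue[, 2], , drop = FALSE]) / 2
  m <- nrow(F)
  mab <- mid_id[seq_len(m)]
  mbc <- mid_id[m + seq_len(m)]
  mca <- mid_id[2 * m + seq_len(m)]
  Fnew <- rbind(
    cbind(F[, 1], mab, mca),
    cbind(mab, F[, 2], mbc),
    cbind(mca, mbc, F[, 3]),
    cbind(mab, mbc, mca))
  TriSurfaceMesh(rbind(V, mids), Fnew, rep(mesh@patch, 4))
})

#' Triangulated sphere (subdivided icosahedron)
#'
#' @param radius sphere radius (micrometres).
#' @param subdivisions rounds of midpoint subdivision (each round
#'   projects the new vertices back onto the sphere).
#' @param center sphere center.
#' @param patch patch label for all triangles (default \code{"AB_outer"},
#'   the single-body testing mode).
#' @export
icosphereMesh <- function(radius = 1, subdivisions = 3, center = c(0, 0, 0),
                          patch = "AB_outer") {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(1 + phi^2)
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  mesh <- TriSurfaceMesh(V, F, rep(.PATCH_LEVELS[[patch]], nrow(F)))
  for (i in seq_len(subdivisions)) {
    mesh <- subdivideMesh(mesh)
    v <- mesh@vertices
    v <- v / sqrt(rowSums(v^2))
    mesh@vertices <- v
  }
  mesh@vertices <- sweep(mesh@vertices * radius, 2, center, "+")
  mesh
}

#' Least-squares ellipsoid fit to a 3D point set
#'
#' Algebraic least squares on the general quadric (the smallest singular
#' vector of the design matrix), with ellipsoid-ness checked on the
#' quadratic form, followed by eigendecomposition into center, semi-axes
#' and orientation. Points are weighted uniformly.
#'
#' @param points numeric n x 3 matrix, n >= 9 and non-degenerate.
#' @return an \code{Ellipsoid}; \code{attr(, "residual")} holds the RMS
#'   relative radial residual of the fit (0 for exact samples).
#' @export
fitEllipsoid <- function(points) {
  X <- as.matrix(points)
  if (nrow(X) < 9) stop("at least 9 points are required")
  x <- X[, 1]; y <- X[, 2]; z <- X[, 3]
  D <- cbind(x^2, y^2, z^2, 2 * x * y, 2 * x * z, 2 * y * z,
             2 * x, 2 * y, 2 * z, 1)
  ## scale for conditioning
  s <- max(abs(X - matrix(colMeans(X), nrow(X), 3, byrow = TRUE)))
  if (s <= 0) stop("degenerate point set")
  Ds <- cbind(D[, 1:6] / s^2, D[, 7:9] / s, D[, 10])
  sv <- svd(Ds, nu = 0)
  if (sv$d[1] <= 0 || sv$d[10] / sv$d[1] > 1e-7 * nrow(X)) {
    ## no exact quadric through the points: still take the LS solution
  }
  th <- sv$v[, 10]
  th <- c(th[1:6] / s^2, th[7:9] / s, th[10])
  A <- matrix(c(th[1], th[4], th[5],
                th[4], th[2], th[6],
                th[5], th[6], th[3]), 3, 3)
  g <- th[7:9]
  eg <- eigen(A, symmetric = TRUE)
  if (any(abs(eg$values) < 1e-12 * max(abs(eg$values))) ||
      length(unique(sign(eg$values))) != 1)
    stop("degenerate or non-ellipsoidal point set")
  ctr <- tryCatch(as.numeric(solve(A, -g)),
                  error = function(err) stop("degenerate or non-ellipsoidal point set"))
  k <- as.numeric(t(ctr) %*% A %*% ctr) - th[10]
  ev <- eg$values / k
  if (any(ev <= 0)) stop("degenerate or non-ellipsoidal point set")
  axes <- 1 / sqrt(ev)
  e <- Ellipsoid(center = ctr, axes = axes, orientation = eg$vectors)
  L <- .toLocal(X, e)
  q <- sqrt(pmax(0, (L[, 1] / e@axes[1])^2 + (L[, 2] / e@axes[2])^2 +
                    (L[, 3] / e@axes[3])^2))
  attr(e, "residual") <- sqrt(mean((q - 1)^2))
  e
}

#' Nearest point(s) on an ellipsoid surface
#'
#' Solves the Lagrange condition of the closest-point problem in the
#' ellipsoid frame by safeguarded 1D root finding (bracketing plus
#' Newton), then maps back to world coordinates. Both interior and
#' exterior points are projected onto the surface; one-sided confinement
#' logic (leave interior points alone) is the caller's responsibility.
#'
#' @param point numeric length 3, or an n x 3 matrix of points.
#' @param e an \code{Ellipsoid}.
#' @export
projectToEllipsoid <- function(point, e) {
  X <- if (is.null(dim(point))) matrix(point, 1, 3) else as.matrix(point)
  P <- .toWorld(cpp_project_ellipsoid(.toLocal(X, e), e@axes), e)
  if (is.null(dim(point))) as.numeric(P) else P
}

#' Is a point inside the ellipsoid?
#' @param point numeric length 3 or n x 3 matrix.
#' @param e an \code{Ellipsoid}.
#' @export
insideEllipsoid <- function(point, e) {
  X <- if (is.null(dim(point))) matrix(point, 1, 3) else as.matrix(point)
  L <- .toLocal(X, e)
  rowSums(sweep(L, 2, e@axes, "/")^2) <= 1
}

## ---- least-squares plane and sphere (used by depth and cap checks) ----

#' Least-squares plane through points
#' @param points n x 3 matrix.
#' @return list with \code{point} (centroid) and unit \code{normal}.
#' @export
fitPlane <- function(points) {
  X <- as.matrix(points)
  ctr <- colMeans(X)
  sv <- svd(sweep(X, 2, ctr), nu = 0)
  list(point = ctr, normal = sv$v[, 3])
}

#' Algebraic least-squares sphere fit
#' @param points n x 3 matrix.
#' @return list with \code{center}, \code{radius} and RMS radial
#'   \code{residual}.
#' @export
fitSphere <- function(points) {
  X <- as.matrix(points)
  b <- rowSums(X^2)
  A <- cbind(2 * X, 1)
  th <- qr.solve(A, b)
  ctr <- th[1:3]
  r <- sqrt(th[4] + sum(ctr^2))
  res <- sqrt(rowSums(sweep(X, 2, ctr)^2)) - r
  list(center = as.numeric(ctr), radius = r, residual = sqrt(mean(res^2)))
}

## ---- mesh and ellipsoid I/O ----

#' Read and write labeled meshes (OFF / PLY)
#'
#' ASCII formats with the patch label carried per face: OFF stores it as
#' a trailing face color-index column, PLY as a face property
#' \code{int patch}.
#'
#' @param mesh a \code{TriSurfaceMesh}.
#' @param path file path.
#' @name mesh-io
#' @export
writeMeshOFF <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh@vertices), nrow(mesh@triangles)), con)
  writeLines(apply(mesh@vertices, 1, function(v)
    sprintf("%.10g %.10g %.10g", v[1], v[2], v[3])), con)
  writeLines(sprintf("3 %d %d %d %d", mesh@triangles[, 1] - 1L,
                     mesh@triangles[, 2] - 1L, mesh@triangles[, 3] - 1L,
                     mesh@patch), con)
  invisible(path)
}

#' @rdname mesh-io
#' @export
readMeshOFF <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln)) & !startsWith(trimws(ln), "#")]
  if (toupper(trimws(ln[1])) != "OFF") stop("not an OFF file")
  cnt <- scan(text = ln[2], quiet = TRUE)
  nv <- cnt[1]; nf <- cnt[2]
  V <- matrix(scan(text = ln[3:(2 + nv)], quiet = TRUE), ncol = 3, byrow = TRUE)
  fl <- matrix(scan(text = ln[(3 + nv):(2 + nv + nf)], quiet = TRUE),
               nrow = nf, byrow = TRUE)
  if (any(fl[, 1] != 3)) stop("only triangle faces are supported")
  patch <- if (ncol(fl) >= 5) as.integer(fl[, 5]) else rep(1L, nf)
  TriSurfaceMesh(V, fl[, 2:4] + 1L, patch)
}

#' @rdname mesh-io
#' @export
writeMeshPLY <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh@vertices)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(mesh@triangles)),
               "property list uchar int vertex_indices",
               "property int patch", "end_header"), con)
  writeLines(apply(mesh@vertices, 1, function(v)
    sprintf("%.10g %.10g %.10g", v[1], v[2], v[3])), con)
  writeLines(sprintf("3 %d %d %d %d", mesh@triangles[, 1] - 1L,
                     mesh@triangles[, 2] - 1L, mesh@triangles[, 3] - 1L,
                     mesh@patch), con)
  invisible(path)
}

#' @rdname mesh-io
#' @export
readMeshPLY <- function(path) {
  ln <- readLines(path)
  hend <- which(trimws(ln) == "end_header")[1]
  if (is.na(hend)) stop("not an ascii PLY file")
  hdr <- ln[1:hend]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", hdr, value = TRUE)))
  V <- matrix(scan(text = ln[hend + seq_len(nv)], quiet = TRUE), ncol = 3, byrow = TRUE)
  fl <- matrix(scan(text = ln[hend + nv + seq_len(nf)], quiet = TRUE),
               nrow = nf, byrow = TRUE)
  patch <- if (ncol(fl) >= 5) as.integer(fl[, 5]) else rep(1L, nf)
  TriSurfaceMesh(V, fl[, 2:4] + 1L, patch)
}

#' Ellipsoid JSON sidecar
#' @param e an \code{Ellipsoid}.
#' @param path file path.
#' @name ellipsoid-io
#' @export
writeEllipsoidJSON <- function(e, path) {
  jsonlite::write_json(list(center = e@center, axes = e@axes,
                            orientation = e@orientation),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname ellipsoid-io
#' @export
readEllipsoidJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  Ellipsoid(center = obj$center, axes = obj$axes,
            orientation = matrix(unlist(obj$orientation), 3, 3))
}
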