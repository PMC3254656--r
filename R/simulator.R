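#' @include geometry.R
NULL

#' Construct surface tension parameters
#'
#' @param gammaAB tension of the AB outer cortex (relative to gammaP1).
#' @param gammaCnt tension of the contact surface.
#' @param gammaP1 tension of the P1 outer cortex; fixed at 1 by
#'   convention (the unit of tension is arbitrary in the model).
#' @export
TensionParams <- function(gammaAB = 1, gammaCnt = 1, gammaP1 = 1) {
  new("TensionParams", gammaAB = gammaAB, gammaP1 = gammaP1, gammaCnt = gammaCnt)
}

.gammaVec <- function(t) c(t@gammaAB, t@gammaP1, t@gammaCnt)

#' Contact-stability triangle inequality
#'
#' The two cells neither detach nor engulf one another only when
#' \code{|gammaAB - gammaP1| <= gammaCnt <= gammaAB + gammaP1}. Grid
#' combinations violating this are excluded from the tension search.
#'
#' @param t a \code{TensionParams} (all tensions positive).
#' @return \code{TRUE} iff the inequality holds (endpoints inclusive,
#'   robust to floating error).
#' @export
checkTensionValidity <- function(t) {
  eps <- 1e-9
  (abs(t@gammaAB - t@gammaP1) <= t@gammaCnt + eps) &&
    (t@gammaCnt <= t@gammaAB + t@gammaP1 + eps)
}

#' Total surface energy of a mesh
#'
#' The model's mechanical energy: the sum over the three surfaces of
#' surface tension times surface area,
#' E = gammaAB * A_AB + gammaP1 * A_P1 + gammaCnt * A_cnt.
#'
#' @param mesh a \code{TriSurfaceMesh}.
#' @param t a \code{TensionParams}.
#' @return energy in tension * square micrometres.
#' @export
totalEnergy <- function(mesh, t) {
  A <- cpp_patch_areas(mesh@vertices, mesh@triangles - 1L, mesh@patch)
  sum(.gammaVec(t) * A)
}

## side length of the initial cubes: 20 voxels of 0.733 um
.INIT_CUBE_SIDE <- 14.7

#' Initial two-cube configuration
#'
#' Two cubes of side 14.7 micrometres sharing one face (the contact
#' patch), centered in the eggshell and aligned along its major axis,
#' with AB on the anterior side (the negative major-axis direction). If
#' the cubes would poke out of the shell they are pre-scaled uniformly
#' to fit; an error is raised if the *target* volumes cannot fit in the
#' shell at all.
#'
#' @param e an \code{Ellipsoid}, or \code{NULL} for an unconfined
#'   configuration centered at the origin and aligned with x.
#' @param volAB,volP1 target volumes (used only for the feasibility
#'   check; the initial cube volumes are equal by construction).
#' @param side cube side length (micrometres).
#' @return a \code{TriSurfaceMesh} with both bodies closed.
#' @export
initConfiguration <- function(e = NULL, volAB = NULL, volP1 = NULL,
                              side = .INIT_CUBE_SIDE) {
  if (!is.null(e) && !is.null(volAB) && !is.null(volP1)) {
    if (volAB + volP1 > 0.999 * ellipsoidVolume(e))
      stop("target volumes (", volAB + volP1,
           " um^3) do not fit inside the eggshell (",
           signif(ellipsoidVolume(e), 6), " um^3)")
  }
  L <- side
  h <- side / 2
  corner <- rbind(c(-h, -h), c(h, -h), c(h, h), c(-h, h))   # CCW seen from +x
  plane <- function(x0) cbind(x0, corner)
  V <- rbind(plane(-L), plane(0), plane(L))
  if (!is.null(e)) {
    q <- rowSums(sweep(V, 2, e@axes, "/")^2)
    if (max(q) > 1) V <- V * 0.98 / sqrt(max(q))
  }
  idx <- function(k, j) 4L * (k - 1L) + j
  quads <- list()
  pat <- integer(0)
  addQuad <- function(q, p) {
    quads[[length(quads) + 1L]] <<- q
    pat[length(pat) + 1L] <<- p
  }
  addQuad(c(idx(1, 1), idx(1, 4), idx(1, 3), idx(1, 2)), 1L)   # AB end, normal -x
  for (j in 1:4) {
    jn <- if (j == 4) 1L else j + 1L
    addQuad(c(idx(1, j), idx(1, jn), idx(2, jn), idx(2, j)), 1L)  # AB sides
  }
  addQuad(c(idx(2, 1), idx(2, 2), idx(2, 3), idx(2, 4)), 3L)   # contact, normal +x
  for (j in 1:4) {
    jn <- if (j == 4) 1L else j + 1L
    addQuad(c(idx(2, j), idx(2, jn), idx(3, jn), idx(3, j)), 2L)  # P1 sides
  }
  addQuad(c(idx(3, 1), idx(3, 2), idx(3, 3), idx(3, 4)), 2L)   # P1 end, normal +x
  F <- do.call(rbind, lapply(quads, function(q)
    rbind(q[c(1, 2, 3)], q[c(1, 3, 4)])))
  patch <- rep(pat, each = 2L)
  if (!is.null(e)) V <- .toWorld(V, e)
  TriSurfaceMesh(V, F, patch)
}

## default minimizer options
.minimizeOpts <- function(opts = list()) {
  def <- list(subdivisions = 3L, maxit = 4000L, tolE = 1e-9, window = 50L,
              stepFrac = 0.25, smoothPasses = 2L, smoothOmega = 0.5,
              flipPasses = 20L, finalPolish = TRUE)
  def[names(opts)] <- opts
  def
}

#' Minimize the surface energy of the two-cell system
#'
#' Gradient descent with backtracking (Armijo) line search on the total
#' surface energy, under both volume constraints (enforced after every
#' trial step by the minimal-norm vertex correction along the two volume
#' gradients) and the one-sided eggshell constraint (vertices outside
#' the ellipsoid are projected back and lose the outward component of
#' their descent direction while in contact). The schedule follows the
#' coarse-to-fine protocol: minimize, then three rounds of triangle
#' subdivision each followed by minimization. Between phases the mesh is
#' improved by equiangulating edge flips and purely tangential vertex
#' smoothing (triple-line vertices move only along the triple line), both
#' shape-neutral, after which the volumes are restored.
#'
#' @param t a \code{TensionParams}; must satisfy
#'   \code{\link{checkTensionValidity}}.
#' @param volAB,volP1 target body volumes (cubic micrometres). Set
#'   \code{volP1 = NULL} for the degenerate single-body mode used to test
#'   the Laplace closed form.
#' @param e an \code{Ellipsoid} eggshell, or \code{NULL} for a free
#'   (unconfined) double bubble.
#' @param opts list of solver options: \code{subdivisions} (default 3),
#'   \code{maxit} per phase (4000), \code{tolE} relative energy decrease
#'   over \code{window} iterations (1e-9 over 50), \code{stepFrac}
#'   maximal step as a fraction of the mean edge length (0.25),
#'   \code{smoothPasses}, \code{smoothOmega}, \code{flipPasses}.
#' @return an \code{\linkS4class{EquilibriumShape}}.
#' @export
minimizeShape <- function(t, volAB, volP1, e = NULL, opts = list()) {
  stopifnot(is(t, "TensionParams"))
  if (!checkTensionValidity(t))
    stop("tension parameters violate the contact-stability inequality")
  o <- .minimizeOpts(opts)
  hasP1 <- !is.null(volP1) && !is.na(volP1) && volP1 > 0
  if (volAB <= 0) stop("volAB must be positive")
  if (hasP1) {
    mesh <- initConfiguration(e, volAB, volP1)
  } else {
    mesh <- initConfiguration(e, volAB, volAB, side = max(volAB, 1)^(1 / 3))
    keep <- mesh@patch == 1L | mesh@patch == 3L
    f <- mesh@triangles[keep, , drop = FALSE]
    used <- sort(unique(as.integer(f)))
    remap <- integer(nrow(mesh@vertices))
    remap[used] <- seq_along(used)
    mesh <- TriSurfaceMesh(mesh@vertices[used, , drop = FALSE],
                           matrix(remap[f], ncol = 3), rep(1L, nrow(f)))
  }
  gamma <- .gammaVec(t)
  axes <- NULL
  V <- mesh@vertices
  if (!is.null(e)) {
    V <- .toLocal(V, e)
    axes <- e@axes
  }
  F0 <- mesh@triangles
  patch <- mesh@patch
  vp <- if (hasP1) volP1 else 0
  res <- NULL
  for (phase in 0:o$subdivisions) {
    if (phase > 0) {
      m <- TriSurfaceMesh(V, F0, patch)
      m <- subdivideMesh(m)
      V <- m@vertices; F0 <- m@triangles; patch <- m@patch
    }
    res <- cpp_minimize(V, F0 - 1L, patch, gamma, volAB, vp, hasP1, axes,
                        as.integer(o$maxit), o$tolE, as.integer(o$window),
                        o$stepFrac)
    V <- res$vertices
    if (phase < o$subdivisions || o$finalPolish) {
      fl <- cpp_equiangulate(V, F0 - 1L, patch, as.integer(o$flipPasses))
      F0 <- matrix(as.integer(fl$triangles), ncol = 3) + 1L
      V <- cpp_smooth(V, F0 - 1L, patch, axes, o$smoothOmega,
                      as.integer(o$smoothPasses))
      rv <- cpp_restore_volumes(V, F0 - 1L, patch, volAB, vp, hasP1, axes,
                                cap = 1, maxit = 400L)
      V <- rv$vertices
      if (o$finalPolish && phase == o$subdivisions) {
        res <- cpp_minimize(V, F0 - 1L, patch, gamma, volAB, vp, hasP1, axes,
                            as.integer(o$maxit), o$tolE, as.integer(o$window),
                            o$stepFrac)
        V <- res$vertices
      }
    }
  }
  if (!res$converged)
    stop("energy minimization did not converge within the iteration budget ",
         "(", res$iterations, " accepted steps, energy ", signif(res$energy, 8),
         ", volume residuals ",
         paste(signif((res$volumes - c(volAB, vp))[1:(1 + hasP1)] / c(volAB, max(vp, 1))[1:(1 + hasP1)], 3), collapse = "/"),
         ")")
  Vw <- if (!is.null(e)) .toWorld(V, e) else V
  meshOut <- TriSurfaceMesh(Vw, F0, patch)
  resid <- c(AB = (res$volumes[1] - volAB) / volAB,
             P1 = if (hasP1) (res$volumes[2] - volP1) / volP1 else NA_real_)
  new("EquilibriumShape", mesh = meshOut, tensions = t,
      energy = res$energy,
      pressures = c(AB = res$pressures[1], P1 = res$pressures[2]),
      targetVolumes = c(AB = volAB, P1 = if (hasP1) volP1 else NA_real_),
      volumeResiduals = resid,
      converged = res$converged, iterations = as.integer(res$iterations),
      energyTrace = as.numeric(res$energyTrace),
      ellipsoid = e)
}

#' Body pressures of an equilibrium shape
#'
#' Pressures relative to the exterior (exterior = 0), computed as the
#' volume-constraint sensitivities dE/dV at the optimum: the
#' least-squares Lagrange multipliers of the stationarity condition
#' grad E = P_AB grad V_AB + P_P1 grad V_P1, restricted to vertices not
#' pressed against the eggshell. By Laplace's law these equal twice the
#' tension times the mean curvature of the free surface patches.
#'
#' @param shape a converged \code{EquilibriumShape}.
#' @param t optional \code{TensionParams} overriding the stored ones.
#' @return named numeric c(AB =, P1 =) in tension/micrometre.
#' @export
bodyPressures <- function(shape, t = NULL) {
  stopifnot(is(shape, "EquilibriumShape"))
  if (!shape@converged) stop("shape is not converged")
  if (is.null(t)) t <- shape@tensions
  mesh <- shape@mesh
  e <- shape@ellipsoid
  V <- mesh@vertices
  axes <- NULL
  if (!is.null(e)) {
    V <- .toLocal(V, e)
    axes <- e@axes
  }
  hasP1 <- "P1" %in% bodiesPresent(mesh)
  p <- cpp_pressures(V, mesh@triangles - 1L, mesh@patch, .gammaVec(t), hasP1, axes)
  c(AB = p[1], P1 = p[2])
}

#' Finite-difference pressures (independent oracle)
#'
#' Re-minimizes the energy at perturbed target volumes V(1 +/- delta)
#' and returns the central difference dE/dV per body. Slow; intended as
#' a cross-check of \code{\link{bodyPressures}}.
#'
#' @param t,volAB,volP1,e,opts as in \code{\link{minimizeShape}}.
#' @param delta relative volume perturbation (default 0.005).
#' @export
finiteDifferencePressures <- function(t, volAB, volP1, e = NULL,
                                      delta = 0.005, opts = list()) {
  ep <- function(vA, vP) minimizeShape(t, vA, vP, e, opts)@energy
  pA <- (ep(volAB * (1 + delta), volP1) - ep(volAB * (1 - delta), volP1)) /
    (2 * delta * volAB)
  pP <- (ep(volAB, volP1 * (1 + delta)) - ep(volAB, volP1 * (1 - delta))) /
    (2 * delta * volP1)
  c(AB = pA, P1 = pP)
}

## vertices on the contact patch boundary ring (the triple line):
## ring edges are contact-triangle edges with exactly one incident
## contact triangle
.tripleLineVertices <- function(mesh) {
  f <- mesh@triangles[mesh@patch == 3L, , drop = FALSE]
  if (!nrow(f)) stop("contact patch is empty")
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  ring <- e[key %in% names(which(table(key) == 1L)), , drop = FALSE]
  sort(unique(as.integer(ring)))
}

#' Signed curve depth of the contact surface (mesh-based)
#'
#' Fits a plane to the contact patch's boundary ring (the triple line)
#' and returns the signed maximal deviation of the contact surface from
#' that plane. The sign follows the experimental convention: positive
#' when the contact bulges from AB toward P1, negative for the opposite
#' direction.
#'
#' @param shape an \code{EquilibriumShape} or \code{TriSurfaceMesh} with
#'   a nonempty contact patch.
#' @return depth in micrometres (signed).
#' @export
meshCurveDepth <- function(shape) {
  mesh <- if (is(shape, "EquilibriumShape")) shape@mesh else shape
  ring <- .tripleLineVertices(mesh)
  if (length(ring) < 3) stop("degenerate contact boundary (fewer than 3 vertices)")
  pl <- fitPlane(mesh@vertices[ring, , drop = FALSE])
  ## orient the plane normal toward P1 using the mean contact normal
  f <- mesh@triangles[mesh@patch == 3L, , drop = FALSE]
  a <- mesh@vertices[f[, 1], , drop = FALSE]
  b <- mesh@vertices[f[, 2], , drop = FALSE]
  c3 <- mesh@vertices[f[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c3 - a
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  toP1 <- colSums(nrm)
  n <- pl$normal
  if (sum(n * toP1) < 0) n <- -n
  cv <- sort(unique(as.integer(f)))
  s <- sweep(mesh@vertices[cv, , drop = FALSE], 2, pl$point) %*% n
  s[which.max(abs(s))]
}

#' Film meeting angles along the triple line
#'
#' For each triple-line edge, measures the angles between the three
#' films (AB outer, P1 outer, contact) in the plane perpendicular to the
#' edge. At mechanical equilibrium with equal tensions the three angles
#' are 120 degrees (the classical double-bubble condition).
#'
#' @param mesh a \code{TriSurfaceMesh} (or \code{EquilibriumShape}).
#' @return data.frame with one row per triple-line edge and columns
#'   \code{ab_cnt}, \code{p1_cnt}, \code{ab_p1} (degrees).
#' @export
tripleLineAngles <- function(mesh) {
  if (is(mesh, "EquilibriumShape")) mesh <- mesh@mesh
  f <- mesh@triangles
  p <- mesh@patch
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  tri <- rep(seq_len(nrow(f)), 3)
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  sp <- split(seq_along(key), key)
  out <- list()
  for (idx in sp) {
    pats <- p[tri[idx]]
    if (length(unique(pats)) < 3) next
    v1 <- e[idx[1], 1]; v2 <- e[idx[1], 2]
    a <- mesh@vertices[v1, ]; b <- mesh@vertices[v2, ]
    ed <- (b - a) / sqrt(sum((b - a)^2))
    mid <- (a + b) / 2
    dirs <- matrix(NA_real_, 3, 3)
    for (k in seq_along(idx)) {
      tr <- f[tri[idx[k]], ]
      cen <- colMeans(mesh@vertices[tr, , drop = FALSE])
      d <- cen - mid
      d <- d - sum(d * ed) * ed
      dirs[pats[k], ] <- d / sqrt(sum(d^2))
    }
    ang <- function(i, j) {
      acos(max(-1, min(1, sum(dirs[i, ] * dirs[j, ])))) * 180 / pi
    }
    out[[length(out) + 1L]] <- data.frame(
      ab_cnt = ang(1, 3), p1_cnt = ang(2, 3), ab_p1 = ang(1, 2))
  }
  do.call(rbind, out)
}
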