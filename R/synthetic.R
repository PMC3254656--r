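#' @include imaging.R
NULL

## run code with a temporary RNG seed, restoring global state afterwards
.withSeed <- function(seed, fun) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fun()
}

#' Construct a synthetic-data configuration
#'
#' All generators are pure functions of the configuration (including its
#' seed): the same configuration reproduces identical outputs bit for
#' bit.
#'
#' @param seed integer RNG seed.
#' @param shellAxes nominal eggshell semi-axes in micrometres (default
#'   25 x 15 x 15, i.e. a 50 x 30 x 30 shell).
#' @param shellJitter relative uniform jitter applied per axis (0.1).
#' @param abFractionRange range of the AB volume fraction (AB is always
#'   the larger blastomere; default uniform in 0.55-0.60).
#' @param packing fraction of the shell volume occupied by the two cells
#'   (0.95).
#' @param tensions ground-truth \code{TensionParams} for simulated
#'   target shapes (default the fitted heterogeneous values 3.4 / 3.4).
#' @param voxelSpacing confocal-like anisotropic voxel spacing in
#'   micrometres (0.244, 0.244, 0.733).
#' @param psfSigma anisotropic PSF sigma in micrometres.
#' @param photonScale expected photon count at unit intensity (Poisson
#'   noise scale).
#' @param readNoise Gaussian read noise s.d. in counts.
#' @param kymoDt kymograph frame interval in seconds (0.1).
#' @param kymoNoise positional noise s.d. of path lines (micrometres).
#' @param kymoLines number of path lines.
#' @param traceNoise additive noise s.d. of intensity traces.
#' @export
SynthConfig <- function(seed = 1L, shellAxes = c(25, 15, 15),
                        shellJitter = 0.1, abFractionRange = c(0.55, 0.60),
                        packing = 0.95,
                        tensions = TensionParams(gammaAB = 3.4, gammaCnt = 3.4),
                        voxelSpacing = c(0.244, 0.244, 0.733),
                        psfSigma = c(0.25, 0.25, 0.75),
                        photonScale = 100, readNoise = 2,
                        kymoDt = 0.1, kymoNoise = 0.3, kymoLines = 3L,
                        traceNoise = 0.02) {
  new("SynthConfig", seed = as.integer(seed), shellAxes = shellAxes,
      shellJitter = shellJitter, abFractionRange = abFractionRange,
      packing = packing, tensions = tensions, voxelSpacing = voxelSpacing,
      psfSigma = psfSigma, photonScale = photonScale, readNoise = readNoise,
      kymoDt = kymoDt, kymoNoise = kymoNoise, kymoLines = as.integer(kymoLines),
      traceNoise = traceNoise)
}

#' Generate an embryo-like geometry
#'
#' Jitters the nominal eggshell semi-axes, samples the AB volume
#' fraction, and splits \code{packing} times the shell volume between
#' the two cells.
#'
#' @param cfg a \code{SynthConfig}.
#' @param jitter apply the configured shell jitter (set \code{FALSE} for
#'   the nominal geometry).
#' @return list with \code{ellipsoid}, \code{volAB}, \code{volP1},
#'   \code{abFraction}.
#' @export
generateEmbryoGeometry <- function(cfg, jitter = TRUE) {
  stopifnot(is(cfg, "SynthConfig"))
  .withSeed(cfg@seed, function() {
    ax <- cfg@shellAxes
    if (jitter) ax <- ax * (1 + runif(3, -cfg@shellJitter, cfg@shellJitter))
    e <- Ellipsoid(center = c(0, 0, 0), axes = sort(ax, decreasing = TRUE))
    f <- runif(1, cfg@abFractionRange[1], cfg@abFractionRange[2])
    vtot <- cfg@packing * ellipsoidVolume(e)
    list(ellipsoid = e, volAB = f * vtot, volP1 = (1 - f) * vtot,
         abFraction = f)
  })
}

## deterministic area-weighted point samples on a mesh surface:
## each triangle is split into n^2 barycentric subtriangles (n chosen so
## the sample spacing is below h) and their centroids are returned with
## weight area / n^2
.sampleMeshPoints <- function(V, F, h) {
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c3 <- V[F[, 3], , drop = FALSE]
  emax <- pmax(sqrt(rowSums((b - a)^2)), sqrt(rowSums((c3 - b)^2)),
               sqrt(rowSums((a - c3)^2)))
  e1 <- b - a; e2 <- c3 - a
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area <- 0.5 * sqrt(rowSums(nrm^2))
  n <- pmax(1L, ceiling(emax / h))
  pts <- list(); wts <- list()
  for (nv in sort(unique(n))) {
    tri <- which(n == nv)
    ## barycentric centroids of the nv^2 subtriangles
    bar <- list()
    for (i in seq_len(nv)) {
      for (j in seq_len(nv - i + 1)) {
        u0 <- (i - 1) / nv; v0 <- (j - 1) / nv
        bar[[length(bar) + 1L]] <- c(u0 + 1 / (3 * nv), v0 + 1 / (3 * nv))
        if (i + j <= nv)
          bar[[length(bar) + 1L]] <- c(u0 + 2 / (3 * nv), v0 + 2 / (3 * nv))
      }
    }
    B <- do.call(rbind, bar)
    for (k in seq_len(nrow(B))) {
      u <- B[k, 1]; v <- B[k, 2]
      pts[[length(pts) + 1L]] <- a[tri, , drop = FALSE] +
        u * e1[tri, , drop = FALSE] + v * e2[tri, , drop = FALSE]
      wts[[length(wts) + 1L]] <- area[tri] / nv^2
    }
  }
  list(points = do.call(rbind, pts), weights = unlist(wts))
}

## bin weighted points into a voxel grid (points already origin-shifted)
.binPoints <- function(pts, wts, dims, spacing) {
  idx <- pmin(pmax(floor(sweep(pts, 2, spacing, "/")) + 1, 1),
              matrix(dims, nrow(pts), 3, byrow = TRUE))
  lin <- (idx[, 1] - 1) + dims[1] * ((idx[, 2] - 1) + dims[2] * (idx[, 3] - 1))
  acc <- rowsum(wts, lin)
  out <- numeric(prod(dims))
  out[as.integer(rownames(acc)) + 1] <- acc
  array(out, dims)
}

#' Render a confocal-like two-channel stack of an equilibrium shape
#'
#' The membrane channel places fluorescence on the cell surfaces
#' (area-weighted surface samples binned into voxels), convolves with an
#' anisotropic Gaussian PSF and, when \code{noise} is \code{TRUE}, adds
#' Poisson photon noise at \code{photonScale} plus Gaussian read noise.
#' The eggshell channel renders the ellipsoid surface the same way.
#' Voxels are anisotropic per the configuration; voxel centers sit at
#' \code{origin + (index - 0.5) * spacing} where \code{origin} (the
#' world coordinate of the lower stack corner) is returned in
#' \code{attr(, "origin")}.
#'
#' @param shape a converged \code{EquilibriumShape} inside \code{e}.
#' @param e the eggshell \code{Ellipsoid}.
#' @param cfg a \code{SynthConfig}.
#' @param noise add Poisson-Gaussian noise (default TRUE).
#' @param margin padding around the shell in micrometres.
#' @return an \code{ImageStack} with channels \code{membrane} and
#'   \code{eggshell}.
#' @export
renderStack <- function(shape, e, cfg, noise = TRUE, margin = 2) {
  stopifnot(is(shape, "EquilibriumShape"), is(e, "Ellipsoid"))
  mesh <- shape@mesh
  if (!all(insideEllipsoid(mesh@vertices, e) |
           rowSums(.toLocal(mesh@vertices, e)^2 /
                   matrix(e@axes^2, nrow(mesh@vertices), 3, byrow = TRUE)) < 1 + 1e-6))
    stop("shape extends outside the eggshell")
  sp <- cfg@voxelSpacing
  half <- e@axes + margin
  origin <- e@center - half
  dims <- pmax(2L, as.integer(ceiling(2 * half / sp)))
  h <- min(sp) / 2
  ms <- .sampleMeshPoints(mesh@vertices, mesh@triangles, h)
  mem <- .binPoints(sweep(ms$points, 2, origin), ms$weights, dims, sp)
  shell <- icosphereMesh(1, 4)
  sv <- .toWorld(sweep(shell@vertices, 2, e@axes, "*"), e)
  ss <- .sampleMeshPoints(sv, shell@triangles, h)
  egg <- .binPoints(sweep(ss$points, 2, origin), ss$weights, dims, sp)
  blur <- function(img) {
    b <- .gaussBlur3D(img, cfg@psfSigma / sp)
    b / max(b)
  }
  mem <- blur(mem); egg <- blur(egg)
  if (noise) {
    .withSeed(cfg@seed + 7L, function() {
      n <- length(mem)
      mem <<- array(rpois(n, cfg@photonScale * mem) +
                      rnorm(n, 0, cfg@readNoise), dims)
      egg <<- array(rpois(n, cfg@photonScale * egg) +
                      rnorm(n, 0, cfg@readNoise), dims)
    })
    mem <- pmax(mem, 0); egg <- pmax(egg, 0)
  } else {
    mem <- cfg@photonScale * mem
    egg <- cfg@photonScale * egg
  }
  out <- ImageStack(list(membrane = mem, eggshell = egg), sp)
  attr(out, "origin") <- origin
  out
}

#' Ground-truth label volume of an equilibrium shape
#'
#' Digitizes the two bodies on a voxel grid by ray-casting point-in-mesh
#' tests at the voxel centers (no boundary layer: every voxel is AB, P1
#' or exterior). Used as the reference for segmentation overlap (Dice)
#' scores.
#'
#' @param shape an \code{EquilibriumShape}.
#' @param dims integer length-3 grid dimensions.
#' @param spacing voxel spacing (isotropic, micrometres).
#' @param origin world coordinate of the lower grid corner.
#' @return a \code{LabelVolume}.
#' @export
groundTruthLabels <- function(shape, dims, spacing, origin = c(0, 0, 0)) {
  mesh <- shape@mesh
  g <- expand.grid(x = (seq_len(dims[1]) - 0.5) * spacing + origin[1],
                   y = (seq_len(dims[2]) - 0.5) * spacing + origin[2],
                   z = (seq_len(dims[3]) - 0.5) * spacing + origin[3])
  pts <- as.matrix(g)
  fa <- bodyTriangles(mesh, "AB")
  fp <- bodyTriangles(mesh, "P1")
  inA <- cpp_points_inside(mesh@vertices, fa - 1L, pts)
  inP <- cpp_points_inside(mesh@vertices, fp - 1L, pts)
  lab <- array(3L, dims)
  lab[array(inA, dims)] <- 1L
  lab[array(inP & !inA, dims)] <- 2L
  new("LabelVolume", labels = lab, spacing = spacing)
}

#' Dice overlap coefficient of two masks
#' @param a,b logical arrays of equal dimension.
#' @export
diceCoefficient <- function(a, b) {
  2 * sum(a & b) / (sum(a) + sum(b))
}

#' Synthetic kymograph with labeled path lines
#'
#' Path lines of yolk granules moving at a common velocity, sampled at
#' the configured frame interval with Gaussian positional noise.
#'
#' @param velocity true flow velocity in micrometres/second.
#' @param cfg a \code{SynthConfig}.
#' @param duration kymograph duration in seconds.
#' @return a \code{\linkS4class{Kymograph}}.
#' @export
synthKymograph <- function(velocity, cfg, duration = 5) {
  stopifnot(is.finite(velocity))
  .withSeed(cfg@seed + 11L, function() {
    tt <- seq(0, duration, by = cfg@kymoDt)
    lines <- lapply(seq_len(cfg@kymoLines), function(i) {
      x0 <- 2 * i
      data.frame(t = tt, x = x0 + velocity * tt +
                   if (cfg@kymoNoise > 0) rnorm(length(tt), 0, cfg@kymoNoise)
                   else 0)
    })
    new("Kymograph", image = matrix(numeric(0), 0, 0), pathLines = lines,
        dt = cfg@kymoDt, dx = NA_real_)
  })
}

#' Synthetic cortical intensity traces
#'
#' Emulates the observed pattern: the AB cortical signal ramps up during
#' the two-cell stage while the P1 signal stays flat and lower. The
#' underlying normalized traces are constructed so the merged-region
#' time average is exactly 1 and the normalized AB value at
#' \code{rampAt} minutes equals \code{rampTo}; raw traces are the
#' normalized truth times a per-sample gain, plus additive noise.
#'
#' @param cfg a \code{SynthConfig}.
#' @param duration trace duration in minutes.
#' @param dt sampling interval in minutes.
#' @param p1Level constant normalized P1 level (default 0.80).
#' @param rampTo,rampAt normalized AB level (1.25) at time
#'   \code{rampAt} (8 min).
#' @param gain multiplicative raw gain (sampled lognormally when NA).
#' @param noise add the configured additive noise.
#' @return list with \code{time}, \code{rawAB}, \code{rawP1},
#'   \code{areas}, and the ground-truth \code{normAB}, \code{normP1}.
#' @export
synthIntensityTraces <- function(cfg, duration = 10, dt = 0.5,
                                 p1Level = 0.80, rampTo = 1.25, rampAt = 8,
                                 gain = NA, noise = TRUE) {
  .withSeed(cfg@seed + 13L, function() {
    tt <- seq(0, duration, by = dt)
    w <- mean(cfg@abFractionRange)
    base <- (1 - (1 - w) * p1Level) / w
    s <- (rampTo - base) / (rampAt - mean(tt))
    nAB <- base + s * (tt - mean(tt))
    nP1 <- rep(p1Level, length(tt))
    if (is.na(gain)) gain <- exp(rnorm(1, log(500), 0.4))
    eps <- if (noise) cfg@traceNoise else 0
    rawAB <- gain * (nAB + rnorm(length(tt), 0, eps))
    rawP1 <- gain * (nP1 + rnorm(length(tt), 0, eps))
    list(time = tt, rawAB = rawAB, rawP1 = rawP1,
         areas = c(AB = w, P1 = 1 - w), normAB = nAB, normP1 = nP1,
         gain = gain)
  })
}

## ---- analytic double bubble (equal tensions, no eggshell) ----

.capVol <- function(R, h) pi * h^2 * (3 * R - h) / 3

## geometry of the standard double bubble for outer radii R1 >= R2:
## centers D apart with D^2 = R1^2 + R2^2 - R1 R2 (120-degree films),
## contact film radius R12 = R1 R2 / (R1 - R2) bulging into bubble 1
.doubleBubbleGeom <- function(R1, R2) {
  D <- sqrt(R1^2 + R2^2 - R1 * R2)
  xc <- (D^2 + R1^2 - R2^2) / (2 * D)
  rho <- sqrt(max(R1^2 - xc^2, 0))
  A1 <- .capVol(R1, R1 + xc)
  A2 <- .capVol(R2, R2 + D - xc)
  if (abs(R1 - R2) < 1e-12 * R1) {
    lens <- 0; R12 <- Inf; x12 <- NA
  } else {
    R12 <- R1 * R2 / (R1 - R2)
    x12 <- xc + sqrt(max(R12^2 - rho^2, 0))
    lens <- .capVol(R12, R12 - (x12 - xc))
  }
  list(D = D, xc = xc, rho = rho, R12 = R12, x12 = x12,
       V1 = A1 - lens, V2 = A2 + lens)
}

#' Analytic equal-tension double bubble mesh
#'
#' Constructs the classical double bubble (two spherical caps plus a
#' spherical-cap contact film meeting at 120 degrees along the triple
#' circle) for given body volumes, independently of the energy
#' minimizer. The larger body is AB; the contact film bulges into it
#' (the smaller bubble has the higher Laplace pressure).
#'
#' @param volAB,volP1 body volumes in cubic micrometres
#'   (\code{volAB >= volP1}).
#' @param n angular resolution (default 48 azimuthal steps).
#' @return list with \code{mesh} (a \code{TriSurfaceMesh}),
#'   \code{R1}, \code{R2}, \code{Rcnt} (film radii, \code{Inf} for a
#'   planar film) and the center distance \code{D}.
#' @export
doubleBubbleMesh <- function(volAB, volP1, n = 48) {
  stopifnot(volAB >= volP1, volP1 > 0)
  ratio <- function(q) {
    g <- .doubleBubbleGeom(1, q)
    g$V2 / g$V1
  }
  tgt <- volP1 / volAB
  q <- if (abs(tgt - 1) < 1e-12) 1 else
    stats::uniroot(function(q) ratio(q) - tgt, c(1e-3, 1), tol = 1e-12)$root
  g1 <- .doubleBubbleGeom(1, q)
  s <- (volAB / g1$V1)^(1 / 3)
  R1 <- s; R2 <- q * s
  g <- .doubleBubbleGeom(R1, R2)

  phi <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  ring <- cbind(g$xc, g$rho * cos(phi), g$rho * sin(phi))
  Vp <- ring                     # shared triple-circle vertices: 1..n
  Fs <- list(); Ps <- integer(0)
  addTri <- function(i, j, k, p) {
    Fs[[length(Fs) + 1L]] <<- c(i, j, k)
    Ps[length(Ps) + 1L] <<- p
  }
  ## lat-long cap about the x axis from the ring angle to the pole.
  ## ctr/R: sphere; thetaRing: ring colatitude from the pole direction
  ## pole = +1 -> cap opens toward +x, outward normal away from ctr
  addCap <- function(ctr, R, pole, patchCode, flip, nthet = NULL) {
    ringTheta <- acos(pmin(pmax((g$xc - ctr) / R * pole, -1), 1))
    if (is.null(nthet)) nthet <- max(3L, ceiling(ringTheta / (pi / n)))
    prev <- 1:n                  # start from shared ring
    for (k in seq_len(nthet)) {
      th <- ringTheta * (1 - k / nthet)
      if (k < nthet) {
        pts <- cbind(ctr + pole * R * cos(th),
                     R * sin(th) * cos(phi), R * sin(th) * sin(phi))
        id0 <- nrow(Vp)
        Vp <<- rbind(Vp, pts)
        cur <- id0 + 1:n
      } else {
        Vp <<- rbind(Vp, c(ctr + pole * R, 0, 0))
        cur <- rep(nrow(Vp), n)
      }
      for (j in 1:n) {
        jn <- if (j == n) 1L else j + 1L
        if (k < nthet) {
          if (flip) {
            addTri(prev[j], cur[j], prev[jn], patchCode)
            addTri(prev[jn], cur[j], cur[jn], patchCode)
          } else {
            addTri(prev[j], prev[jn], cur[j], patchCode)
            addTri(prev[jn], cur[jn], cur[j], patchCode)
          }
        } else {
          if (flip) addTri(prev[j], cur[j], prev[jn], patchCode)
          else addTri(prev[j], prev[jn], cur[j], patchCode)
        }
      }
      prev <- cur
    }
  }
  ## AB outer: sphere at 0 radius R1, pole toward -x
  addCap(0, R1, -1, 1L, flip = FALSE)
  ## P1 outer: sphere at D radius R2, pole toward +x
  addCap(g$D, R2, +1, 2L, flip = TRUE)
  ## contact film
  if (is.finite(g$R12)) {
    addCap(g$x12, g$R12, -1, 3L, flip = TRUE)
  } else {
    ## planar disc: concentric rings down to the axis
    nr <- max(2L, ceiling(n / 8))
    prev <- 1:n
    for (k in seq_len(nr)) {
      r <- g$rho * (1 - k / nr)
      if (k < nr) {
        id0 <- nrow(Vp)
        Vp <- rbind(Vp, cbind(g$xc, r * cos(phi), r * sin(phi)))
        cur <- id0 + 1:n
      } else {
        Vp <- rbind(Vp, c(g$xc, 0, 0))
        cur <- rep(nrow(Vp), n)
      }
      for (j in 1:n) {
        jn <- if (j == n) 1L else j + 1L
        if (k < nr) {
          addTri(prev[j], cur[j], prev[jn], 3L)
          addTri(prev[jn], cur[j], cur[jn], 3L)
        } else addTri(prev[j], cur[j], prev[jn], 3L)
      }
      prev <- cur
    }
  }
  F <- do.call(rbind, Fs)
  P <- Ps
  ## repair per-patch orientation on the raw matrices (each patch is
  ## internally consistent by construction; only its global sense can be
  ## wrong) so that both bodies close with positive volume
  flipCode <- function(F, code) {
    F[P == code, c(2, 3)] <- F[P == code, c(3, 2)]
    F
  }
  mesh <- NULL
  for (mask in 0:7) {
    F2 <- F
    if (bitwAnd(mask, 1L)) F2 <- flipCode(F2, 1L)
    if (bitwAnd(mask, 2L)) F2 <- flipCode(F2, 2L)
    if (bitwAnd(mask, 4L)) F2 <- flipCode(F2, 3L)
    fa <- rbind(F2[P == 1L, , drop = FALSE], F2[P == 3L, , drop = FALSE])
    cnt <- F2[P == 3L, , drop = FALSE]
    fp <- rbind(F2[P == 2L, , drop = FALSE], cnt[, c(1, 3, 2), drop = FALSE])
    if (!cpp_check_closed(fa - 1L)[["oriented"]]) next
    if (!cpp_check_closed(fp - 1L)[["oriented"]]) next
    vol <- cpp_body_volumes(Vp, F2 - 1L, P)
    if (vol[1] > 0 && vol[2] > 0) {
      mesh <- TriSurfaceMesh(Vp, F2, P)
      break
    }
  }
  if (is.null(mesh)) stop("internal error: could not orient double-bubble mesh")
  list(mesh = mesh, R1 = R1, R2 = R2, Rcnt = g$R12, D = g$D, rho = g$rho)
}
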