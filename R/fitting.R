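#' @include simulator.R
NULL

#' Construct a tension grid specification
#'
#' @param min,max,step grid of tension values \code{min + k * step}
#'   (dimensionless). Defaults reproduce the full search grid: 0.2 to
#'   10.0 in increments of 0.2.
#' @export
GridSpec <- function(min = 0.2, max = 10, step = 0.2) {
  new("GridSpec", min = min, max = max, step = step)
}

#' Enumerate the valid tension grid
#'
#' All (gammaAB, gammaCnt) grid pairs with gammaP1 = 1 that satisfy the
#' contact-stability inequality \code{|gammaAB - 1| <= gammaCnt <=
#' gammaAB + 1} (endpoints inclusive), in lexicographic order. Grid
#' membership uses integer indices so the boundary comparisons are exact;
#' the default grid yields 514 combinations.
#'
#' @param g a \code{GridSpec} for \code{gamma_ab}.
#' @param gCnt optional separate \code{GridSpec} for \code{gamma_cnt}
#'   (defaults to the same grid).
#' @return data.frame with columns \code{gamma_ab}, \code{gamma_cnt}.
#' @export
validTensionGrid <- function(g = GridSpec(), gCnt = g) {
  stopifnot(is(g, "GridSpec"), is(gCnt, "GridSpec"))
  gridVals <- function(x) x@min + (0:floor((x@max - x@min) / x@step + 1e-9)) * x@step
  va <- gridVals(g)
  vc <- gridVals(gCnt)
  eps <- min(g@step, gCnt@step) * 1e-6
  out <- vector("list", length(va))
  for (i in seq_along(va)) {
    ga <- va[i]
    ok <- (abs(ga - 1) <= vc + eps) & (vc <= ga + 1 + eps)
    out[[i]] <- if (any(ok)) data.frame(gamma_ab = ga, gamma_cnt = vc[ok])
  }
  do.call(rbind, out)
}

#' Iterative closest point rigid registration
#'
#' Rigid (rotation + translation, no scaling) alignment of a source
#' point set onto a target set by alternating nearest-neighbour
#' correspondence (directional: source points to target points) and the
#' least-squares orthogonal Procrustes solution. Initialization is
#' centroid alignment followed by principal-axes alignment with the
#' rotation sign ambiguity resolved by RMSE. The RMSE is computed from
#' the remaining distances between corresponding points and is
#' non-increasing across iterations.
#'
#' @param source,target numeric n x 3 matrices, each with at least 3
#'   non-collinear points.
#' @param opts list: \code{maxIter} (default 100), \code{tol} RMSE
#'   improvement threshold in micrometres (1e-6), \code{axesInit}
#'   (TRUE).
#' @return list with \code{rotation} (3 x 3), \code{translation}
#'   (length 3), \code{rmse}, \code{iterations}, \code{aligned} (the
#'   transformed source).
#' @export
icpAlign <- function(source, target, opts = list()) {
  o <- list(maxIter = 100L, tol = 1e-6, axesInit = TRUE)
  o[names(opts)] <- opts
  S <- as.matrix(source); Tg <- as.matrix(target)
  .checkCloud <- function(X, nm) {
    if (nrow(X) < 3) stop(nm, " must contain at least 3 points")
    sv <- svd(sweep(X, 2, colMeans(X)), nu = 0)
    if (sv$d[2] <= 1e-12 * max(sv$d[1], 1)) stop(nm, " points are collinear")
  }
  .checkCloud(S, "source"); .checkCloud(Tg, "target")
  cs <- colMeans(S); ct <- colMeans(Tg)
  rmseOf <- function(R, tr) {
    Sa <- S %*% t(R) + matrix(tr, nrow(S), 3, byrow = TRUE)
    sqrt(mean(cpp_nn(Sa, Tg)$dist^2))
  }
  R <- diag(3); tr <- ct - cs
  if (o$axesInit) {
    es <- eigen(stats::cov(S), symmetric = TRUE)$vectors
    et <- eigen(stats::cov(Tg), symmetric = TRUE)$vectors
    ## candidate set: centroid-only identity plus the four proper
    ## principal-axes alignments (sign ambiguity resolved by RMSE);
    ## the identity candidate anchors near-axisymmetric clouds whose
    ## azimuth the covariance axes cannot pin down
    best <- rmseOf(R, tr)
    for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
      D <- diag(c(s1, s2, s1 * s2))   # proper rotations only
      Rc <- et %*% D %*% t(es)
      if (det(Rc) < 0) Rc <- et %*% (D * c(1, 1, -1)) %*% t(es)
      trc <- ct - as.numeric(Rc %*% cs)
      r <- rmseOf(Rc, trc)
      if (r < best) { best <- r; R <- Rc; tr <- trc }
    }
  }
  rmse <- rmseOf(R, tr)
  iters <- 0L
  repeat {
    Sa <- S %*% t(R) + matrix(tr, nrow(S), 3, byrow = TRUE)
    nn <- cpp_nn(Sa, Tg)
    Y <- Tg[nn$index, , drop = FALSE]
    sy <- colMeans(Y)
    A <- crossprod(sweep(S, 2, cs), sweep(Y, 2, sy))
    sv <- svd(A)
    d <- sign(det(sv$v %*% t(sv$u)))
    Rn <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    trn <- sy - as.numeric(Rn %*% cs)
    rn <- rmseOf(Rn, trn)
    iters <- iters + 1L
    if (rn <= rmse) { R <- Rn; tr <- trn }
    if (rmse - rn < o$tol || iters >= o$maxIter) {
      rmse <- min(rmse, rn)
      break
    }
    rmse <- rn
  }
  Sa <- S %*% t(R) + matrix(tr, nrow(S), 3, byrow = TRUE)
  list(rotation = R, translation = as.numeric(tr),
       rmse = sqrt(mean(cpp_nn(Sa, Tg)$dist^2)),
       iterations = iters, aligned = Sa)
}

#' Precompute equilibrium shapes for a set of grid combinations
#'
#' Runs \code{\link{minimizeShape}} for every row of \code{combos};
#' failures are recorded as NULL with a warning. Useful for scoring
#' several targets (e.g. replicate noisy renderings of one geometry)
#' against one set of model shapes.
#'
#' @param combos data.frame with columns gamma_ab, gamma_cnt (e.g. from
#'   \code{\link{validTensionGrid}}).
#' @param volAB,volP1,e,opts as in \code{\link{minimizeShape}}.
#' @return list of \code{EquilibriumShape} (or NULL) per row.
#' @export
simulateTensionGrid <- function(combos, volAB, volP1, e, opts = list()) {
  lapply(seq_len(nrow(combos)), function(i) {
    tp <- TensionParams(gammaAB = combos$gamma_ab[i],
                        gammaCnt = combos$gamma_cnt[i])
    tryCatch(minimizeShape(tp, volAB, volP1, e, opts),
             error = function(err) {
               warning(sprintf("combination (%.2f, %.2f) failed: %s",
                               combos$gamma_ab[i], combos$gamma_cnt[i],
                               conditionMessage(err)), call. = FALSE)
               NULL
             })
  })
}

#' Fit tension parameters by grid search
#'
#' For every valid combination of the tension grid, minimizes the model
#' shape under the measured volumes and eggshell, rigidly registers the
#' model vertices onto the target membrane-contour points by ICP, and
#' scores the combination by the registration RMSE. The combination with
#' the smallest RMSE is selected.
#'
#' @param targetContour numeric n x 3 matrix of membrane-contour points
#'   (micrometres), e.g. from \code{\link{segmentStack}} or a synthetic
#'   rendering.
#' @param volAB,volP1 measured cell volumes (cubic micrometres).
#' @param e fitted eggshell \code{Ellipsoid}.
#' @param g a \code{GridSpec}.
#' @param opts solver options passed to \code{\link{minimizeShape}}.
#' @param icpOpts options passed to \code{\link{icpAlign}}.
#' @param shapes optional precomputed result of
#'   \code{\link{simulateTensionGrid}} on the same grid.
#' @return a \code{\linkS4class{FitResult}}.
#' @export
fitTensions <- function(targetContour, volAB, volP1, e, g = GridSpec(),
                        gCnt = g, opts = list(), icpOpts = list(),
                        shapes = NULL) {
  combos <- validTensionGrid(g, gCnt)
  if (is.null(shapes)) shapes <- simulateTensionGrid(combos, volAB, volP1, e, opts)
  stopifnot(length(shapes) == nrow(combos))
  tab <- data.frame(gamma_ab = combos$gamma_ab, gamma_cnt = combos$gamma_cnt,
                    rmse_um = NA_real_, pressure_ratio = NA_real_,
                    depth_um = NA_real_, converged = FALSE)
  icps <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    sh <- shapes[[i]]
    if (is.null(sh)) next
    icp <- icpAlign(vertices(sh), targetContour, icpOpts)
    icps[[i]] <- icp
    p <- pressures(sh)
    tab$rmse_um[i] <- icp$rmse
    tab$pressure_ratio[i] <- p[["AB"]] / p[["P1"]]
    tab$depth_um[i] <- meshCurveDepth(sh)
    tab$converged[i] <- TRUE
  }
  if (!any(tab$converged)) stop("all grid combinations failed to converge")
  best <- which(tab$rmse_um == min(tab$rmse_um, na.rm = TRUE))[1]
  new("FitResult", table = tab, best = as.integer(best),
      rotation = icps[[best]]$rotation,
      translation = icps[[best]]$translation,
      target = sprintf("point cloud (%d points)", nrow(as.matrix(targetContour))))
}
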