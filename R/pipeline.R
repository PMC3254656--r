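#' @include synthetic.R fitting.R
NULL

#' Default end-to-end run configuration
#'
#' A small demonstration configuration: generate a synthetic embryo
#' geometry, simulate the ground-truth shape, optionally render and
#' segment a confocal-like stack, then recover the tensions on a coarse
#' grid around the truth.
#'
#' @param seed integer seed routed to every random stage.
#' @export
defaultRunConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    outDir = tempfile("embryoshape_run_"),
    synth = list(shellAxes = c(25, 15, 15), shellJitter = 0.1,
                 abFractionRange = c(0.55, 0.60), packing = 0.95,
                 gammaAB = 3.4, gammaCnt = 3.4),
    render = list(enabled = FALSE, noise = FALSE),
    fit = list(gridMin = 3.0, gridMax = 3.8, gridStep = 0.4),
    simulateOpts = list()
  )
}

#' Validate a run configuration
#'
#' Schema and cross-field checks; violations are reported, not thrown.
#'
#' @param cfg a run configuration list (see
#'   \code{\link{defaultRunConfig}}) or a path to a JSON file.
#' @return character vector of violations (empty when valid).
#' @export
validateConfig <- function(cfg) {
  if (is.character(cfg)) cfg <- jsonlite::read_json(cfg, simplifyVector = TRUE)
  v <- character(0)
  bad <- function(msg) v <<- c(v, msg)
  if (is.null(cfg$seed) || !is.finite(cfg$seed)) bad("seed missing or non-finite")
  s <- cfg$synth
  if (is.null(s)) bad("synth block missing")
  else {
    if (length(s$shellAxes) != 3 || any(s$shellAxes <= 0))
      bad("synth$shellAxes must be 3 positive semi-axes")
    if (!is.null(s$packing) && (s$packing <= 0 || s$packing >= 1))
      bad("synth$packing must lie in (0,1)")
    if (!is.null(s$abFractionRange) &&
        (any(s$abFractionRange <= 0) || any(s$abFractionRange >= 1)))
      bad("synth$abFractionRange must lie in (0,1)")
    if (!is.null(s$gammaAB) && s$gammaAB <= 0) bad("synth$gammaAB must be positive")
    if (!is.null(s$gammaCnt) && s$gammaCnt <= 0) bad("synth$gammaCnt must be positive")
  }
  f <- cfg$fit
  if (!is.null(f)) {
    if (is.null(f$gridStep) || f$gridStep <= 0) bad("fit$gridStep must be positive")
    if (is.null(f$gridMin) || f$gridMin <= 0) bad("fit$gridMin must be positive")
    if (!is.null(f$gridMin) && !is.null(f$gridMax) && !is.null(f$gridStep) &&
        f$gridStep > 0 && f$gridMax < f$gridMin)
      bad("fit$gridMax must be >= fit$gridMin")
  }
  v
}

#' Run the end-to-end pipeline
#'
#' Composes the flow the tension fit follows on real data — geometry,
#' energy minimization, (optionally) rendering and segmentation, and the
#' grid search — on synthetic inputs, writing every stage's outputs plus
#' a provenance manifest to the configured output directory.
#'
#' @param cfg a run configuration (list or JSON path); see
#'   \code{\link{defaultRunConfig}}.
#' @return invisibly, a list with the stage results (\code{geometry},
#'   \code{truth}, \code{fit}, \code{files}).
#' @export
runPipeline <- function(cfg = defaultRunConfig()) {
  if (is.character(cfg)) {
    if (!file.exists(cfg)) stop("config file not found: ", cfg)
    cfg <- jsonlite::read_json(cfg, simplifyVector = TRUE)
  }
  viol <- validateConfig(cfg)
  if (length(viol)) stop("invalid configuration:\n  ", paste(viol, collapse = "\n  "))
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  message("[embryoshape] output: ", cfg$outDir)

  sc <- SynthConfig(seed = cfg$seed, shellAxes = cfg$synth$shellAxes,
                    shellJitter = cfg$synth$shellJitter,
                    abFractionRange = cfg$synth$abFractionRange,
                    packing = cfg$synth$packing,
                    tensions = TensionParams(gammaAB = cfg$synth$gammaAB,
                                             gammaCnt = cfg$synth$gammaCnt))
  geom <- generateEmbryoGeometry(sc)
  writeEllipsoidJSON(geom$ellipsoid, file.path(cfg$outDir, "eggshell.json"))

  message("[embryoshape] simulating ground-truth shape (gammaAB=",
          cfg$synth$gammaAB, ", gammaCnt=", cfg$synth$gammaCnt, ")")
  truth <- minimizeShape(sc@tensions, geom$volAB, geom$volP1,
                         geom$ellipsoid, cfg$simulateOpts)
  writeMeshPLY(truth@mesh, file.path(cfg$outDir, "truth.ply"))

  if (isTRUE(cfg$render$enabled)) {
    message("[embryoshape] rendering + segmenting synthetic stack")
    stk <- renderStack(truth, geom$ellipsoid, sc,
                       noise = isTRUE(cfg$render$noise))
    iso <- preprocessStack(stk)
    d <- dim(iso@channels$membrane)
    origin <- attr(stk, "origin")
    mk <- rbind(AB = .voxelOf(.bodyCentroid(truth, "AB"), origin, 0.733, d),
                P1 = .voxelOf(.bodyCentroid(truth, "P1"), origin, 0.733, d),
                exterior = c(2L, 2L, 2L))
    lv <- watershedSegment(iso, mk)
    target <- sweep(labelCoordinates(lv, "boundary"), 2, -origin, "-")
    volAB <- regionVolume(lv, "AB")
    volP1 <- regionVolume(lv, "P1")
  } else {
    target <- vertices(truth)
    volAB <- geom$volAB
    volP1 <- geom$volP1
  }

  g <- GridSpec(cfg$fit$gridMin, cfg$fit$gridMax, cfg$fit$gridStep)
  message("[embryoshape] grid search over ", nrow(validTensionGrid(g)),
          " combinations")
  fit <- fitTensions(target, volAB, volP1, geom$ellipsoid, g,
                     opts = cfg$simulateOpts)
  fitCsv <- file.path(cfg$outDir, "fit.csv")
  write.csv(fit@table, fitCsv, row.names = FALSE)

  best <- fit@table[fit@best, ]
  report <- list(
    seed = cfg$seed,
    abFraction = geom$abFraction,
    volumes = list(AB = volAB, P1 = volP1),
    truth = list(gammaAB = cfg$synth$gammaAB, gammaCnt = cfg$synth$gammaCnt,
                 energy = truth@energy,
                 pressureRatio = unname(pressures(truth)[["AB"]] /
                                          pressures(truth)[["P1"]]),
                 depth = meshCurveDepth(truth)),
    best = as.list(best))
  jsonlite::write_json(report, file.path(cfg$outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA)

  cfgPath <- file.path(cfg$outDir, "config.json")
  jsonlite::write_json(cfg, cfgPath, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "embryoshape",
    version = as.character(utils::packageVersion("embryoshape")),
    rversion = R.version.string,
    configMD5 = unname(tools::md5sum(cfgPath)),
    seed = cfg$seed,
    files = list.files(cfg$outDir))
  jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(geometry = geom, truth = truth, fit = fit,
                 files = file.path(cfg$outDir, list.files(cfg$outDir))))
}

.bodyCentroid <- function(shape, body) {
  f <- bodyTriangles(shape@mesh, body)
  colMeans(shape@mesh@vertices[unique(as.integer(f)), , drop = FALSE])
}

.voxelOf <- function(pt, origin, spacing, dims) {
  pmin(pmax(as.integer(floor((pt - origin) / spacing)) + 1L, 1L), dims)
}
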