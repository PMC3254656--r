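# Shared fixtures, all built in code. Expensive equilibrium shapes are
# cached per test session.

.fx <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fx[[key]])) assign(key, builder(), envir = .fx)
  .fx[[key]]
}

# closed 12-triangle cube, outward orientation
cubeMesh <- function(side = 1, center = c(0, 0, 0), patch = "AB_outer") {
  h <- side / 2
  V <- as.matrix(expand.grid(x = c(-h, h), y = c(-h, h), z = c(-h, h)))
  V <- sweep(V, 2, center, "+")
  # vertices: 1(---) 2(+--) 3(-+-) 4(++-) 5(--+) 6(+-+) 7(-++) 8(+++)
  F <- rbind(
    c(1, 3, 4), c(1, 4, 2),   # z = -h
    c(5, 6, 8), c(5, 8, 7),   # z = +h
    c(1, 2, 6), c(1, 6, 5),   # y = -h
    c(3, 7, 8), c(3, 8, 4),   # y = +h
    c(1, 5, 7), c(1, 7, 3),   # x = -h
    c(2, 4, 8), c(2, 8, 6))   # x = +h
  TriSurfaceMesh(V, F, rep(patch, 12))
}

# membrane-ridge landscape of a sphere of radius r voxels, with markers
# inside (AB) and outside (exterior)
sphereLandscape <- function(r, sigma = 1) {
  n <- 2L * ceiling(r) + 9L
  ctr <- (n + 1) / 2
  g <- seq_len(n) - ctr
  d <- sqrt(outer(outer(g^2, g^2, "+"), g^2, "+"))
  img <- exp(-(d - r)^2 / (2 * sigma^2))
  markers <- rbind(AB = rep(ctr, 3), exterior = c(1, 1, 1))
  list(img = img, markers = markers, n = n)
}

# nominal embryo-like study geometry: eggshell 25 x 15 x 15 um half-axes,
# cells occupy 95% of the shell, AB fraction 0.58
embryoEllipsoid <- function() Ellipsoid(axes = c(25, 15, 15))
embryoVolumes <- function() {
  vt <- 0.95 * ellipsoidVolume(embryoEllipsoid())
  c(AB = 0.58 * vt, P1 = 0.42 * vt)
}

homoShape <- function(sub = 4) cached(paste0("homo", sub), function() {
  v <- embryoVolumes()
  minimizeShape(TensionParams(1, 1, 1), v[["AB"]], v[["P1"]],
                embryoEllipsoid(), list(subdivisions = sub))
})

hetShape <- function(sub = 4) cached(paste0("het", sub), function() {
  v <- embryoVolumes()
  minimizeShape(TensionParams(gammaAB = 3.4, gammaCnt = 3.4),
                v[["AB"]], v[["P1"]],
                embryoEllipsoid(), list(subdivisions = sub))
})

# a jittered synthetic embryo with its ground-truth equilibrium shape
synthTruth <- function() cached("synthTruth", function() {
  cfg <- SynthConfig(seed = 3)
  geom <- generateEmbryoGeometry(cfg)
  truth <- minimizeShape(cfg@tensions, geom$volAB, geom$volP1, geom$ellipsoid)
  list(cfg = cfg, geom = geom, truth = truth)
})

# segment a rendered stack of `truth`; returns label volume, measured
# volumes, contour in world coordinates, and grid metadata
segmentRendered <- function(truth, geom, cfg, noise) {
  stk <- renderStack(truth, geom$ellipsoid, cfg, noise = noise)
  origin <- attr(stk, "origin")
  iso <- preprocessStack(stk)
  d <- dim(iso@channels$membrane)
  centroid <- function(body) {
    f <- embryoshape:::bodyTriangles(truth@mesh, body)
    colMeans(truth@mesh@vertices[unique(as.integer(f)), , drop = FALSE])
  }
  vox <- function(pt) pmin(pmax(as.integer(floor((pt - origin) / 0.733)) + 1L, 1L), d)
  mk <- rbind(AB = vox(centroid("AB")), P1 = vox(centroid("P1")),
              exterior = c(2L, 2L, 2L))
  lv <- watershedSegment(iso, mk)
  list(lv = lv, iso = iso, origin = origin, dims = d,
       volAB = regionVolume(lv, "AB"), volP1 = regionVolume(lv, "P1"),
       contour = sweep(labelCoordinates(lv, "boundary"), 2, origin, "+"))
}

# uniformly random points on the unit sphere (for ellipsoid sampling)
spherePoints <- function(n) {
  z <- runif(n, -1, 1)
  ph <- runif(n, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  cbind(s * cos(ph), s * sin(ph), z)
}

# film meeting angles from fitted spheres: angle between the outward
# sphere normals of two films at the shared triple-circle points
filmAngleFromSpheres <- function(fitA, fitB, ringPts) {
  nA <- sweep(ringPts, 2, fitA$center)
  nB <- sweep(ringPts, 2, fitB$center)
  nA <- nA / sqrt(rowSums(nA^2))
  nB <- nB / sqrt(rowSums(nB^2))
  mean(acos(pmin(pmax(rowSums(nA * nB), -1), 1))) * 180 / pi
}

# cached zero-noise segmentation of the synthetic truth
segFixture <- function() cached("seg0", function() {
  fx <- synthTruth()
  segmentRendered(fx$truth, fx$geom, fx$cfg, noise = FALSE)
})

gtFixture <- function() cached("gt0", function() {
  fx <- synthTruth()
  seg <- segFixture()
  groundTruthLabels(fx$truth, seg$dims, 0.733, seg$origin)
})
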