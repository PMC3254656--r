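test_that("preprocessing smooths, resamples to cubic voxels, and conserves mass", {
  const <- ImageStack(array(3.5, c(20, 20, 8)), c(0.244, 0.244, 0.733))
  out <- preprocessStack(const)
  expect_equal(out@spacing, rep(0.733, 3))
  expect_true(all(abs(out@channels$membrane - 3.5) < 1e-9))

  # interior-supported blob: integrated intensity conserved within 1%
  d <- c(48, 48, 24)
  g1 <- ((1:d[1]) - d[1] / 2) * 0.244
  g2 <- ((1:d[2]) - d[2] / 2) * 0.244
  g3 <- ((1:d[3]) - d[3] / 2) * 0.733
  blob <- exp(-outer(outer(g1^2, g2^2, "+"), g3^2, "+") / 4)
  stk <- ImageStack(blob, c(0.244, 0.244, 0.733))
  iso <- preprocessStack(stk)
  massIn <- sum(blob) * prod(stk@spacing)
  massOut <- sum(iso@channels$membrane) * 0.733^3
  expect_lt(abs(massOut - massIn) / massIn, 0.01)
})

test_that("marker-based watershed partitions a two-blob landscape", {
  # two spherical membrane shells side by side
  n <- 40
  g <- 1:n
  d1 <- sqrt(outer(outer((g - 12)^2, (g - 20)^2, "+"), (g - 20)^2, "+"))
  d2 <- sqrt(outer(outer((g - 29)^2, (g - 20)^2, "+"), (g - 20)^2, "+"))
  img <- exp(-(d1 - 8)^2 / 2) + exp(-(d2 - 8)^2 / 2)
  mk <- rbind(AB = c(12, 20, 20), P1 = c(29, 20, 20), exterior = c(1, 1, 1))
  lv <- watershedSegment(img, mk, spacing = 1)
  lab <- lv@labels
  # labels are exhaustive (partition)
  expect_equal(sum(table(lab)), n^3)
  # each marker voxel carries its own region label
  expect_equal(lab[12, 20, 20], 1L)
  expect_equal(lab[29, 20, 20], 2L)
  expect_equal(lab[1, 1, 1], 3L)
  # boundary voxels separate distinct regions: no AB voxel touches P1
  ab <- lab == 1L
  adjP1 <- embryoshape:::.faceAdjacent(lab == 2L)
  expect_equal(sum(ab & adjP1), 0L)
  expect_error(watershedSegment(img, rbind(c(1, 1, 1), c(1, 1, 1)), spacing = 1),
               "coincident")
})

test_that("half-boundary volume estimator is within 1% on digitized spheres", {
  for (r in c(8, 15)) {
    L <- sphereLandscape(r)
    lv <- watershedSegment(L$img, L$markers, spacing = 1)
    V <- regionVolume(lv, "AB")
    expect_lt(abs(V - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3), 0.01)
  }
})

test_that("volume estimator edge cases follow the counting rule", {
  # full-volume region without boundary: N_cell times voxel volume
  lab <- array(1L, c(5, 5, 5))
  lv <- new("LabelVolume", labels = lab, spacing = 2)
  expect_equal(regionVolume(lv, "AB"), 125 * 8)
  expect_error(regionVolume(lv, "P1"), "absent")
  # 10^3 cube region with a full boundary shell: face-adjacent boundary
  # voxels number 600, so V = (1000 + 300) voxel volumes (the cube-corner
  # bias relative to the true 12^3 enclosed cube is expected: the
  # estimator's contract covers smooth shapes)
  n <- 14
  lab <- array(3L, c(n, n, n))
  cell <- 3:12
  lab[cell, cell, cell] <- 1L
  shell <- 2:13
  mask <- array(FALSE, c(n, n, n))
  mask[shell, shell, shell] <- TRUE
  mask[cell, cell, cell] <- FALSE
  lab[mask] <- 0L
  lv <- new("LabelVolume", labels = lab, spacing = 1)
  expect_equal(regionVolume(lv, "AB"), 1000 + 600 / 2)
})

test_that("2D curve depth matches the sagitta with the AB-to-P1 sign rule", {
  # straight trace
  straight <- cbind(seq(0, 10, length.out = 11), 0)
  expect_equal(curveDepth2D(straight, c(0, 1)), 0)
  # circular arc of radius R through chord half-length rho
  R <- 12; rho <- 5
  th <- asin(rho / R)
  ang <- seq(-th, th, length.out = 41)
  arcP1 <- cbind(R * sin(ang), R * cos(ang) - sqrt(R^2 - rho^2))  # bulge +y
  sag <- R - sqrt(R^2 - rho^2)
  expect_equal(curveDepth2D(arcP1, c(0, 1)), sag, tolerance = 1e-6)
  expect_equal(curveDepth2D(arcP1, c(0, -1)), -sag, tolerance = 1e-6)
  # invariance under rigid in-plane transforms
  phi <- 0.7
  Rot <- rbind(c(cos(phi), -sin(phi)), c(sin(phi), cos(phi)))
  moved <- arcP1 %*% t(Rot) + matrix(c(4, -3), nrow(arcP1), 2, byrow = TRUE)
  expect_equal(curveDepth2D(moved, as.numeric(Rot %*% c(0, 1))), sag,
               tolerance = 1e-6)
  expect_error(curveDepth2D(arcP1[1:2, ], c(0, 1)), "at least 3")
})

test_that("contact classification uses the strict 160-degree criterion", {
  mkpts <- function(angleDeg) {
    half <- angleDeg / 2 * pi / 180
    list(E = rbind(c(cos(half), sin(half)) * 10, c(cos(half), -sin(half)) * 10),
         M = c(0, 0))
  }
  p <- mkpts(180)
  expect_equal(classifyContact(rbind(c(-10, 0), c(10, 0)), c(0, 0)), "flat")
  p159 <- mkpts(159)
  expect_equal(classifyContact(p159$E, p159$M), "curved")
  p160 <- mkpts(160)
  expect_equal(classifyContact(p160$E, p160$M), "flat")
  p90 <- mkpts(90)
  expect_equal(classifyContact(p90$E, p90$M), "curved")
  expect_error(classifyContact(rbind(c(0, 0), c(1, 1)), c(0, 0)), "coincident")
})

test_that("size symmetry uses the larger-length denominator, boundary inclusive", {
  expect_true(sizeSymmetry(20, 20))
  expect_true(sizeSymmetry(20, 18))     # exactly 10%
  expect_false(sizeSymmetry(22, 15))
  expect_true(sizeSymmetry(18, 20))
  expect_error(sizeSymmetry(0, 10), "positive")
})

test_that("intensity normalization divides by the merged-region time average", {
  # constant equal traces normalize to 1
  tr <- normalizeIntensity(rep(100, 5), rep(100, 5), areas = c(3, 2))
  expect_equal(tr@normAB, rep(1, 5))
  expect_equal(tr@normP1, rep(1, 5))
  # gain invariance
  a <- normalizeIntensity(c(80, 100, 120), c(60, 60, 60), areas = c(2, 1))
  b <- normalizeIntensity(7 * c(80, 100, 120), 7 * c(60, 60, 60), areas = c(2, 1))
  expect_equal(a@normAB, b@normAB)
  expect_equal(a@normP1, b@normP1)
  # direct ratio: merged mean 100, I_AB = 125 -> 1.25
  IP1 <- (100 * 3 - 125 * 1.5) / 1.5   # merged mean exactly 100 with equal areas
  tr2 <- normalizeIntensity(rep(125, 4), rep(IP1, 4), areas = c(1.5, 1.5))
  expect_equal(tr2@normAB, rep(1.25, 4))
  expect_error(normalizeIntensity(c(0, 0), c(0, 0), areas = c(1, 1)),
               "nonpositive")
})

test_that("flow velocity is the mean least-squares path-line slope", {
  tt <- seq(0, 5, by = 0.1)
  mkk <- function(slopes) new("Kymograph", image = matrix(numeric(0), 0, 0),
                              pathLines = lapply(slopes, function(s)
                                data.frame(t = tt, x = 1 + s * tt)),
                              dt = 0.1, dx = NA_real_)
  expect_equal(flowVelocity(mkk(c(2.4, 2.4, 2.4))), 2.4)
  expect_equal(flowVelocity(mkk(c(0.5, 0.6, 0.7))), 0.6)
  expect_error(flowVelocity(mkk(c(1, 2))), "at least 3")
})

test_that("boundary filling removes watershed lines by majority vote", {
  L <- sphereLandscape(8)
  lv <- watershedSegment(L$img, L$markers, spacing = 1)
  filled <- fillBoundary(lv)
  expect_equal(sum(filled@labels == 0L), 0L)
  # regions only grow into former boundary voxels
  expect_true(all(filled@labels[lv@labels == 1L] == 1L))
  expect_true(all(filled@labels[lv@labels == 3L] == 3L))
})

test_that("image stacks round-trip through multi-page TIFF", {
  set.seed(9)
  s <- ImageStack(list(membrane = array(runif(4 * 5 * 3, 0, 800), c(4, 5, 3)),
                       eggshell = array(runif(4 * 5 * 3, 0, 90), c(4, 5, 3))),
                  c(0.244, 0.244, 0.733))
  base <- tempfile("stack")
  writeImageStack(s, base)
  s2 <- readImageStack(base)
  expect_equal(s2@spacing, s@spacing)
  expect_equal(names(s2@channels), names(s@channels))
  # 32-bit float pages: agreement to single precision
  expect_lt(max(abs(s2@channels$membrane - s@channels$membrane)), 1e-3)
})
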