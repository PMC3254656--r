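test_that("embryo geometry generation is deterministic and respects its contract", {
  cfg <- SynthConfig(seed = 17)
  g1 <- generateEmbryoGeometry(cfg)
  g2 <- generateEmbryoGeometry(cfg)
  expect_identical(g1, g2)
  for (s in 1:50) {
    g <- generateEmbryoGeometry(SynthConfig(seed = s))
    f <- g$volAB / (g$volAB + g$volP1)
    expect_gte(f, 0.55); expect_lte(f, 0.60)
    expect_lt(abs((g$volAB + g$volP1) / ellipsoidVolume(g$ellipsoid) - 0.95), 1e-9)
    expect_true(all(abs(g$ellipsoid@axes / sort(c(25, 15, 15), TRUE) - 1) <= 0.1 + 1e-9))
  }
})

test_that("stack rendering is seed-deterministic and localizes the membrane", {
  fx <- synthTruth()
  s1 <- renderStack(fx$truth, fx$geom$ellipsoid, fx$cfg, noise = TRUE)
  s2 <- renderStack(fx$truth, fx$geom$ellipsoid, fx$cfg, noise = TRUE)
  expect_identical(s1@channels, s2@channels)
  # zero-noise render: the brightest voxels sit within one voxel of the
  # true surface
  s0 <- renderStack(fx$truth, fx$geom$ellipsoid, fx$cfg, noise = FALSE)
  mem <- s0@channels$membrane
  origin <- attr(s0, "origin")
  sp <- fx$cfg@voxelSpacing
  idx <- which(mem >= 0.8 * max(mem), arr.ind = TRUE)
  idx <- idx[seq(1, nrow(idx), length.out = min(200, nrow(idx))), , drop = FALSE]
  pts <- sweep(sweep(idx - 0.5, 2, sp, "*"), 2, origin, "+")
  surf <- embryoshape:::.sampleMeshPoints(fx$truth@mesh@vertices,
                                          fx$truth@mesh@triangles, 0.4)
  nn <- embryoshape:::cpp_nn(pts, surf$points)
  expect_lt(max(nn$dist), max(sp) + 1e-6)
})

test_that("render-segment round trip recovers volumes and overlaps ground truth", {
  fx <- synthTruth()
  seg <- segFixture()
  expect_lt(abs(seg$volAB - fx$geom$volAB) / fx$geom$volAB, 0.03)
  expect_lt(abs(seg$volP1 - fx$geom$volP1) / fx$geom$volP1, 0.03)
  gt <- gtFixture()
  filled <- fillBoundary(seg$lv)
  expect_gt(diceCoefficient(filled@labels == 1L, gt@labels == 1L), 0.97)
  expect_gt(diceCoefficient(filled@labels == 2L, gt@labels == 2L), 0.97)
  # noisy variant (photon-limited, SNR ~ 5)
  cfgN <- SynthConfig(seed = 3, photonScale = 25)
  segN <- segmentRendered(fx$truth, fx$geom, cfgN, noise = TRUE)
  filledN <- fillBoundary(segN$lv)
  expect_gt(diceCoefficient(filledN@labels == 1L, gt@labels == 1L), 0.93)
  expect_gt(diceCoefficient(filledN@labels == 2L, gt@labels == 2L), 0.93)
})

test_that("synthetic kymographs close the loop with the velocimeter", {
  cfg0 <- SynthConfig(seed = 1, kymoNoise = 0)
  expect_equal(flowVelocity(synthKymograph(2.4, cfg0)), 2.4)
  expect_equal(flowVelocity(synthKymograph(0, cfg0)), 0)
  k1 <- synthKymograph(1.1, SynthConfig(seed = 4))
  k2 <- synthKymograph(1.1, SynthConfig(seed = 4))
  expect_identical(k1@pathLines, k2@pathLines)
  # noisy recovery within 10% across seeds
  for (s in 1:10) {
    k <- synthKymograph(0.6, SynthConfig(seed = s, kymoNoise = 0.3))
    expect_lt(abs(flowVelocity(k) - 0.6) / 0.6, 0.10)
  }
})

test_that("synthetic intensity traces close the loop with the normalizer", {
  cfg <- SynthConfig(seed = 2)
  tr <- synthIntensityTraces(cfg, noise = FALSE, gain = 700)
  out <- normalizeIntensity(tr$rawAB, tr$rawP1, areas = tr$areas, time = tr$time)
  expect_equal(out@normAB, tr$normAB, tolerance = 1e-9)
  expect_equal(out@normP1, tr$normP1, tolerance = 1e-9)
  # configured landmark: normalized AB at 8 min is 1.25
  expect_equal(out@normAB[which(tr$time == 8)], 1.25, tolerance = 1e-9)
  # gain invariance and determinism
  tr2 <- synthIntensityTraces(cfg, noise = FALSE, gain = 70)
  out2 <- normalizeIntensity(tr2$rawAB, tr2$rawP1, areas = tr2$areas)
  expect_equal(out2@normAB, out@normAB, tolerance = 1e-9)
  expect_identical(synthIntensityTraces(cfg), synthIntensityTraces(cfg))
})

test_that("analytic double bubble is self-consistent", {
  vA <- 4000; vP <- 2600
  db <- doubleBubbleMesh(vA, vP)
  expect_lt(abs(enclosedVolume(db$mesh, "AB") - vA) / vA, 0.005)
  expect_lt(abs(enclosedVolume(db$mesh, "P1") - vP) / vP, 0.005)
  # center separation satisfies the 120-degree condition
  expect_equal(db$D^2, db$R1^2 + db$R2^2 - db$R1 * db$R2, tolerance = 1e-9)
  # contact film curvature follows from the outer radii
  expect_equal(1 / db$Rcnt, 1 / db$R2 - 1 / db$R1, tolerance = 1e-9)
  # equal volumes give a planar film
  dbe <- doubleBubbleMesh(3000, 3000)
  expect_true(is.infinite(dbe$Rcnt))
  expect_equal(meshCurveDepth(dbe$mesh), 0, tolerance = 1e-9)
})
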