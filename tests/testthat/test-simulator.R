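test_that("contact-stability triangle inequality classifies tension sets", {
  expect_true(checkTensionValidity(TensionParams(1, 1, 1)))
  expect_true(checkTensionValidity(TensionParams(gammaAB = 3.4, gammaCnt = 3.4)))
  expect_false(checkTensionValidity(TensionParams(gammaAB = 5, gammaCnt = 0.2)))
  # boundary cases are inclusive
  expect_true(checkTensionValidity(TensionParams(gammaAB = 2, gammaCnt = 1)))
  expect_true(checkTensionValidity(TensionParams(gammaAB = 2, gammaCnt = 3)))
  expect_error(TensionParams(gammaAB = -1), "positive")
})

test_that("total energy is the tension-weighted patch-area sum", {
  m <- initConfiguration(NULL)
  areas <- surfaceArea(m, "AB_outer") + surfaceArea(m, "P1_outer") +
    surfaceArea(m, "contact")
  expect_equal(totalEnergy(m, TensionParams(1, 1, 1)), areas)
  expect_equal(totalEnergy(m, TensionParams(2, 2, 2)),
               2 * totalEnergy(m, TensionParams(1, 1, 1)))
  # two 14.7-um cubes sharing one face: 2 * 5 faces + 1 shared face
  expect_equal(totalEnergy(m, TensionParams(1, 1, 1)), 11 * 14.7^2)
})

test_that("initial configuration builds two face-sharing cubes on the major axis", {
  e <- embryoEllipsoid()
  m <- initConfiguration(e, 100, 100)
  expect_equal(sum(m@patch == 3L), 2L)            # shared face, stored once
  expect_equal(enclosedVolume(m, "AB"), enclosedVolume(m, "P1"))
  expect_equal(enclosedVolume(m, "AB"), 14.7^3, tolerance = 1e-12)
  # contact normal parallel to the major axis
  f <- triangles(m)[m@patch == 3L, , drop = FALSE][1, ]
  v <- vertices(m)[f, ]
  nrm <- c(
    (v[2, 2] - v[1, 2]) * (v[3, 3] - v[1, 3]) - (v[2, 3] - v[1, 3]) * (v[3, 2] - v[1, 2]),
    (v[2, 3] - v[1, 3]) * (v[3, 1] - v[1, 1]) - (v[2, 1] - v[1, 1]) * (v[3, 3] - v[1, 3]),
    (v[2, 1] - v[1, 1]) * (v[3, 2] - v[1, 2]) - (v[2, 2] - v[1, 2]) * (v[3, 1] - v[1, 1]))
  nrm <- nrm / sqrt(sum(nrm^2))
  expect_lt(sum(abs(abs(nrm) - abs(e@orientation[, 1]))), 1e-8)
  # infeasible target volumes are rejected
  expect_error(initConfiguration(e, 2e4, 1e4), "do not fit")
})

test_that("symmetric equal-tension system relaxes to a flat contact with equal pressures", {
  V <- 14.7^3
  big <- Ellipsoid(axes = c(60, 50, 50))      # non-binding shell
  sh <- minimizeShape(TensionParams(1, 1, 1), V, V, big)
  p <- pressures(sh)
  expect_lt(abs(p[["AB"]] / p[["P1"]] - 1), 0.01)
  ring <- vertices(sh)[embryoshape:::.tripleLineVertices(sh@mesh), ]
  diam <- 2 * mean(sqrt(rowSums(sweep(ring, 2, colMeans(ring))^2)))
  expect_lt(abs(meshCurveDepth(sh)), 0.01 * diam)
  expect_lt(max(abs(sh@volumeResiduals)), 1e-4)
})

test_that("free double bubble matches the classical equal-tension solution", {
  Vt <- 2 * 14.7^3
  sh <- minimizeShape(TensionParams(1, 1, 1), 0.6 * Vt, 0.4 * Vt, NULL)
  mesh <- equilibriumMesh(sh)
  pl <- patchLabels(mesh)
  fit <- lapply(c("AB_outer", "P1_outer", "contact"), function(lbl) {
    vv <- unique(as.integer(triangles(mesh)[pl == lbl, ]))
    fitSphere(vertices(mesh)[vv, ])
  })
  names(fit) <- c("AB", "P1", "cnt")
  # outer patches are spherical caps
  expect_lt(fit$AB$residual / fit$AB$radius, 0.01)
  expect_lt(fit$P1$residual / fit$P1$radius, 0.01)
  # Laplace: P_i = 2 gamma_i / R_i, dP = 2 gamma_cnt / R_cnt (within 2%)
  p <- pressures(sh)
  expect_lt(abs(p[["AB"]] - 2 / fit$AB$radius) / (2 / fit$AB$radius), 0.02)
  expect_lt(abs(p[["P1"]] - 2 / fit$P1$radius) / (2 / fit$P1$radius), 0.02)
  dP <- p[["P1"]] - p[["AB"]]                  # smaller bubble has higher pressure
  expect_lt(abs(dP - 2 / fit$cnt$radius) / (2 / fit$cnt$radius), 0.02)
  # films meet at 120 degrees along the triple circle (sphere-normal method)
  ring <- vertices(mesh)[embryoshape:::.tripleLineVertices(mesh), ]
  angAP <- filmAngleFromSpheres(fit$AB, fit$P1, ring)
  expect_lt(abs(angAP - 60), 2)                # outward normals of the outer caps
  # energy agrees with the analytic double-bubble construction
  db <- doubleBubbleMesh(0.6 * Vt, 0.4 * Vt)
  expect_lt(abs(energy(sh) - totalEnergy(db$mesh, TensionParams(1, 1, 1))) /
              energy(sh), 0.01)
  # contact bulges into the larger body: negative depth
  expect_lt(meshCurveDepth(sh), 0)
})

test_that("tension scaling rescales pressures and leaves the geometry unchanged", {
  Vt <- 2 * 14.7^3
  a <- minimizeShape(TensionParams(1.5, 1.2, 1), 0.55 * Vt, 0.45 * Vt, NULL)
  b <- minimizeShape(TensionParams(3.0, 2.4, 2), 0.55 * Vt, 0.45 * Vt, NULL)
  pa <- pressures(a); pb <- pressures(b)
  expect_lt(abs(pb[["AB"]] / pa[["AB"]] - 2), 0.01)
  expect_lt(abs(pb[["P1"]] / pa[["P1"]] - 2), 0.01)
  expect_lt(abs(meshCurveDepth(b) - meshCurveDepth(a)) /
              max(abs(meshCurveDepth(a)), 0.1), 0.005)
  expect_lt(abs(energy(b) - 2 * energy(a)) / energy(b), 0.005)
})

test_that("swapping body labels and tensions mirrors the shape", {
  Vt <- 2 * 14.7^3
  a <- minimizeShape(TensionParams(2, 1.5, 1), 0.55 * Vt, 0.45 * Vt, NULL)
  # swapped system, rescaled so gammaP1 stays 1: (1, 1.5, 2)/2
  b <- minimizeShape(TensionParams(0.5, 0.75, 1), 0.45 * Vt, 0.55 * Vt, NULL)
  da <- meshCurveDepth(a); db <- meshCurveDepth(b)
  expect_lt(abs(da + db), 0.02 * max(abs(da), abs(db), 0.5))
  pa <- pressures(a); pb <- pressures(b)
  expect_lt(abs(pb[["P1"]] / pa[["AB"]] - 0.5), 0.01)
})

test_that("energy is non-increasing over accepted descent steps", {
  sh <- minimizeShape(TensionParams(1, 1, 1), 14.7^3, 14.7^3, NULL)
  tr <- sh@energyTrace
  expect_true(all(diff(tr) <= 1e-9 * abs(tr[-length(tr)])))
})

test_that("single spherical body reproduces the Laplace closed form", {
  R <- 8
  sh <- minimizeShape(TensionParams(1, 1, 1), 4 / 3 * pi * R^3, NULL, NULL)
  p <- pressures(sh)
  expect_lt(abs(p[["AB"]] - 2 / R) / (2 / R), 0.02)
  expect_true(is.na(p[["P1"]]))
  fs <- fitSphere(vertices(sh))
  expect_lt(fs$residual / fs$radius, 0.005)
})

test_that("multiplier pressures agree with the finite-difference dE/dV oracle", {
  Vt <- 2 * 14.7^3
  sh <- minimizeShape(TensionParams(1, 1, 1), 0.6 * Vt, 0.4 * Vt, NULL)
  fd <- finiteDifferencePressures(TensionParams(1, 1, 1), 0.6 * Vt, 0.4 * Vt,
                                  NULL, delta = 0.01)
  p <- pressures(sh)
  expect_lt(abs(p[["AB"]] - fd[["AB"]]) / fd[["AB"]], 0.02)
  expect_lt(abs(p[["P1"]] - fd[["P1"]]) / fd[["P1"]], 0.02)
})

test_that("mesh curve depth is zero on planar contacts and matches the sagitta on caps", {
  expect_equal(meshCurveDepth(initConfiguration(NULL)), 0, tolerance = 1e-10)
  db <- doubleBubbleMesh(1.4 * 14.7^3, 0.9 * 14.7^3)
  sag <- db$Rcnt - sqrt(db$Rcnt^2 - db$rho^2)
  # the film bulges into the larger body (AB): negative by the sign rule
  expect_equal(meshCurveDepth(db$mesh), -sag, tolerance = 0.02 * sag)
  expect_error(meshCurveDepth(cubeMesh()), "contact patch is empty")
})

test_that("embryo-scale result is stable under one extra subdivision round", {
  h4 <- homoShape(4); h5 <- homoShape(5)
  r4 <- pressures(h4)[["AB"]] / pressures(h4)[["P1"]]
  r5 <- pressures(h5)[["AB"]] / pressures(h5)[["P1"]]
  expect_lt(abs(r5 - r4) / abs(r5), 0.01)
  expect_lt(abs(meshCurveDepth(h5) - meshCurveDepth(h4)) /
              abs(meshCurveDepth(h5)), 0.01)
})

test_that("equilibrium invariants hold on embryo-like geometry", {
  sh <- homoShape(4)
  # energy equals the tension-weighted area of the stored mesh
  expect_equal(energy(sh), totalEnergy(equilibriumMesh(sh), tensions(sh)),
               tolerance = 1e-9)
  # all vertices respect the one-sided shell constraint
  e <- embryoEllipsoid()
  L <- vertices(sh)
  q <- (L[, 1] / 25)^2 + (L[, 2] / 15)^2 + (L[, 3] / 15)^2
  expect_lt(max(q), 1 + 1e-6)
  expect_lt(max(abs(sh@volumeResiduals)), 1e-4)
})
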