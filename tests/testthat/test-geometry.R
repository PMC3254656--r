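test_that("patch areas are exact on polyhedra and convergent on spheres", {
  cube <- cubeMesh(side = 14.7)
  expect_equal(surfaceArea(cube, "AB_outer"), 6 * 14.7^2)
  expect_equal(surfaceArea(cube, "contact"), 0)
  expect_error(surfaceArea(cube, "outer"), "unknown patch label")

  sph <- icosphereMesh(10, 3)
  expect_lt(abs(surfaceArea(sph, "AB_outer") - 4 * pi * 100) / (4 * pi * 100), 0.01)
})

test_that("enclosed volume is exact on cubes, invariant under translation,
           convergent on spheres", {
  cube <- cubeMesh(side = 3.2)
  expect_equal(enclosedVolume(cube, "AB"), 3.2^3)
  moved <- TriSurfaceMesh(sweep(vertices(cube), 2, c(11, -4, 7), "+"),
                          triangles(cube), cube@patch)
  expect_equal(enclosedVolume(moved, "AB"), enclosedVolume(cube, "AB"))
  # ... and for an off-origin construction (divergence theorem is
  # independent of the origin choice)
  for (sh in list(c(100, 0, 0), c(-3, 55, 2), c(0.1, -0.2, 0.3))) {
    m <- cubeMesh(side = 2, center = sh)
    expect_equal(enclosedVolume(m, "AB"), 8, tolerance = 1e-12)
  }
  sph <- icosphereMesh(10, 3)
  expect_lt(abs(enclosedVolume(sph, "AB") - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.01)
  expect_error(enclosedVolume(cube, "P1"), "absent")
})

test_that("midpoint subdivision quadruples triangles and preserves geometry", {
  cube <- cubeMesh(side = 5)
  sub <- subdivideMesh(cube)
  expect_equal(nrow(triangles(sub)), 4 * nrow(triangles(cube)))
  expect_equal(enclosedVolume(sub, "AB"), 125)
  expect_equal(surfaceArea(sub, "AB_outer"), surfaceArea(cube, "AB_outer"))
  # labels inherited
  expect_equal(as.character(unique(patchLabels(sub))), "AB_outer")
  # shared (two-body) meshes stay conforming and closed
  pair <- subdivideMesh(initConfiguration(NULL))
  expect_equal(enclosedVolume(pair, "AB"), 14.7^3, tolerance = 1e-12)
  expect_equal(enclosedVolume(pair, "P1"), 14.7^3, tolerance = 1e-12)
})

test_that("ellipsoid least squares is exact on clean samples and robust to noise", {
  set.seed(42)
  U <- spherePoints(400)
  P <- sweep(sweep(U, 2, c(25, 15, 15), "*"), 2, c(3, -2, 1), "+")
  e <- fitEllipsoid(P)
  expect_equal(e@axes, c(25, 15, 15), tolerance = 1e-6)
  expect_equal(e@center, c(3, -2, 1), tolerance = 1e-6)
  expect_lt(attr(e, "residual"), 1e-8)

  es <- fitEllipsoid(spherePoints(200) * 10)
  expect_lt(diff(range(es@axes)) / 10, 1e-6)

  Pn <- P + matrix(rnorm(length(P), 0, 0.2), ncol = 3)
  en <- fitEllipsoid(Pn)
  expect_lt(max(abs(en@axes - c(25, 15, 15)) / c(25, 15, 15)), 0.02)

  flat <- cbind(rnorm(50), rnorm(50), 0)
  expect_error(fitEllipsoid(flat), "degenerate|ellipsoidal")
  expect_error(fitEllipsoid(P[1:5, ]), "at least 9")
})

test_that("nearest-point ellipsoid projection matches a brute-force oracle", {
  e <- Ellipsoid(center = c(1, 2, 3), axes = c(25, 15, 12),
                 orientation = diag(3))
  # fixed point on the surface
  p0 <- c(1, 2, 3) + c(25, 0, 0)
  expect_equal(projectToEllipsoid(p0, e), p0, tolerance = 1e-9)
  # radial projection on a sphere
  s <- Ellipsoid(axes = c(7, 7, 7))
  expect_equal(projectToEllipsoid(c(14, 0, 0), s), c(7, 0, 0), tolerance = 1e-9)

  set.seed(7)
  X <- sweep(spherePoints(25) * 40, 2, c(1, 2, 3), "+")   # exterior points
  P <- projectToEllipsoid(X, e)
  L <- sweep(P, 2, c(1, 2, 3))
  q <- (L[, 1] / 25)^2 + (L[, 2] / 15)^2 + (L[, 3] / 12)^2
  expect_lt(max(abs(q - 1)), 1e-8)
  # distance-minimality against a dense surface sampling
  U <- spherePoints(20000)
  surf <- sweep(sweep(U, 2, c(25, 15, 12), "*"), 2, c(1, 2, 3), "+")
  for (i in seq_len(nrow(X))) {
    dProj <- sqrt(sum((X[i, ] - P[i, ])^2))
    dBrute <- min(sqrt(rowSums(sweep(surf, 2, X[i, ])^2)))
    expect_lte(dProj, dBrute + 1e-6)
  }
})

test_that("mesh and ellipsoid round-trip through OFF, PLY and JSON", {
  m <- subdivideMesh(initConfiguration(NULL))
  off <- tempfile(fileext = ".off")
  ply <- tempfile(fileext = ".ply")
  writeMeshOFF(m, off)
  writeMeshPLY(m, ply)
  for (m2 in list(readMeshOFF(off), readMeshPLY(ply))) {
    expect_equal(vertices(m2), unname(vertices(m)), tolerance = 1e-9)
    expect_equal(unname(triangles(m2)), unname(triangles(m)))
    expect_equal(m2@patch, m@patch)
  }
  e <- Ellipsoid(center = c(1, 2, 3), axes = c(25, 15, 14))
  js <- tempfile(fileext = ".json")
  writeEllipsoidJSON(e, js)
  e2 <- readEllipsoidJSON(js)
  expect_equal(e2@axes, e@axes)
  expect_equal(e2@center, e@center)
  expect_equal(e2@orientation, e@orientation)
})

test_that("mesh validity rejects open or inconsistent bodies", {
  cube <- cubeMesh()
  expect_error(TriSurfaceMesh(vertices(cube), triangles(cube)[-1, ],
                              rep(1L, 11)), "not closed")
  badF <- triangles(cube)
  badF[1, ] <- badF[1, c(1, 3, 2)]
  expect_error(TriSurfaceMesh(vertices(cube), badF, rep(1L, 12)),
               "not consistently oriented|not closed")
})
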