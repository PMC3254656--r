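test_that("the full tension grid contains exactly 514 valid combinations", {
  grid <- validTensionGrid(GridSpec(0.2, 10, 0.2))
  expect_equal(nrow(grid), 514L)
  # brute force with exact integer indices: gamma = 0.2 k, gammaP1 = 1
  cnt <- 0L
  for (a in 1:50) for (c in 1:50)
    if (abs(a - 5) <= c && c <= a + 5) cnt <- cnt + 1L
  expect_equal(nrow(grid), cnt)
  # lexicographic order and the inequality on every row
  expect_true(!is.unsorted(grid$gamma_ab))
  expect_true(all(abs(grid$gamma_ab - 1) <= grid$gamma_cnt + 1e-9))
  expect_true(all(grid$gamma_cnt <= grid$gamma_ab + 1 + 1e-9))
})

test_that("degenerate grids enumerate as expected", {
  ten <- validTensionGrid(GridSpec(1, 1, 0.2), GridSpec(0.2, 2, 0.2))
  expect_equal(nrow(ten), 10L)
  expect_equal(ten$gamma_cnt, seq(0.2, 2, by = 0.2))
  one <- validTensionGrid(GridSpec(1, 1, 0.2), GridSpec(1, 1, 0.2))
  expect_equal(unname(as.matrix(one)), matrix(c(1, 1), 1))
})

test_that("ICP recovers known rigid transforms", {
  set.seed(11)
  S <- matrix(rnorm(300), ncol = 3) * c(8, 4, 2)
  # identical clouds: identity transform, zero RMSE
  r0 <- icpAlign(S, S)
  expect_lt(r0$rmse, 1e-9)
  expect_equal(r0$rotation, diag(3), tolerance = 1e-6)
  # rotation 10 degrees about z plus translation
  th <- 10 * pi / 180
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  Tg <- S %*% t(Rz) + matrix(c(3, 2, 1), nrow(S), 3, byrow = TRUE)
  r <- icpAlign(S, Tg)
  expect_lt(r$rmse, 1e-6)
  expect_equal(r$rotation, Rz, tolerance = 1e-4)
  expect_equal(r$translation, c(3, 2, 1), tolerance = 1e-3)
  # noise floor: near-identity transform, RMSE at the noise scale
  Tn <- S + matrix(rnorm(length(S), 0, 0.1), ncol = 3)
  rn <- icpAlign(S, Tn)
  expect_lt(rn$rmse, 0.3)
  expect_lt(max(abs(rn$rotation - diag(3))), 0.05)
  expect_error(icpAlign(S[1:2, ], Tg), "at least 3")
  expect_error(icpAlign(cbind(1:9, 2 * (1:9), 3 * (1:9)), Tg), "collinear")
})

test_that("tension fitting recovers generating parameters on self-consistent targets", {
  fx <- synthTruth()
  g <- GridSpec(3.2, 3.6, 0.2)
  combos <- validTensionGrid(g)
  shapes <- cached("gridShapesSmall", function()
    simulateTensionGrid(combos, fx$geom$volAB, fx$geom$volP1, fx$geom$ellipsoid))
  fit <- fitTensions(vertices(fx$truth), fx$geom$volAB, fx$geom$volP1,
                     fx$geom$ellipsoid, g, shapes = shapes)
  best <- fit@table[fit@best, ]
  expect_equal(best$gamma_ab, 3.4)
  expect_equal(best$gamma_cnt, 3.4)
  # RMSE at the generating parameters is minimal over the grid
  truthRow <- fit@table$gamma_ab == 3.4 & fit@table$gamma_cnt == 3.4
  expect_true(all(fit@table$rmse_um[truthRow] <= fit@table$rmse_um + 1e-12))
  expect_lt(best$rmse_um, 1e-6)
  # invariants of the result table
  expect_equal(nrow(fit@table), nrow(combos))
  expect_true(all(abs(fit@table$gamma_ab - 1) <= fit@table$gamma_cnt + 1e-9))
})
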