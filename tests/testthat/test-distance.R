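test_that("spatial gradient matches closed forms", {
  g0 <- spatialGradient(ScalarVolume(array(5, c(6, 6, 6))))
  expect_equal(max(abs(g0)), 0)

  g1 <- spatialGradient(rampVolume(8, axis = 1, slope = 2))
  expect_equal(max(abs(g1[, , , 1] - 2)), 0, tolerance = 1e-12)
  expect_equal(max(abs(g1[, , , 2:3])), 0)

  # separable product of one-axis ramps: f = x0 * x1
  n <- 8
  v1 <- volumeData(rampVolume(n, axis = 1))
  v2 <- volumeData(rampVolume(n, axis = 2))
  g <- spatialGradient(ScalarVolume(v1 * v2))
  interior <- 2:(n - 1)
  expect_equal(g[interior, interior, interior, 1],
               v2[interior, interior, interior], tolerance = 1e-10)
  expect_equal(g[interior, interior, interior, 2],
               v1[interior, interior, interior], tolerance = 1e-10)
  expect_equal(max(abs(g[, , , 3])), 0, tolerance = 1e-12)
})

test_that("NGF distance vanishes for identical constant images", {
  v <- ScalarVolume(array(2, c(8, 8, 8)))
  expect_equal(ngfDistance(v, v, eps = EdgeParameters(0.1)), 0)
})

test_that("orthogonal gradients approach the per-voxel maximum 1/2", {
  n <- 10
  r <- rampVolume(n, axis = 1, slope = 10)
  t <- rampVolume(n, axis = 2, slope = 10)
  d <- ngfDistance(r, t, eps = EdgeParameters(1e-3))
  expect_equal(d, 0.5 * n^3, tolerance = 1e-3)
})

test_that("a full mask gives zero distance regardless of images", {
  r <- smoothNoiseVolume(8, seed = 1)
  t <- smoothNoiseVolume(8, seed = 2)
  m <- PathologyMask(array(1, c(8, 8, 8)))
  expect_equal(ngfDistance(r, t, mask = m, eps = EdgeParameters(0.05)), 0)
})

test_that("enlarging the mask never increases the distance", {
  r <- smoothNoiseVolume(10, seed = 3)
  t <- smoothNoiseVolume(10, seed = 4)
  eps <- EdgeParameters(0.05)
  a <- array(0, c(10, 10, 10)); a[4:6, 4:6, 4:6] <- 1
  b <- a; b[3:8, 3:8, 3:8] <- 1
  d0 <- ngfDistance(r, t, eps = eps)
  dA <- ngfDistance(r, t, mask = PathologyMask(a), eps = eps)
  dB <- ngfDistance(r, t, mask = PathologyMask(b), eps = eps)
  expect_lte(dA, d0)
  expect_lte(dB, dA)
})

test_that("distance is symmetric and shift-invariant", {
  r <- smoothNoiseVolume(9, seed = 5)
  t <- smoothNoiseVolume(9, seed = 6)
  eps <- EdgeParameters(0.07)
  expect_equal(ngfDistance(r, t, eps = eps), ngfDistance(t, r, eps = eps),
               tolerance = 1e-12)
  shifted <- ScalarVolume(volumeData(t) + 11.5)
  expect_equal(ngfDistance(r, shifted, eps = eps),
               ngfDistance(r, t, eps = eps), tolerance = 1e-9)
})

test_that("per-voxel integrand is bounded in [0, 1/2]", {
  for (seed in 1:4) {
    r <- smoothNoiseVolume(8, seed = seed)
    t <- smoothNoiseVolume(8, seed = seed + 10)
    d <- ngfDistance(r, t, eps = EdgeParameters(0.03))
    expect_gte(d, 0)
    expect_lte(d, 0.5 * 8^3 + 1e-9)
  }
})

test_that("analytic NGF gradient matches finite differences", {
  n <- 10
  r <- smoothNoiseVolume(n, seed = 7)
  t <- smoothNoiseVolume(n, seed = 8)
  u <- smoothTestField(n, seed = 9)
  eps <- EdgeParameters(0.05)
  an <- ngfDistanceGradient(r, t, u, eps = eps)
  set.seed(1)
  idx <- sample(n^3 * 3, 60)
  fn <- function(uarr) ngfDistanceGradient(
    r, t, DisplacementField(uarr), eps = eps)$value
  fd <- fdGradientAt(fn, displacement(u), idx)
  expect_lt(maxRelError(as.numeric(an$gradient)[idx], fd), 1e-3)
})

test_that("masked-everywhere gradient is exactly zero", {
  n <- 8
  r <- smoothNoiseVolume(n, seed = 11)
  t <- smoothNoiseVolume(n, seed = 12)
  u <- smoothTestField(n, seed = 13)
  m <- PathologyMask(array(1, c(n, n, n)))
  g <- ngfDistanceGradient(r, t, u, mask = m, eps = EdgeParameters(0.05))
  expect_equal(g$value, 0)
  expect_equal(max(abs(g$gradient)), 0)
})

test_that("identical images at zero displacement are a stationary point", {
  v <- smoothNoiseVolume(10, seed = 14)
  u <- DisplacementField(shape = c(10, 10, 10))
  g <- ngfDistanceGradient(v, v, u, eps = EdgeParameters(0.04))
  expect_lt(abs(g$value), 1e-10)
  expect_lt(sqrt(sum(g$gradient^2)), 1e-8)
})

test_that("multi-channel distance is the sum of per-channel distances", {
  n <- 8
  r1 <- smoothNoiseVolume(n, seed = 15); r2 <- smoothNoiseVolume(n, seed = 16)
  t1 <- smoothNoiseVolume(n, seed = 17); t2 <- smoothNoiseVolume(n, seed = 18)
  u <- smoothTestField(n, seed = 19)
  eps <- EdgeParameters(0.05)

  # duplicated channel doubles value and gradient exactly
  dup <- multichannelDistance(MultiSequenceVolume(list(r1, r1)),
                              MultiSequenceVolume(list(t1, t1)), u,
                              eps = eps)
  single <- ngfDistanceGradient(r1, t1, u, eps = eps)
  expect_equal(dup$value, 2 * single$value, tolerance = 1e-12)
  expect_equal(dup$gradient, 2 * single$gradient, tolerance = 1e-12)

  # distinct channels: per-channel oracle
  two <- multichannelDistance(MultiSequenceVolume(list(r1, r2)),
                              MultiSequenceVolume(list(t1, t2)), u,
                              eps = list(eps, EdgeParameters(0.1)))
  p1 <- ngfDistanceGradient(r1, t1, u, eps = eps)
  p2 <- ngfDistanceGradient(r2, t2, u, eps = EdgeParameters(0.1))
  expect_equal(two$value, p1$value + p2$value, tolerance = 1e-12)
  expect_equal(two$gradient, p1$gradient + p2$gradient, tolerance = 1e-12)

  expect_error(multichannelDistance(MultiSequenceVolume(list(r1, r2)),
                                    MultiSequenceVolume(list(t1)), u,
                                    eps = eps), "channel count")
})

test_that("edge-parameter estimation follows the gradient magnitude", {
  flat <- ScalarVolume(array(1, c(8, 8, 8)))
  expect_equal(estimateEdgeParameter(flat), 1e-3)

  ramp <- rampVolume(8, axis = 1, slope = 2)
  expect_equal(estimateEdgeParameter(ramp, eta = 0.1), 0.2, tolerance = 1e-12)

  v <- smoothNoiseVolume(8, seed = 20)
  e1 <- estimateEdgeParameter(v, eta = 0.3)
  e2 <- estimateEdgeParameter(ScalarVolume(3 * volumeData(v)), eta = 0.3)
  expect_equal(e2, 3 * e1, tolerance = 1e-12)
})
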