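phSmall <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generatePhantomPair(PhantomSpec(seed = 5, size = 32,
                                                nLandmarks = 10,
                                                amplitude = 3,
                                                smoothness = 6))
    cache
  }
})

test_that("phantom generation is deterministic per seed", {
  spec <- PhantomSpec(seed = 9, size = 24, nLandmarks = 6, amplitude = 2,
                      smoothness = 5)
  a <- generatePhantomPair(spec)
  b <- generatePhantomPair(spec)
  expect_identical(volumeData(channels(a$fixed)[[1]]),
                   volumeData(channels(b$fixed)[[1]]))
  expect_identical(displacement(a$truth), displacement(b$truth))
  expect_identical(landmarkCoords(a$fixedLandmarks),
                   landmarkCoords(b$fixedLandmarks))

  f1 <- generateSmoothField(spec)
  f2 <- generateSmoothField(spec)
  expect_identical(displacement(f1), displacement(f2))
})

test_that("zero amplitude and zero noise give identical time points", {
  ph <- generatePhantomPair(PhantomSpec(seed = 2, size = 24, amplitude = 0,
                                        noiseSigma = 0, nLandmarks = 5,
                                        smoothness = 5))
  expect_equal(volumeData(channels(ph$fixed)[[1]]),
               volumeData(channels(ph$moving)[[1]]), tolerance = 1e-12)
  expect_equal(max(abs(displacement(ph$truth))), 0)
  expect_equal(treBaselineMean(computeTRE(ph$fixedLandmarks,
                                          ph$movingLandmarks)), 0)
})

test_that("generated deformations are fold-free with bounded amplitude", {
  for (s in 1:3) {
    f <- generateSmoothField(PhantomSpec(seed = s, size = 24, amplitude = 4,
                                         smoothness = 8))
    expect_equal(foldingFraction(f), 0)
    mag <- sqrt(displacement(f)[, , , 1]^2 + displacement(f)[, , , 2]^2 +
                  displacement(f)[, , , 3]^2)
    expect_lte(max(mag), 4 + 1e-9)
  }
  z <- generateSmoothField(PhantomSpec(seed = 1, size = 16, amplitude = 0))
  expect_equal(max(abs(displacement(z))), 0)
})

test_that("baseline TRE equals the mean true displacement at landmarks", {
  ph <- phSmall()
  rep <- computeTRE(ph$fixedLandmarks, ph$movingLandmarks)
  p <- landmarkCoords(ph$fixedLandmarks) + 1      # 1-based voxel index
  mags <- vapply(seq_len(nrow(p)), function(i) {
    sqrt(sum(displacement(ph$truth)[p[i, 1], p[i, 2], p[i, 3], ]^2))
  }, numeric(1))
  expect_equal(treBaselineMean(rep), mean(mags), tolerance = 1e-12)
})

test_that("warping the moving image by the truth reproduces the fixed image", {
  ph <- phSmall()
  w <- warpImage(channels(ph$moving)[[1]], ph$truth)
  f <- channels(ph$fixed)[[1]]
  keep <- volumeData(ph$mask) == 0
  err <- (volumeData(w) - volumeData(f))[keep]
  nrmse <- sqrt(mean(err^2)) / diff(range(volumeData(f)))
  expect_lt(nrmse, 0.05)
})

test_that("the cavity is non-corresponding and the mask removes its cost", {
  ph <- generatePhantomPair(PhantomSpec(seed = 4, size = 32, nLandmarks = 8,
                                        amplitude = 3, smoothness = 6,
                                        cavityRadius = 5))
  expect_gt(sum(volumeData(ph$mask)), 0)
  eps <- EdgeParameters(
    estimateEdgeParameter(channels(ph$fixed)[[1]]),
    estimateEdgeParameter(channels(ph$moving)[[1]]))
  w <- warpImage(channels(ph$moving)[[1]], ph$truth)
  dMasked <- ngfDistance(channels(ph$fixed)[[1]], w, mask = ph$mask,
                         eps = eps)
  dFull <- ngfDistance(channels(ph$fixed)[[1]], w, eps = eps)
  expect_lt(dMasked, dFull)
})

test_that("landmarks avoid the border and the cavity", {
  ph <- generatePhantomPair(PhantomSpec(seed = 6, size = 32, nLandmarks = 8,
                                        amplitude = 3, smoothness = 6,
                                        cavityRadius = 5))
  p <- landmarkCoords(ph$fixedLandmarks)
  expect_true(all(p >= 2) && all(p <= 32 - 3))
  pIdx <- p + 1
  inMask <- vapply(seq_len(nrow(pIdx)), function(i)
    volumeData(ph$mask)[pIdx[i, 1], pIdx[i, 2], pIdx[i, 3]], numeric(1))
  expect_true(all(inMask == 0))
})

test_that("per-sequence channels share geometry but differ in contrast", {
  ph <- generatePhantomPair(PhantomSpec(seed = 7, size = 24, nSequences = 3,
                                        nLandmarks = 5, amplitude = 2,
                                        smoothness = 5))
  expect_length(channels(ph$fixed), 3)
  expect_equal(seqLabels(ph$fixed), c("T1", "T1CE", "T2"))
  c1 <- volumeData(channels(ph$moving)[[1]])
  c2 <- volumeData(channels(ph$moving)[[2]])
  expect_gt(cor(as.numeric(c1), as.numeric(c2)), 0.7)  # shared anatomy
  expect_gt(max(abs(c1 - c2)), 0.05)                   # distinct contrast
})
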