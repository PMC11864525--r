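vol16 <- function(seed = 1) Volume3D(rand_volume(c(16, 16, 16), seed))

test_that("simple extractor has one tap per layer with the configured width", {
  fe <- buildLossNetwork(lossNetConfig(depth = 3, kernelSize = 3,
                                       nFeatures = 32))
  expect_equal(nTapPoints(fe), 3L)
  fm <- extractFeatures(fe, vol16())
  fd <- featureDims(fm)
  expect_equal(unname(fd[, "C"]), rep(32L, 3))
  expect_equal(unname(fd[, "H"]), rep(16L, 3))  # same padding: spatial kept
  expect_equal(unname(fd[, "W"]), rep(16L, 3))
  expect_equal(unname(fd[, "D"]), rep(16L, 3))
})

test_that("pooling halves the spatial dims of later taps (shape law)", {
  fe <- buildLossNetwork(lossNetConfig(depth = 3, poolingAfter = 1L,
                                       nFeatures = 8))
  fd <- featureDims(extractFeatures(fe, Volume3D(rand_volume(c(32, 32, 32), 2))))
  expect_equal(unname(fd[, "H"]), c(32L, 16L, 16L))

  fe2 <- buildLossNetwork(lossNetConfig(depth = 3, poolingAfter = c(1L, 2L),
                                        nFeatures = 8))
  # taps are ReLU outputs before the pooling that follows the layer, so each
  # pooling halves every *later* tap
  fd2 <- featureDims(extractFeatures(fe2, vol16()))
  expect_equal(unname(fd2[, "H"]), c(16L, 8L, 4L))
  # general law: tap j halved once per pooling strictly before layer j
  fe3 <- buildLossNetwork(lossNetConfig(depth = 5, poolingAfter = c(1L, 3L),
                                        nFeatures = 4))
  fd3 <- featureDims(extractFeatures(fe3, vol16()))
  expect_equal(unname(fd3[, "H"]), c(16L, 8L, 8L, 4L, 4L))
})

test_that("all studied depths and kernels build and run", {
  for (depth in c(3L, 13L)) {
    fe <- buildLossNetwork(lossNetConfig(depth = depth, nFeatures = 4))
    expect_equal(nTapPoints(fe), depth)
    fm <- extractFeatures(fe, vol16())
    expect_equal(nTapPoints(fm), depth)
  }
  for (k in c(5L, 9L)) {
    fe <- buildLossNetwork(lossNetConfig(depth = 2, kernelSize = k,
                                         nFeatures = 4))
    fd <- featureDims(extractFeatures(fe, vol16()))
    expect_equal(unname(fd[, "H"]), c(16L, 16L))
  }
})

test_that("invalid loss-network configurations are rejected", {
  expect_error(lossNetConfig(depth = 3, poolingAfter = 4L), "1..depth",
               fixed = TRUE)
  expect_error(lossNetConfig(kernelSize = 4L), "odd")
  expect_error(lossNetConfig(initMethod = "he_normal"), "kaiming_uniform")
})

test_that("default-uniform weights honour the printed reciprocal fan-in bound", {
  fe <- buildLossNetwork(lossNetConfig(depth = 2, kernelSize = 3,
                                       nFeatures = 32,
                                       initMethod = "default_uniform",
                                       seed = 9))
  # layer 2: Cin = 32, 3x3x3 kernel -> k = 1/(32*27) = 1/864
  w <- fe@layers[[2]]$w$value
  k <- 1 / 864
  expect_length(w, 864 * 32)
  expect_true(all(abs(w) <= k))
  # consistent with uniformity: the sample spans most of the interval
  expect_gt(max(w) - min(w), 2 * k * 0.9)
  expect_true(all(abs(fe@layers[[2]]$b$value) <= k))

  # legacy variant widens the bound to 1/sqrt(864)
  fl <- buildLossNetwork(lossNetConfig(depth = 2, kernelSize = 3,
                                       nFeatures = 32,
                                       initMethod = "default_uniform",
                                       legacySqrtBound = TRUE, seed = 9))
  wl <- fl@layers[[2]]$w$value
  expect_gt(max(abs(wl)), k)
  expect_true(all(abs(wl) <= 1 / sqrt(864)))
})

test_that("xavier and kaiming draws match their closed-form variances", {
  fe <- buildLossNetwork(lossNetConfig(depth = 2, kernelSize = 3,
                                       nFeatures = 32,
                                       initMethod = "xavier_normal",
                                       seed = 4))
  w <- fe@layers[[2]]$w$value  # 27648 weights, fan_in = fan_out = 864
  expect_equal(var(as.numeric(w)), 2 / (864 + 864), tolerance = 0.1)
  expect_true(all(fe@layers[[2]]$b$value == 0))

  fk <- initializeWeights(fe, "kaiming_normal", seed = 4)
  expect_equal(var(as.numeric(fk@layers[[2]]$w$value)), 2 / 864,
               tolerance = 0.1)
})

test_that("initialization is deterministic in the seed and sensitive to it", {
  fe <- buildLossNetwork(lossNetConfig(depth = 3, nFeatures = 8))
  a <- initializeWeights(fe, "kaiming_uniform", seed = 7)
  b <- initializeWeights(fe, "kaiming_uniform", seed = 7)
  c <- initializeWeights(fe, "kaiming_uniform", seed = 8)
  expect_identical(parameterValues(a), parameterValues(b))
  expect_false(identical(parameterValues(a), parameterValues(c)))
  expect_error(initializeWeights(fe, "nope", seed = 1), "default_uniform")
})

test_that("VGG19-3D preset: 64-channel first conv, >= 8 taps on a 32^3 input", {
  fe <- buildPresetVGG19_3d(seed = 1)
  expect_equal(dim(fe@layers[[1]]$w$value)[5], 64L)
  fm <- extractFeatures(fe, Volume3D(rand_volume(c(32, 32, 32), 5)))
  expect_gte(nTapPoints(fm), 8L)
  fd <- featureDims(fm)
  expect_equal(unname(fd[1, "C"]), 64L)
  expect_equal(unname(fd[3, "C"]), 128L)  # channel progression 64,64,128,...
})

test_that("AlexNet-3D preset: 64-channel first conv; too-small inputs error", {
  fe <- buildPresetAlexNet3d(seed = 1)
  expect_equal(dim(fe@layers[[1]]$w$value)[5], 64L)
  fm <- extractFeatures(fe, Volume3D(rand_volume(c(48, 48, 48), 6)))
  expect_equal(nTapPoints(fm), 5L)
  expect_equal(unname(featureDims(fm)[2, "C"]), 192L)
  expect_error(extractFeatures(fe, Volume3D(rand_volume(c(4, 4, 4), 6))),
               "too small")
  # determinism under a fixed seed
  fe2 <- buildPresetAlexNet3d(seed = 1)
  expect_identical(parameterValues(fe), parameterValues(fe2))
})
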