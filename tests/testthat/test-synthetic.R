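test_that("phantom generation is deterministic and seed-sensitive", {
  cfg <- phantomConfig(shape = c(32, 32, 32), nTubes = 3)
  a <- generatePhantom(cfg, seed = 11)
  b <- generatePhantom(cfg, seed = 11)
  c <- generatePhantom(cfg, seed = 12)
  expect_identical(volData(a), volData(b))
  expect_false(identical(volData(a), volData(c)))
  expect_true(all(volData(a) >= 0 & volData(a) <= 1))
})

test_that("zero tubes gives a constant background volume", {
  cfg <- phantomConfig(shape = c(24, 24, 24), nTubes = 0,
                       backgroundLevel = 0.02)
  v <- generatePhantom(cfg, seed = 1)
  expect_true(all(volData(v) == 0.02))
  expect_equal(v@metadata$foregroundFraction, 0)
})

test_that("non-branching tubes form exactly nTubes 26-connected components", {
  cfg <- phantomConfig(shape = c(48, 48, 48), nTubes = 3, branchProb = 0,
                       radiusRange = c(1.5, 2.5))
  for (seed in c(1, 7)) {
    v <- generatePhantom(cfg, seed = seed)
    mask <- volData(v) > v@metadata$foregroundThreshold
    expect_equal(count_components_26(mask), 3L,
                 label = sprintf("components at seed %d", seed))
  }
})

test_that("default phantoms are sparse (foreground fraction < 10%)", {
  for (seed in 1:4) {
    v <- generatePhantom(phantomConfig(), seed = seed)
    expect_lt(v@metadata$foregroundFraction, 0.10)
    expect_gt(v@metadata$foregroundFraction, 0)
  }
})

test_that("phantom errors when the shape cannot contain the tubes", {
  expect_error(
    generatePhantom(phantomConfig(shape = c(16, 16, 16),
                                  radiusRange = c(6, 8)), seed = 1),
    "too small")
})

test_that("Rician corruption is deterministic, nonnegative, level-0 identity", {
  v <- generatePhantom(phantomConfig(shape = c(24, 24, 24)), seed = 3)
  n1 <- addRicianNoise(v, noiseSpec(0.10, seed = 5))
  n2 <- addRicianNoise(v, noiseSpec(0.10, seed = 5))
  n3 <- addRicianNoise(v, noiseSpec(0.10, seed = 6))
  expect_identical(volData(n1), volData(n2))
  expect_false(identical(volData(n1), volData(n3)))
  expect_true(all(volData(n1) >= 0))
  expect_identical(volData(addRicianNoise(v, noiseSpec(0, seed = 1))),
                   volData(v))
})

test_that("Rician noise rejects invalid levels and unnormalized input", {
  v <- Volume3D(array(0.5, c(16, 16, 16)))
  expect_error(noiseSpec(-0.1), "level")
  expect_error(noiseSpec(1.0), "level")
  big <- Volume3D(array(2, c(16, 16, 16)))
  expect_error(addRicianNoise(big, noiseSpec(0.1)), "normalized")
})

test_that("Rician moments match the closed forms at all four study levels", {
  # E[out^2] = A^2 + 2 sigma^2 for a constant volume of amplitude A
  for (level in c(0.01, 0.05, 0.10, 0.20)) {
    for (seed in 1:3) {
      A <- 1.0
      v <- Volume3D(array(A, c(32, 32, 32)))
      out <- volData(addRicianNoise(v, noiseSpec(level, seed = seed)))
      expect_equal(mean(out^2), A^2 + 2 * level^2,
                   tolerance = 0.01,
                   label = sprintf("second moment at level %g seed %d",
                                   level, seed))
    }
  }
  # zero signal: the magnitude is Rayleigh with mean sigma * sqrt(pi/2)
  sigma <- 0.10
  means <- vapply(1:3, function(seed) {
    z <- Volume3D(array(0, c(32, 32, 32)))
    mean(volData(addRicianNoise(z, noiseSpec(sigma, seed = seed), peak = 1)))
  }, numeric(1))
  expect_equal(mean(means), sigma * sqrt(pi / 2), tolerance = 0.02)
})
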