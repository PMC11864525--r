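test_that("ssim3d matches the sliding-window oracle and is exactly 1 at identity", {
  for (seed in 1:5) {
    a <- rand_volume(c(12, 12, 12), seed)
    b <- rand_volume(c(12, 12, 12), seed + 50)
    expect_equal(ssim3d(a, b), naive_ssim3d(a, b), tolerance = 1e-5)
    expect_identical(ssim3d(a, a), 1)
    expect_equal(ssim3d(a, b), ssim3d(b, a))
  }
  # window auto-shrinks on small volumes
  s <- rand_volume(c(7, 7, 7), 1)
  t <- rand_volume(c(7, 7, 7), 2)
  expect_equal(ssim3d(s, t), naive_ssim3d(s, t, win = 7), tolerance = 1e-5)
})

test_that("a constant offset strictly lowers SSIM (luminance penalty)", {
  a <- rand_volume(c(12, 12, 12), 3)
  expect_lt(ssim3d(a, a + 0.5), 1)
})

test_that("psnr follows its closed forms", {
  a <- array(0, c(4, 4, 4))
  b <- array(0.1, c(4, 4, 4))     # MSE = 0.01
  expect_equal(psnr(a, b, peak = 1), 20)
  expect_identical(psnr(a, a), Inf)
  expect_equal(psnr(a, b, peak = 2) - psnr(a, b, peak = 1), 10 * log10(4))
  expect_error(psnr(a, b, peak = 0), "peak")
})

test_that("psnr decreases monotonically as noise grows", {
  set.seed(4)
  a <- rand_volume(c(10, 10, 10), 4)
  eps <- array(rnorm(1000, sd = 0.05), c(10, 10, 10))
  vals <- vapply(c(0.5, 1, 2, 4), function(k) psnr(a, a + k * eps),
                 numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("mse matches the nested-loop oracle and its trivial cases", {
  a <- rand_volume(c(4, 4, 4), 1)
  b <- rand_volume(c(4, 4, 4), 2)
  expect_equal(mse(a, a), 0)
  expect_equal(mse(a, a + 0.3), 0.09)
  s <- 0
  for (i in 1:4) for (j in 1:4) for (k in 1:4) s <- s + (a[i,j,k] - b[i,j,k])^2
  expect_equal(mse(a, b), s / 64)
  expect_error(mse(a, rand_volume(c(4, 4, 5), 3)), "mismatch")
})

test_that("root crop takes a 52^3 cube at z offset 0 and in-plane offset 70", {
  set.seed(5)
  v <- Volume3D(array(runif(140 * 140 * 60), c(60, 140, 140)))
  cr <- cropEvalRegion(v, cropSpec("root"))
  expect_equal(dim(cr), c(52L, 52L, 52L))
  expect_identical(volData(cr), volData(v)[1:52, 71:122, 71:122])
  # window out of bounds names the axis
  small <- Volume3D(array(0, c(60, 100, 140)))
  expect_error(cropEvalRegion(small, cropSpec("root")), "axis y")
})

test_that("mra crop is a centered 68^3 cube; none is the identity", {
  set.seed(6)
  v <- Volume3D(array(runif(100 * 90 * 80), c(100, 90, 80)))
  cr <- cropEvalRegion(v, cropSpec("mra"))
  expect_equal(dim(cr), c(68L, 68L, 68L))
  start <- (c(100, 90, 80) - 68) %/% 2  # floor of the volume center offset
  expect_identical(volData(cr),
                   volData(v)[start[1] + 1:68, start[2] + 1:68,
                              start[3] + 1:68])
  expect_identical(volData(cropEvalRegion(v, cropSpec("none"))), volData(v))
  expect_error(cropEvalRegion(Volume3D(array(0, c(60, 70, 70))),
                              cropSpec("mra")), "axis z")
})

test_that("aggregation matches hand-computed means and stds", {
  one <- evalResult(data.frame(seed = 1, image = 1, ssim = 0.9, psnr = 30,
                               mse = 0.01))
  expect_equal(unname(one@aggregate$pooled$ssim), c(0.9, 0))
  # 3 seeds x 2 images, fabricated values
  grid <- expand.grid(seed = 1:3, image = 1:2)
  grid$ssim <- c(0.90, 0.80, 0.70, 0.92, 0.84, 0.72)
  grid$psnr <- c(30, 28, 26, 31, 29, 27)
  grid$mse <- c(0.01, 0.02, 0.03, 0.011, 0.021, 0.031)
  res <- lapply(1:3, function(s) evalResult(grid[grid$seed == s, ]))
  agg <- aggregateResults(res)
  expect_equal(unname(agg@aggregate$pooled$ssim["mean"]), mean(grid$ssim))
  expect_equal(unname(agg@aggregate$pooled$ssim["sd"]), sd(grid$ssim))
  seed_means <- tapply(grid$ssim, grid$seed, mean)
  expect_equal(unname(agg@aggregate$bySeed$ssim["mean"]),
               mean(seed_means))
  expect_equal(unname(agg@aggregate$bySeed$ssim["sd"]), sd(seed_means))
  # two seeds with per-seed means m1, m2 -> seed-level mean (m1+m2)/2
  agg2 <- aggregateResults(res[1:2])
  expect_equal(unname(agg2@aggregate$bySeed$ssim["mean"]),
               mean(seed_means[1:2]))
  expect_error(aggregateResults(list()), "empty")
})

test_that("infinite PSNR values are excluded from means with a warning", {
  df <- data.frame(seed = 1, image = 1:2, ssim = c(1, 0.9),
                   psnr = c(Inf, 30), mse = c(0, 0.01))
  expect_warning(r <- evalResult(df), "infinite")
  expect_equal(unname(r@aggregate$pooled$psnr["mean"]), 30)
})

test_that("metrics commute with cropping when the volume equals its crop", {
  set.seed(8)
  a <- Volume3D(array(runif(68^3), c(68, 68, 68)))
  b <- Volume3D(array(runif(68^3), c(68, 68, 68)))
  m1 <- evalMetrics(a, b, crop = cropSpec("mra"))
  m2 <- evalMetrics(a, b, crop = cropSpec("none"))
  expect_equal(m1, m2)
})
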