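test_that("DnCNN has exactly 5 conv layers with 64 hidden channels", {
  d <- buildDnCNN()
  m <- d@modules
  convs <- c(list(m$head), lapply(m$blocks, `[[`, "conv"), list(m$tail))
  expect_length(convs, 5L)
  expect_equal(dim(m$head$w$value), c(3L, 3L, 3L, 1L, 64L))
  for (blk in m$blocks)
    expect_equal(dim(blk$conv$w$value), c(3L, 3L, 3L, 64L, 64L))
  expect_equal(dim(m$tail$w$value), c(3L, 3L, 3L, 64L, 1L))
  # head conv + 3 block convs + tail conv, batch-norm affine pairs:
  # 1792 + 3*(110656 + 128) + 1729 = 335873
  expect_identical(parameterCount(d), 335873)
})

test_that("ResNet has exactly 5 residual blocks and zeroed blocks are identities", {
  d <- buildResNet()
  expect_length(d@modules$blocks, 5L)
  expect_identical(parameterCount(d), 668232)
  up <- asNamespace("uperc3d")
  # zero every residual-block conv: each block must reduce to the identity
  for (blk in d@modules$blocks) {
    blk$conv$w$value <- 0 * blk$conv$w$value
    blk$conv$b$value <- 0 * blk$conv$b$value
    blk$bn$beta$value <- 0 * blk$bn$beta$value
  }
  x <- array(rnorm(8 * 8 * 8 * 64), c(8, 8, 8, 64, 1))
  h <- up$ag_const(x)
  blk <- d@modules$blocks[[1]]
  inner <- up$ag_prelu(up$ag_batchnorm(up$.apply_conv(blk$conv, h, FALSE),
                                       blk$bn$gamma, blk$bn$beta,
                                       blk$bn$state, training = FALSE),
                       blk$act$alpha)
  out <- up$ag_add(h, inner)
  expect_equal(out$value, x)
})

test_that("transformer head emits 8 channels; feed-forward widths are 16 and 32", {
  d <- buildTransformer3d()
  expect_equal(dim(d@modules$head$w$value)[4:5], c(1L, 8L))
  blk <- d@modules$blocks[[1]]
  expect_equal(dim(blk$ff1$w$value)[4:5], c(8L, 16L))
  expect_equal(dim(blk$ff2$w$value)[4:5], c(16L, 32L))
  expect_length(d@modules$blocks, 4L)
  expect_identical(parameterCount(d), 91421)
})

test_that("the MDTA attention matrix is channels x channels with unit row sums", {
  d <- buildTransformer3d()
  v <- Volume3D(rand_volume(c(10, 10, 10), 1))
  for (blk in c(1L, 3L)) {
    A <- attentionMatrix(d, v, block = blk)
    expect_equal(dim(A), c(8L, 8L))  # channels^2, never voxels^2
    expect_equal(unname(rowSums(A)), rep(1, 8), tolerance = 1e-12)
    expect_true(all(A >= 0))
  }
})

test_that("all three architectures are shape-preserving", {
  set.seed(2)
  sizes <- list(dncnn = c(20, 16, 24), resnet = c(16, 20, 16),
                transformer = c(16, 16, 20))
  for (arch in names(sizes)) {
    d <- buildDenoiser(denoiserConfig(arch), seed = 3)
    v <- Volume3D(rand_volume(sizes[[arch]], 7))
    out <- denoise(d, v)
    expect_equal(dim(out), dim(v), label = arch)
    expect_true(all(volData(out) >= 0 & volData(out) <= 1), label = arch)
  }
})

test_that("residual output with a zeroed tail returns the input unchanged", {
  d <- buildDnCNN(denoiserConfig("dncnn", residualOutput = TRUE))
  d@modules$tail$w$value <- 0 * d@modules$tail$w$value
  d@modules$tail$b$value <- 0 * d@modules$tail$b$value
  v <- Volume3D(rand_volume(c(12, 12, 12), 9))
  expect_equal(volData(denoise(d, v)), volData(v))
})

test_that("builds are deterministic in the seed", {
  for (arch in c("dncnn", "transformer")) {
    a <- buildDenoiser(denoiserConfig(arch), seed = 5)
    b <- buildDenoiser(denoiserConfig(arch), seed = 5)
    c <- buildDenoiser(denoiserConfig(arch), seed = 6)
    expect_identical(parameterValues(a), parameterValues(b))
    expect_false(identical(parameterValues(a), parameterValues(c)))
  }
})

test_that("too-small volumes are rejected at inference", {
  d <- buildDnCNN()
  expect_error(denoise(d, Volume3D(array(0.1, c(4, 4, 4)))), ">= 8")
})
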