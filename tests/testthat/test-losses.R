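# helper: copy an extractor's conv weights into the plain-list form the
# nested-loop oracle consumes
extractor_layers <- function(fe) {
  lapply(fe@layers, function(ly) list(w = ly$w$value, b = ly$b$value))
}

test_that("perceptual loss matches the nested-loop brute force on small nets", {
  for (seed in 1:20) {
    set.seed(seed)
    depth <- sample(1:2, 1)
    feat <- sample(2:3, 1)
    edge <- sample(4:6, 1)
    fe <- buildLossNetwork(lossNetConfig(depth = depth, kernelSize = 3,
                                         nFeatures = feat, seed = seed))
    a <- rand_volume(c(edge, edge, edge), seed * 101)
    b <- rand_volume(c(edge, edge, edge), seed * 101 + 1)
    got <- perceptualLoss(fe, Volume3D(a), Volume3D(b))
    want <- naive_perceptual(naive_simple_features(extractor_layers(fe), a),
                             naive_simple_features(extractor_layers(fe), b))
    expect_equal(got@value, want, tolerance = 1e-6)
    expect_equal(sum(got@perLayer), got@value)
    expect_true(all(got@perLayer >= 0))
  }
})

test_that("an identity 1x1x1 linear extractor collapses the loss to the MSE", {
  fe <- buildLossNetwork(lossNetConfig(depth = 1, kernelSize = 1,
                                       nFeatures = 1))
  fe@layers[[1]]$w$value <- array(1, dim = c(1, 1, 1, 1, 1))
  fe@layers[[1]]$b$value <- 0
  fe@layers[[1]]$act <- "none"
  for (seed in 1:20) {
    a <- rand_volume(c(5, 4, 6), seed)
    b <- rand_volume(c(5, 4, 6), seed + 1000)
    expect_equal(perceptualLoss(fe, Volume3D(a), Volume3D(b))@value,
                 mean((a - b)^2), tolerance = 1e-6)
  }
})

test_that("perceptual loss is symmetric, zero at identity, shape-checked", {
  fe <- buildLossNetwork(lossNetConfig(depth = 2, nFeatures = 4))
  a <- Volume3D(rand_volume(c(8, 8, 8), 1))
  b <- Volume3D(rand_volume(c(8, 8, 8), 2))
  pl <- perceptualLoss(fe, a, b)
  expect_equal(pl@value, perceptualLoss(fe, b, a)@value)
  id <- perceptualLoss(fe, a, a)
  expect_equal(id@value, 0)
  expect_true(all(id@perLayer == 0))
  expect_error(perceptualLoss(fe, a, Volume3D(rand_volume(c(8, 8, 4), 3))),
               "mismatch")
})

test_that("all-zero input through a zero-bias extractor gives all-zero maps", {
  fe <- buildLossNetwork(lossNetConfig(depth = 2, nFeatures = 4,
                                       initMethod = "xavier_normal"))
  fm <- extractFeatures(fe, Volume3D(array(0, c(8, 8, 8))))
  for (m in fm@maps) expect_true(all(m == 0))
})

test_that("gradients reach the prediction but never the frozen extractor", {
  up <- asNamespace("uperc3d")
  fe <- buildLossNetwork(lossNetConfig(depth = 2, nFeatures = 4))
  pred <- up$ag_param(rand_volume(c(6, 6, 6, 1, 1), 5))
  target <- rand_volume(c(6, 6, 6, 1, 1), 6)
  loss <- up$.pl_node(fe, pred, target)
  up$agBackward(loss)
  expect_false(is.null(pred$grad))
  expect_gt(max(abs(pred$grad)), 0)
  for (ly in fe@layers) {
    expect_false(ly$w$requires)
    expect_null(ly$w$grad)
    expect_null(ly$b$grad)
  }
})

test_that("l1 loss matches the direct mean absolute difference", {
  a <- Volume3D(rand_volume(c(4, 4, 4), 1))
  b <- Volume3D(rand_volume(c(4, 4, 4), 2))
  expect_equal(l1Loss(a, a), 0)
  expect_equal(l1Loss(a, Volume3D(pmin(volData(a) + 0.5, Inf))), 0.5)
  # nested-loop oracle
  s <- 0
  for (i in 1:4) for (j in 1:4) for (k in 1:4)
    s <- s + abs(volData(a)[i, j, k] - volData(b)[i, j, k])
  expect_equal(l1Loss(a, b), s / 64)
  expect_error(l1Loss(a, Volume3D(rand_volume(c(4, 4, 5), 3))), "mismatch")
})

test_that("SSIM objective is 1 - ssim3d, zero at identity, large for inverted", {
  a <- Volume3D(rand_volume(c(12, 12, 12), 7))
  b <- Volume3D(rand_volume(c(12, 12, 12), 8))
  expect_equal(ssimObjective(a, a), 0)
  expect_equal(ssimObjective(a, b), 1 - ssim3d(a, b), tolerance = 1e-6)
  # inverted binary volume: objective near the top of the range
  set.seed(9)
  bin <- array(rbinom(12^3, 1, 0.5), c(12, 12, 12))
  inv <- 1 - bin
  expect_gt(ssimObjective(Volume3D(bin * 1.0), Volume3D(inv * 1.0)), 1)
})
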