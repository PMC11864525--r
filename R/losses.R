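# losses: the untrained perceptual loss and the comparison losses.

# Volume3D (z,y,x) -> 5D activation array (z,y,x,channel=1,sample=1)
.vol_to_batch <- function(vol) {
  d <- if (is(vol, "Volume3D")) dim(vol@data) else dim(vol)
  a <- if (is(vol, "Volume3D")) vol@data else vol
  array(a, dim = c(d, 1L, 1L))
}

.check_same_dims <- function(a, b) {
  da <- if (is(a, "Volume3D")) dim(a@data) else dim(a)
  db <- if (is(b, "Volume3D")) dim(b@data) else dim(b)
  if (!identical(da, db))
    stop(sprintf("dimension mismatch: %s vs %s",
                 paste(da, collapse = "x"), paste(db, collapse = "x")))
  invisible(NULL)
}

#' Extract per-layer feature maps from a frozen loss network
#'
#' Runs the extractor forward and returns the activations at every tap point
#' together with their recorded (C, H, W, D). No parameter of the extractor
#' is modified. Pooled axes with odd extent are floor-pooled (the trailing
#' voxel is dropped).
#'
#' @param extractor a [FeatureExtractor-class].
#' @param vol a [Volume3D-class] (or a plain 3D array).
#' @return A [FeatureMaps-class].
#' @examples
#' fe <- buildLossNetwork(lossNetConfig(depth = 3))
#' fm <- extractFeatures(fe, Volume3D(array(runif(16^3), c(16, 16, 16))))
#' featureDims(fm)
#' @export
extractFeatures <- function(extractor, vol) {
  stopifnot(is(extractor, "FeatureExtractor"))
  x <- .vol_to_batch(vol)
  taps <- .forward_extractor(extractor, ag_const(x))
  maps <- lapply(taps, function(t) {
    v <- t$value
    d <- dim(v)
    array(v, dim = d[1:4])  # drop the singleton sample axis
  })
  fd <- t(vapply(maps, function(m) {
    d <- dim(m)
    c(C = d[4L], H = d[1L], W = d[2L], D = d[3L])
  }, integer(4)))
  new("FeatureMaps", maps = maps, featureDims = fd)
}

# node-level perceptual loss used by training; `target` is a plain 5D array.
# Each tap contributes ||phi(pred) - phi(target)||^2 / (C*H*W*D), averaged
# over the batch.
.pl_node <- function(extractor, pred_node, target, single = FALSE) {
  taps_p <- .forward_extractor(extractor, pred_node, single = single)
  taps_t <- .forward_extractor(extractor, ag_const(target), single = single)
  total <- NULL
  for (j in seq_along(taps_p)) {
    d <- ag_sub(taps_p[[j]], taps_t[[j]])
    cnt <- prod(dim(d$value)[1:4])
    nb <- dim(d$value)[5L]
    term <- ag_scale(ag_sum(ag_mul(d, d)), 1 / (cnt * nb))
    total <- if (is.null(total)) term else ag_add(total, term)
  }
  total
}

#' Untrained perceptual loss between two volumes
#'
#' The layer-normalized feature-space squared error
#' \deqn{\sum_j \frac{1}{C_j H_j W_j D_j} \lVert \phi_j(\hat y) - \phi_j(y)
#' \rVert_2^2,}
#' where \eqn{\phi_j} is the activation of the j-th tap point of the frozen
#' extractor. The squared norm runs over all entries of the feature map and
#' is normalized by that same entry count. Symmetric in its two image
#' arguments; zero iff the feature maps agree. During training, gradients
#' flow to the predicted image only — the extractor parameters receive none.
#'
#' @param extractor a [FeatureExtractor-class].
#' @param pred,target [Volume3D-class] objects (or 3D arrays) of identical
#'   dims.
#' @return A [LossValue-class] with the total and per-layer contributions.
#' @examples
#' fe <- buildLossNetwork(lossNetConfig(depth = 2, nFeatures = 4))
#' a <- Volume3D(array(runif(8^3), c(8, 8, 8)))
#' perceptualLoss(fe, a, a)@value  # 0 at identity
#' @export
perceptualLoss <- function(extractor, pred, target) {
  stopifnot(is(extractor, "FeatureExtractor"))
  .check_same_dims(pred, target)
  fp <- extractFeatures(extractor, pred)
  ft <- extractFeatures(extractor, target)
  per <- vapply(seq_along(fp@maps), function(j) {
    d <- fp@maps[[j]] - ft@maps[[j]]
    sum(d * d) / length(d)
  }, numeric(1))
  new("LossValue", value = sum(per), perLayer = per)
}

#' Mean absolute voxel difference
#'
#' @param pred,target [Volume3D-class] objects (or arrays) of identical dims.
#' @return Nonnegative scalar, zero iff the volumes are equal.
#' @export
l1Loss <- function(pred, target) {
  .check_same_dims(pred, target)
  a <- if (is(pred, "Volume3D")) pred@data else pred
  b <- if (is(target, "Volume3D")) target@data else target
  mean(abs(a - b))
}

.l1_node <- function(pred_node, target) {
  ag_mean(ag_abs(ag_sub(pred_node, ag_const(target))))
}

# Gaussian window weights, normalized to sum 1
.gauss_weights <- function(size, sigma) {
  half <- (size - 1) / 2
  w <- exp(-((-half:half)^2) / (2 * sigma^2))
  w / sum(w)
}

# differentiable SSIM between a 5D node and a constant 5D array, valid-mode
# Gaussian windows; returns the scalar mean-SSIM node.
.ssim_node <- function(x, y, dataRange = 1, windowSize = 11L, sigma = 1.5,
                       single = FALSE) {
  xd <- dim(agValue(x))
  win <- min(windowSize, xd[1:3])
  if (win %% 2L == 0L) win <- win - 1L
  if (win < 1L) stop("SSIM window does not fit inside the volume")
  g <- .gauss_weights(win, sigma)
  k1 <- ag_const(array(g, dim = c(win, 1L, 1L, 1L, 1L)))
  k2 <- ag_const(array(g, dim = c(1L, win, 1L, 1L, 1L)))
  k3 <- ag_const(array(g, dim = c(1L, 1L, win, 1L, 1L)))
  b0 <- ag_const(0)
  gm <- function(t) {
    t <- ag_conv3d(t, k1, b0, pad = c(0L, 0L, 0L), single = single)
    t <- ag_conv3d(t, k2, b0, pad = c(0L, 0L, 0L), single = single)
    ag_conv3d(t, k3, b0, pad = c(0L, 0L, 0L), single = single)
  }
  C1 <- (0.01 * dataRange)^2
  C2 <- (0.03 * dataRange)^2
  x <- as_node(x); y <- as_node(y)
  mx <- gm(x); my <- gm(y)
  sxx <- ag_sub(gm(ag_mul(x, x)), ag_mul(mx, mx))
  syy <- ag_sub(gm(ag_mul(y, y)), ag_mul(my, my))
  sxy <- ag_sub(gm(ag_mul(x, y)), ag_mul(mx, my))
  num <- ag_mul(ag_shift(ag_scale(ag_mul(mx, my), 2), C1),
                ag_shift(ag_scale(sxy, 2), C2))
  den <- ag_mul(ag_shift(ag_add(ag_mul(mx, mx), ag_mul(my, my)), C1),
                ag_shift(ag_add(sxx, syy), C2))
  ag_mean(ag_div(num, den))
}

.ssim_objective_node <- function(pred_node, target, dataRange = 1,
                                 single = FALSE) {
  ag_shift(ag_scale(.ssim_node(pred_node, ag_const(target),
                               dataRange = dataRange, single = single), -1), 1)
}

#' SSIM training objective (1 - SSIM)
#'
#' Returns \code{1 - ssim3d(pred, target)}, so that minimization maximizes
#' structural similarity; the value lies in [0, 2] and is differentiable.
#'
#' @param pred,target [Volume3D-class] objects (or arrays) of identical dims.
#' @param dataRange intensity range of the data (1 after normalization).
#' @return Scalar objective value.
#' @export
ssimObjective <- function(pred, target, dataRange = 1) {
  .check_same_dims(pred, target)
  1 - ssim3d(pred, target, dataRange = dataRange)
}
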