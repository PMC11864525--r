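# denoisers: the three 3D denoising architectures.

# trainable conv init: U(-k, k) with k = 1/sqrt(fan_in) for weights and
# biases (the usual feed-forward default)
.trainable_conv <- function(K, Cin, Cout, stride = 1L, pad = "same") {
  K <- rep(K, length.out = 3L)
  fan_in <- Cin * prod(K)
  k <- 1 / sqrt(fan_in)
  list(type = "conv",
       w = ag_param(array(stats::runif(prod(K) * Cin * Cout, -k, k),
                          dim = c(K, Cin, Cout))),
       b = ag_param(stats::runif(Cout, -k, k)),
       stride = as.integer(rep(stride, length.out = 3L)), pad = pad)
}

.bn_module <- function(C) {
  state <- new.env(parent = emptyenv())
  state$running_mean <- rep(0, C)
  state$running_var <- rep(1, C)
  list(type = "bn", gamma = ag_param(rep(1, C)), beta = ag_param(rep(0, C)),
       state = state)
}

.prelu_module <- function(init = 0.25) {
  list(type = "prelu", alpha = ag_param(init))
}

.apply_conv <- function(m, x, single) {
  ag_conv3d(x, m$w, m$b, stride = m$stride, pad = m$pad, single = single)
}

.apply_bn <- function(m, x, training) {
  ag_batchnorm(x, m$gamma, m$beta, m$state, training = training)
}

# recursively collect trainable parameter nodes from a module tree
.collect_params <- function(x) {
  if (is_node(x)) return(if (x$requires) list(x) else list())
  if (is.list(x)) return(do.call(c, lapply(x, .collect_params)))
  list()
}

#' Build a 3D denoising network
#'
#' Dispatches on \code{config@architecture}; see [buildDnCNN()],
#' [buildResNet()] and [buildTransformer3d()].
#'
#' @param config a [DenoiserConfig-class].
#' @param seed integer seed for the trainable weights.
#' @return A [Denoiser-class].
#' @export
buildDenoiser <- function(config, seed = 1L) {
  stopifnot(is(config, "DenoiserConfig"))
  validObject(config)
  switch(config@architecture,
         dncnn = buildDnCNN(config, seed),
         resnet = buildResNet(config, seed),
         transformer = buildTransformer3d(config, seed))
}

#' DnCNN: feed-forward convolutional denoiser
#'
#' One convolution (64 feature maps, kernel 3) with ReLU, then three blocks
#' of convolution (64 maps, kernel 3) + ReLU + batch normalization, then a
#' final kernel-3 convolution with one output channel: exactly five
#' convolutional layers under the defaults, all same-padding, so the output
#' has the input's spatial dims. By default the clean image is predicted
#' directly; \code{residualOutput = TRUE} subtracts the prediction from the
#' input instead.
#'
#' @param config a [DenoiserConfig-class] (architecture "dncnn").
#' @param seed integer seed.
#' @return A [Denoiser-class].
#' @export
buildDnCNN <- function(config = denoiserConfig("dncnn"), seed = 1L) {
  C <- config@dncnnChannels
  with_seed(seed, {
    modules <- list(
      head = .trainable_conv(3L, 1L, C),
      blocks = lapply(seq_len(config@dncnnBlocks), function(i)
        list(conv = .trainable_conv(3L, C, C), bn = .bn_module(C))),
      tail = .trainable_conv(3L, C, 1L)
    )
    new("Denoiser", architecture = "dncnn", modules = modules,
        config = config)
  })
}

#' Residual CNN denoiser
#'
#' A head convolution with PReLU, five residual blocks (convolution +
#' batch normalization + PReLU, each wrapped by an additive identity skip),
#' a tail convolution + batch normalization + PReLU, and a final kernel-3
#' projection to one channel. Shape-preserving.
#'
#' @param config a [DenoiserConfig-class] (architecture "resnet").
#' @param seed integer seed.
#' @return A [Denoiser-class].
#' @export
buildResNet <- function(config = denoiserConfig("resnet"), seed = 1L) {
  C <- config@resnetChannels
  with_seed(seed, {
    modules <- list(
      head = .trainable_conv(3L, 1L, C),
      headAct = .prelu_module(),
      blocks = lapply(seq_len(config@resnetBlocks), function(i)
        list(conv = .trainable_conv(3L, C, C), bn = .bn_module(C),
             act = .prelu_module())),
      tail = .trainable_conv(3L, C, C),
      tailBn = .bn_module(C),
      tailAct = .prelu_module(),
      proj = .trainable_conv(3L, C, 1L)
    )
    new("Denoiser", architecture = "resnet", modules = modules,
        config = config)
  })
}

#' Sequential 3D transformer denoiser with channel attention
#'
#' A head convolution (kernel 3, 8 feature maps) followed by sequential
#' transformer blocks — no spatial down- or up-sampling — and a 1-channel
#' tail convolution. Each block applies multi-head "transposed" attention
#' (MDTA): queries, keys and values are formed per channel by kernel-3
#' convolutions, spatial dims are flattened to length H*W*D, channels are
#' L2-normalized and a channels x channels attention matrix (softmax of the
#' temperature-scaled channel similarity) mixes the values, so cost is
#' quadratic in channels but linear in voxels. The following gated
#' feed-forward expands with two kernel-3 convolutions (16 then 32 maps),
#' gates by the elementwise product of the two 16-channel halves, and
#' projects back with a 1x1x1 convolution; both sub-blocks carry residual
#' connections.
#'
#' @param config a [DenoiserConfig-class] (architecture "transformer").
#' @param seed integer seed.
#' @return A [Denoiser-class].
#' @export
buildTransformer3d <- function(config = denoiserConfig("transformer"),
                               seed = 1L) {
  C <- config@tfChannels
  ff <- config@tfFF
  H <- config@tfHeads
  with_seed(seed, {
    modules <- list(
      head = .trainable_conv(3L, 1L, C),
      blocks = lapply(seq_len(config@tfBlocks), function(i) list(
        q = .trainable_conv(3L, C, C),
        k = .trainable_conv(3L, C, C),
        v = .trainable_conv(3L, C, C),
        temps = lapply(seq_len(H), function(h) ag_param(1)),
        attProj = .trainable_conv(1L, C, C),
        ff1 = .trainable_conv(3L, C, ff[1L]),
        ff2 = .trainable_conv(3L, ff[1L], ff[2L]),
        ffProj = .trainable_conv(1L, ff[2L] %/% 2L, C)
      )),
      tail = .trainable_conv(3L, C, 1L)
    )
    new("Denoiser", architecture = "transformer", modules = modules,
        config = config)
  })
}

# one MDTA + gated feed-forward block
.tf_block <- function(blk, h, heads, single) {
  q <- .apply_conv(blk$q, h, single)
  k <- .apply_conv(blk$k, h, single)
  v <- .apply_conv(blk$v, h, single)
  C <- dim(h$value)[4L]
  if (heads == 1L) {
    att <- ag_mdta(q, k, v, blk$temps[[1L]])
  } else {
    per <- C %/% heads
    parts <- lapply(seq_len(heads), function(hh) {
      idx <- (hh - 1L) * per + seq_len(per)
      ag_mdta(ag_slice_channels(q, idx), ag_slice_channels(k, idx),
              ag_slice_channels(v, idx), blk$temps[[hh]])
    })
    att <- ag_concat_channels(parts)
  }
  h <- ag_add(h, .apply_conv(blk$attProj, att, single))
  e1 <- .apply_conv(blk$ff1, h, single)
  e2 <- .apply_conv(blk$ff2, e1, single)
  half <- dim(e2$value)[4L] %/% 2L
  gated <- ag_mul(ag_slice_channels(e2, seq_len(half)),
                  ag_slice_channels(e2, half + seq_len(half)))
  ag_add(h, .apply_conv(blk$ffProj, gated, single))
}

# forward pass; x is a 5D node or array, returns a 5D node
.forward_denoiser <- function(den, x, training = FALSE, single = FALSE) {
  x <- as_node(x)
  m <- den@modules
  out <- switch(den@architecture,
    dncnn = {
      h <- ag_relu(.apply_conv(m$head, x, single))
      for (blk in m$blocks)
        h <- .apply_bn(blk$bn, ag_relu(.apply_conv(blk$conv, h, single)),
                       training)
      .apply_conv(m$tail, h, single)
    },
    resnet = {
      h <- ag_prelu(.apply_conv(m$head, x, single), m$headAct$alpha)
      for (blk in m$blocks) {
        inner <- ag_prelu(.apply_bn(blk$bn,
                                    .apply_conv(blk$conv, h, single),
                                    training),
                          blk$act$alpha)
        h <- ag_add(h, inner)
      }
      h <- ag_prelu(.apply_bn(m$tailBn, .apply_conv(m$tail, h, single),
                              training),
                    m$tailAct$alpha)
      .apply_conv(m$proj, h, single)
    },
    transformer = {
      h <- .apply_conv(m$head, x, single)
      for (blk in m$blocks)
        h <- .tf_block(blk, h, den@config@tfHeads, single)
      .apply_conv(m$tail, h, single)
    })
  if (den@config@residualOutput) out <- ag_sub(x, out)
  out
}

#' MDTA attention matrix of one transformer block for a given input
#'
#' Runs the network forward (eval mode) up to the requested block and returns
#' the channels x channels attention matrix (one per head). Each row is a
#' softmax distribution and sums to 1.
#'
#' @param den a transformer [Denoiser-class].
#' @param vol a [Volume3D-class] input.
#' @param block 1-based block index.
#' @return A matrix (single head) or list of per-head matrices.
#' @export
attentionMatrix <- function(den, vol, block = 1L) {
  stopifnot(is(den, "Denoiser"), den@architecture == "transformer")
  x <- ag_const(.vol_to_batch(vol))
  m <- den@modules
  h <- .apply_conv(m$head, x, FALSE)
  heads <- den@config@tfHeads
  for (i in seq_len(block - 1L))
    h <- .tf_block(m$blocks[[i]], h, heads, FALSE)
  blk <- m$blocks[[block]]
  q <- .apply_conv(blk$q, h, FALSE)$value
  k <- .apply_conv(blk$k, h, FALSE)$value
  C <- dim(q)[4L]
  L <- prod(dim(q)[1:3])
  per <- C %/% heads
  mats <- lapply(seq_len(heads), function(hh) {
    idx <- (hh - 1L) * per + seq_len(per)
    Q <- matrix(q[, , , idx, 1], L, per)
    K <- matrix(k[, , , idx, 1], L, per)
    .channel_attention(Q, K, as.numeric(blk$temps[[hh]]$value))$A
  })
  if (heads == 1L) mats[[1L]] else mats
}

#' @rdname parameterCount
setMethod("parameterCount", "Denoiser", function(x) {
  sum(vapply(.collect_params(x@modules), function(p) length(p$value),
             numeric(1)))
})

#' @rdname parameterValues
setMethod("parameterValues", "Denoiser", function(x) {
  ps <- .collect_params(x@modules)
  unlist(lapply(seq_along(ps), function(i) {
    v <- as.numeric(ps[[i]]$value)
    names(v) <- sprintf("p%d.%d", i, seq_along(v))
    v
  }))
})
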