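# loss_networks: frozen, randomly initialized 3D feature extractors.

# draw one conv layer's weights; `method` is one of .init_methods.
# fan_in = Cin * prod(K), fan_out = Cout * prod(K). Biases follow the same
# uniform law for default_uniform and are zero for the kaiming/xavier schemes
# (their standard convention).
.init_conv <- function(K, Cin, Cout, method, legacy_sqrt = FALSE) {
  K <- rep(K, length.out = 3L)
  fan_in <- Cin * prod(K)
  fan_out <- Cout * prod(K)
  nw <- prod(K) * Cin * Cout
  w <- switch(method,
    kaiming_uniform = stats::runif(nw, -sqrt(6 / fan_in), sqrt(6 / fan_in)),
    kaiming_normal = stats::rnorm(nw, 0, sqrt(2 / fan_in)),
    xavier_uniform = stats::runif(nw, -sqrt(6 / (fan_in + fan_out)),
                                  sqrt(6 / (fan_in + fan_out))),
    xavier_normal = stats::rnorm(nw, 0, sqrt(2 / (fan_in + fan_out))),
    default_uniform = {
      k <- if (legacy_sqrt) 1 / sqrt(fan_in) else 1 / fan_in
      stats::runif(nw, -k, k)
    },
    stop(paste0("unknown initialization method '", method,
                "'; valid methods are: ",
                paste(.init_methods, collapse = ", ")))
  )
  b <- if (method == "default_uniform") {
    k <- if (legacy_sqrt) 1 / sqrt(fan_in) else 1 / fan_in
    stats::runif(Cout, -k, k)
  } else rep(0, Cout)
  list(w = array(w, dim = c(K, Cin, Cout)), b = b)
}

.conv_layer <- function(K, Cin, Cout, method, legacy_sqrt, stride = 1L,
                        pad = "same", act = "relu", pool = NULL,
                        trainable = FALSE) {
  init <- .init_conv(K, Cin, Cout, method, legacy_sqrt)
  list(w = ag_param(init$w, requires_grad = trainable),
       b = ag_param(init$b, requires_grad = trainable),
       stride = as.integer(rep(stride, length.out = 3L)), pad = pad,
       act = act, pool = pool, K = rep(K, length.out = 3L),
       Cin = Cin, Cout = Cout)
}

#' Build a frozen loss network
#'
#' The "simple" preset stacks \code{depth} same-padding, stride-1
#' convolutions (each followed by ReLU), with a window-2/stride-2 max-pooling
#' inserted after the layers named in \code{poolingAfter}; the first layer
#' takes one input channel, every layer outputs \code{nFeatures} channels.
#' Tap points are all ReLU outputs (taken before any pooling that follows the
#' layer), optionally capped by \code{tapLimit}. Weights are drawn per
#' \code{initMethod} under \code{seed}; the extractor is frozen: its
#' parameters receive no gradient and are bit-identical before and after any
#' training run. Odd input extents are floor-pooled (trailing voxels
#' dropped).
#'
#' @param config a [LossNetConfig-class].
#' @return A [FeatureExtractor-class].
#' @examples
#' fe <- buildLossNetwork(lossNetConfig(depth = 3, kernelSize = 3))
#' nTapPoints(fe)
#' @export
buildLossNetwork <- function(config) {
  stopifnot(is(config, "LossNetConfig"))
  validObject(config)
  if (config@preset == "vgg19_3d")
    return(buildPresetVGG19_3d(config@seed, tapLimit = config@tapLimit,
                               initMethod = config@initMethod))
  if (config@preset == "alexnet_3d")
    return(buildPresetAlexNet3d(config@seed, tapLimit = config@tapLimit,
                                initMethod = config@initMethod))
  with_seed(config@seed, {
    layers <- vector("list", config@depth)
    for (i in seq_len(config@depth)) {
      pool <- if (i %in% config@poolingAfter)
        list(window = 2L, stride = 2L) else NULL
      layers[[i]] <- .conv_layer(config@kernelSize,
                                 Cin = if (i == 1L) 1L else config@nFeatures,
                                 Cout = config@nFeatures,
                                 method = config@initMethod,
                                 legacy_sqrt = config@legacySqrtBound,
                                 pool = pool)
    }
    taps <- seq_len(config@depth)
    if (!is.na(config@tapLimit)) taps <- utils::head(taps, config@tapLimit)
    new("FeatureExtractor", layers = layers, tapLayers = taps,
        config = config)
  })
}

#' Re-draw the weights of a loss network
#'
#' All five schemes are fan-based: Kaiming uses the fan-in, Xavier the mean
#' of fan-in and fan-out (uniform or normal variants); "default_uniform"
#' draws every weight and bias from U(-k, k) with \code{k = 1 / (Cin * prod(K))}
#' computed per layer, exactly as printed in the source description of the
#' method (the conventional reciprocal-square-root bound is available via
#' the config's \code{legacySqrtBound} flag).
#'
#' @param extractor a [FeatureExtractor-class].
#' @param method one of "kaiming_uniform", "kaiming_normal",
#'   "xavier_uniform", "xavier_normal", "default_uniform".
#' @param seed integer seed; equal seeds give bit-identical weights.
#' @return A new [FeatureExtractor-class] with re-drawn frozen weights.
#' @export
initializeWeights <- function(extractor, method, seed) {
  stopifnot(is(extractor, "FeatureExtractor"))
  if (!method %in% .init_methods)
    stop(paste0("unknown initialization method '", method,
                "'; valid methods are: ",
                paste(.init_methods, collapse = ", ")))
  cfg <- extractor@config
  with_seed(seed, {
    layers <- extractor@layers
    for (i in seq_along(layers)) {
      ly <- layers[[i]]
      init <- .init_conv(ly$K, ly$Cin, ly$Cout, method, cfg@legacySqrtBound)
      ly$w <- ag_param(init$w, requires_grad = FALSE)
      ly$b <- ag_param(init$b, requires_grad = FALSE)
      layers[[i]] <- ly
    }
    cfg@initMethod <- method
    cfg@seed <- as.integer(seed)
    new("FeatureExtractor", layers = layers, tapLayers = extractor@tapLayers,
        config = cfg)
  })
}

#' 3D translation of the VGG19 convolutional stack, untrained
#'
#' 2D convolutions become 3D convolutions with the unchanged channel
#' progression (64, 64, 128, 128, 256 x 4, 512 x 4, 512 x 4) and 2D max-pools
#' become window-2 3D max-pools after layers 2, 4, 8, 12 and 16. Tap points
#' sit at each ReLU, capped at the first 8 by default to bound memory (set
#' \code{tapLimit = NA} for the full stack; layers beyond the last tap are
#' not materialized).
#'
#' @param seed integer seed.
#' @param tapLimit number of exposed taps (default 8; NA = all 16).
#' @param initMethod weight scheme (default "kaiming_uniform", the usual
#'   untrained-network default).
#' @return A frozen [FeatureExtractor-class].
#' @export
buildPresetVGG19_3d <- function(seed = 1L, tapLimit = 8L,
                                initMethod = "kaiming_uniform") {
  channels <- c(64, 64, 128, 128, 256, 256, 256, 256,
                512, 512, 512, 512, 512, 512, 512, 512)
  pool_after <- c(2L, 4L, 8L, 12L, 16L)
  ntap <- if (is.na(tapLimit)) length(channels) else
    min(as.integer(tapLimit), length(channels))
  with_seed(seed, {
    layers <- vector("list", ntap)
    cin <- 1L
    for (i in seq_len(ntap)) {
      pool <- if (i %in% pool_after) list(window = 2L, stride = 2L) else NULL
      layers[[i]] <- .conv_layer(3L, cin, channels[i], initMethod, FALSE,
                                 pool = pool)
      cin <- channels[i]
    }
    cfg <- lossNetConfig(preset = "vgg19_3d", depth = ntap, kernelSize = 3L,
                         nFeatures = 64L, initMethod = initMethod,
                         seed = seed, tapLimit = as.integer(ntap))
    new("FeatureExtractor", layers = layers, tapLayers = seq_len(ntap),
        config = cfg)
  })
}

#' 3D translation of the AlexNet convolutional stack, untrained
#'
#' Channels 64, 192, 384, 256, 256; the strided first convolution (kernel 11,
#' stride 4, padding 2) and the window-3/stride-2 max-pools are translated to
#' 3D. Inputs smaller than the receptive footprint of the strided stack raise
#' a dimensionality error at forward time.
#'
#' @param seed integer seed.
#' @param tapLimit number of exposed taps (default all 5).
#' @param initMethod weight scheme (default "kaiming_uniform").
#' @return A frozen [FeatureExtractor-class].
#' @export
buildPresetAlexNet3d <- function(seed = 1L, tapLimit = NA_integer_,
                                 initMethod = "kaiming_uniform") {
  with_seed(seed, {
    pool32 <- list(window = 3L, stride = 2L)
    layers <- list(
      .conv_layer(11L, 1L, 64L, initMethod, FALSE, stride = 4L, pad = 2L,
                  pool = pool32),
      .conv_layer(5L, 64L, 192L, initMethod, FALSE, pad = 2L, pool = pool32),
      .conv_layer(3L, 192L, 384L, initMethod, FALSE, pad = 1L),
      .conv_layer(3L, 384L, 256L, initMethod, FALSE, pad = 1L),
      .conv_layer(3L, 256L, 256L, initMethod, FALSE, pad = 1L, pool = pool32)
    )
    ntap <- if (is.na(tapLimit)) 5L else min(as.integer(tapLimit), 5L)
    cfg <- lossNetConfig(preset = "alexnet_3d", depth = 5L, kernelSize = 3L,
                         nFeatures = 64L, initMethod = initMethod,
                         seed = seed, tapLimit = ntap)
    new("FeatureExtractor", layers = layers, tapLayers = seq_len(ntap),
        config = cfg)
  })
}

# forward pass through an extractor; returns the list of tap nodes
.forward_extractor <- function(ext, x, single = FALSE) {
  h <- as_node(x)
  taps <- vector("list", length(ext@layers))
  for (i in seq_along(ext@layers)) {
    ly <- ext@layers[[i]]
    h <- ag_conv3d(h, ly$w, ly$b, stride = ly$stride, pad = ly$pad,
                   single = single)
    if (identical(ly$act, "relu")) h <- ag_relu(h)
    taps[[i]] <- h
    if (!is.null(ly$pool))
      h <- ag_maxpool3d(h, ly$pool$window, ly$pool$stride)
  }
  taps[ext@tapLayers]
}

#' @rdname parameterCount
setMethod("parameterCount", "FeatureExtractor", function(x) {
  sum(vapply(x@layers, function(ly)
    length(ly$w$value) + length(ly$b$value), numeric(1)))
})

#' @rdname parameterValues
setMethod("parameterValues", "FeatureExtractor", function(x) {
  vals <- lapply(seq_along(x@layers), function(i) {
    ly <- x@layers[[i]]
    out <- c(as.numeric(ly$w$value), as.numeric(ly$b$value))
    names(out) <- c(sprintf("layer%d.w%d", i, seq_along(ly$w$value)),
                    sprintf("layer%d.b%d", i, seq_along(ly$b$value)))
    out
  })
  unlist(vals)
})
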