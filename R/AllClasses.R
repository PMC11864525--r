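#' @import methods
NULL

#' Volume3D: a single-channel 3D intensity image
#'
#' The universal image currency of the package: a dense 3D array of
#' nonnegative, finite intensities with voxel-size metadata. The axis order is
#' fixed as (z, y, x); slice indices in the documentation are 0-based to match
#' the usual imaging convention, while R accessors are 1-based as usual.
#'
#' @slot data 3D numeric array of intensities, axis order (z, y, x).
#' @slot spacing voxel dimensions in mm per axis, length 3.
#' @slot metadata free-form list (e.g. foreground fraction of a phantom).
#' @export
setClass("Volume3D", representation(
  data = "array",
  spacing = "numeric",
  metadata = "list"
), prototype(spacing = c(1, 1, 1), metadata = list()))

setValidity("Volume3D", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L)
    return(sprintf("data must have exactly 3 dimensions (observed rank %d)",
                   length(d)))
  if (any(d < 1L)) return("all dimensions must be >= 1")
  if (!all(is.finite(object@data))) return("all intensities must be finite")
  if (length(object@spacing) != 3L) return("spacing must have length 3")
  if (any(!is.finite(object@spacing)) || any(object@spacing <= 0))
    return("spacing must be positive and finite")
  TRUE
})

#' Construct a Volume3D
#'
#' @param data 3D numeric array (z, y, x) of finite intensities.
#' @param spacing voxel size in mm per axis; defaults to isotropic 1 mm.
#' @param metadata optional list of free-form annotations.
#' @return A [Volume3D-class] object.
#' @examples
#' v <- Volume3D(array(runif(8^3), c(8, 8, 8)))
#' dim(v)
#' @export
Volume3D <- function(data, spacing = c(1, 1, 1), metadata = list()) {
  storage.mode(data) <- "double"
  new("Volume3D", data = data, spacing = as.numeric(spacing),
      metadata = metadata)
}

#' Phantom generator configuration
#'
#' Describes a synthetic volume of sparse, line-like structures: branching
#' tubes (root- or vessel-like) on a dark background, rendered with soft
#' (anti-aliased) edges.
#'
#' @slot shape target (z, y, x) dimensions, each >= 16.
#' @slot nTubes number of primary tubes (>= 0).
#' @slot radiusRange (min, max) tube radius in voxels, min >= 0.5.
#' @slot branchProb per-tube probability of spawning one child branch.
#' @slot tubeIntensityRange (min, max) tube intensity, inside (0, 1].
#' @slot backgroundLevel constant background intensity in [0, 0.1].
#' @slot curvature maximum per-step angular deviation of the centerline (rad).
#' @export
setClass("PhantomConfig", representation(
  shape = "integer",
  nTubes = "integer",
  radiusRange = "numeric",
  branchProb = "numeric",
  tubeIntensityRange = "numeric",
  backgroundLevel = "numeric",
  curvature = "numeric"
))

setValidity("PhantomConfig", function(object) {
  if (length(object@shape) != 3L || any(object@shape < 16L))
    return("shape must have 3 axes, each >= 16")
  if (object@nTubes < 0L) return("nTubes must be >= 0")
  if (length(object@radiusRange) != 2L ||
      object@radiusRange[1] > object@radiusRange[2])
    return("radiusRange must be an ordered (min, max) pair")
  if (object@radiusRange[1] < 0.5) return("minimum radius must be >= 0.5")
  if (object@branchProb < 0 || object@branchProb > 1)
    return("branchProb must lie in [0, 1]")
  if (length(object@tubeIntensityRange) != 2L ||
      object@tubeIntensityRange[1] > object@tubeIntensityRange[2])
    return("tubeIntensityRange must be an ordered (min, max) pair")
  if (object@tubeIntensityRange[1] <= 0 || object@tubeIntensityRange[2] > 1)
    return("tubeIntensityRange must lie inside (0, 1]")
  if (object@backgroundLevel < 0 || object@backgroundLevel > 0.1)
    return("backgroundLevel must lie in [0, 0.1]")
  if (object@curvature < 0) return("curvature must be >= 0")
  TRUE
})

#' Construct a PhantomConfig
#'
#' Defaults emulate the sparsity and connectivity of volumetric images of
#' roots or vessels: a handful of smooth tubes occupying well under 10% of the
#' volume.
#'
#' @param shape target (z, y, x) dimensions, each >= 16.
#' @param nTubes number of primary tubes.
#' @param radiusRange (min, max) tube radius in voxels.
#' @param branchProb probability per tube of spawning one child branch.
#' @param tubeIntensityRange (min, max) tube intensity in (0, 1].
#' @param backgroundLevel constant background intensity in [0, 0.1].
#' @param curvature maximum per-step angular deviation of the centerline, in
#'   radians.
#' @return A [PhantomConfig-class] object.
#' @export
phantomConfig <- function(shape = c(64L, 64L, 64L), nTubes = 5L,
                          radiusRange = c(1.5, 3), branchProb = 0.3,
                          tubeIntensityRange = c(0.7, 1),
                          backgroundLevel = 0.02, curvature = 0.3) {
  new("PhantomConfig", shape = as.integer(shape), nTubes = as.integer(nTubes),
      radiusRange = as.numeric(radiusRange), branchProb = branchProb,
      tubeIntensityRange = as.numeric(tubeIntensityRange),
      backgroundLevel = backgroundLevel, curvature = curvature)
}

#' Rician corruption specification
#'
#' @slot level noise standard deviation as a fraction of peak intensity,
#'   in [0, 1); 0 means identity. The study levels are 0.01, 0.05, 0.10, 0.20.
#' @slot seed integer seed making the corruption deterministic.
#' @export
setClass("NoiseSpec", representation(level = "numeric", seed = "integer"))

setValidity("NoiseSpec", function(object) {
  if (object@level < 0 || object@level >= 1)
    return("level must lie in [0, 1)")
  TRUE
})

#' Construct a NoiseSpec
#'
#' @param level fraction of peak intensity in [0, 1); the four study levels
#'   are 0.01, 0.05, 0.10 and 0.20.
#' @param seed integer seed.
#' @return A [NoiseSpec-class] object.
#' @export
noiseSpec <- function(level, seed = 1L) {
  new("NoiseSpec", level = as.numeric(level), seed = as.integer(seed))
}

#' Configuration of an untrained loss network
#'
#' Describes one frozen, randomly initialized 3D convolutional feature
#' extractor: either the "simple" stack of identical conv+ReLU layers whose
#' depth, kernel size, width, pooling positions and initialization scheme span
#' the ablation space, or a 3D translation of the VGG19 / AlexNet
#' convolutional stacks.
#'
#' @slot preset one of "simple", "vgg19_3d", "alexnet_3d".
#' @slot depth number of convolutional layers (simple preset).
#' @slot kernelSize odd isotropic kernel edge.
#' @slot nFeatures channels per layer (simple preset).
#' @slot poolingAfter 1-based layer indices after which a 2x2x2 max-pooling is
#'   inserted.
#' @slot initMethod one of "kaiming_uniform", "kaiming_normal",
#'   "xavier_uniform", "xavier_normal", "default_uniform".
#' @slot seed integer seed for weight drawing.
#' @slot legacySqrtBound if TRUE, the default-uniform bound uses the
#'   conventional reciprocal square root of the fan-in instead of the
#'   reciprocal fan-in itself.
#' @slot tapLimit maximum number of exposed tap points (NA = all); the large
#'   presets default to 8 to bound memory.
#' @export
setClass("LossNetConfig", representation(
  preset = "character",
  depth = "integer",
  kernelSize = "integer",
  nFeatures = "integer",
  poolingAfter = "integer",
  initMethod = "character",
  seed = "integer",
  legacySqrtBound = "logical",
  tapLimit = "integer"
))

.init_methods <- c("kaiming_uniform", "kaiming_normal", "xavier_uniform",
                   "xavier_normal", "default_uniform")

setValidity("LossNetConfig", function(object) {
  if (!object@preset %in% c("simple", "vgg19_3d", "alexnet_3d"))
    return("preset must be one of simple, vgg19_3d, alexnet_3d")
  if (object@depth < 1L) return("depth must be >= 1")
  if (object@kernelSize %% 2L == 0L)
    return(sprintf("kernelSize must be odd (got %d)", object@kernelSize))
  if (object@nFeatures < 1L) return("nFeatures must be >= 1")
  if (length(object@poolingAfter) &&
      (any(object@poolingAfter < 1L) || any(object@poolingAfter > object@depth)))
    return(sprintf("poolingAfter indices must lie in 1..depth (= %d)",
                   object@depth))
  if (!object@initMethod %in% .init_methods)
    return(paste0("initMethod must be one of: ",
                  paste(.init_methods, collapse = ", ")))
  TRUE
})

#' Construct a LossNetConfig
#'
#' @param preset "simple" (default), "vgg19_3d" or "alexnet_3d".
#' @param depth number of conv layers for the simple preset; the studied
#'   depths are 3, 5, 7, 9 and 13.
#' @param kernelSize odd isotropic kernel edge; the studied sizes are 3, 5, 7
#'   and 9.
#' @param nFeatures channels per layer (default 32).
#' @param poolingAfter integer vector of 1-based layer indices after which a
#'   window-2 max-pooling is inserted (default none).
#' @param initMethod weight initialization scheme (default "xavier_normal",
#'   the scheme used for the headline experiments).
#' @param seed integer seed for the random weights.
#' @param legacySqrtBound use the reciprocal-square-root variant of the
#'   default-uniform bound (see [initializeWeights()]).
#' @param tapLimit cap on exposed tap points (NA = all simple-preset taps;
#'   the VGG19/AlexNet presets default to 8).
#' @return A [LossNetConfig-class] object.
#' @examples
#' cfg <- lossNetConfig(depth = 3, kernelSize = 3, nFeatures = 32)
#' @export
lossNetConfig <- function(preset = "simple", depth = 3L, kernelSize = 3L,
                          nFeatures = 32L, poolingAfter = integer(0),
                          initMethod = "xavier_normal", seed = 1L,
                          legacySqrtBound = FALSE, tapLimit = NA_integer_) {
  new("LossNetConfig", preset = preset, depth = as.integer(depth),
      kernelSize = as.integer(kernelSize), nFeatures = as.integer(nFeatures),
      poolingAfter = as.integer(poolingAfter), initMethod = initMethod,
      seed = as.integer(seed), legacySqrtBound = legacySqrtBound,
      tapLimit = as.integer(tapLimit))
}

#' A frozen 3D convolutional feature extractor
#'
#' Built by [buildLossNetwork()] (or the preset builders); its parameters are
#' excluded from optimization and remain bit-identical across any training
#' run. Tap points are the ReLU outputs exposed to the perceptual loss.
#'
#' @slot layers internal layer list (convolution weights, activations,
#'   pooling markers).
#' @slot tapLayers indices (into the layer list) of the exposed tap points.
#' @slot config the [LossNetConfig-class] that built the extractor.
#' @export
setClass("FeatureExtractor", representation(
  layers = "list",
  tapLayers = "integer",
  config = "LossNetConfig"
))

#' Ordered per-layer feature activations
#'
#' The operands of the perceptual loss: one activation array per tap point,
#' with its (channels, height, width, depth) record.
#'
#' @slot maps list of activation arrays, internal layout (z, y, x, channel).
#' @slot featureDims integer matrix, one row per tap, columns C, H, W, D.
#' @export
setClass("FeatureMaps", representation(
  maps = "list",
  featureDims = "matrix"
))

#' A perceptual-loss evaluation
#'
#' @slot value total loss (sum of the per-layer contributions).
#' @slot perLayer nonnegative per-tap contributions.
#' @export
setClass("LossValue", representation(value = "numeric", perLayer = "numeric"))

setValidity("LossValue", function(object) {
  if (any(object@perLayer < 0)) return("per-layer contributions must be >= 0")
  if (abs(object@value - sum(object@perLayer)) >
      1e-8 * max(1, abs(object@value)))
    return("value must equal the sum of per-layer contributions")
  TRUE
})

#' Denoiser architecture configuration
#'
#' @slot architecture one of "dncnn", "resnet", "transformer".
#' @slot dncnnChannels hidden channels of the DnCNN (default 64).
#' @slot dncnnBlocks inner conv+ReLU+batch-norm blocks (default 3).
#' @slot resnetChannels hidden channels of the residual CNN (default 64).
#' @slot resnetBlocks residual blocks (default 5).
#' @slot tfChannels base channels of the transformer (default 8).
#' @slot tfFF ordered pair of feed-forward conv widths (default 16, 32).
#' @slot tfBlocks sequential transformer blocks (default 4).
#' @slot tfHeads attention heads (default 1).
#' @slot residualOutput if TRUE the network predicts the noise and the output
#'   is input minus prediction; default FALSE (the clean image is predicted
#'   directly).
#' @export
setClass("DenoiserConfig", representation(
  architecture = "character",
  dncnnChannels = "integer",
  dncnnBlocks = "integer",
  resnetChannels = "integer",
  resnetBlocks = "integer",
  tfChannels = "integer",
  tfFF = "integer",
  tfBlocks = "integer",
  tfHeads = "integer",
  residualOutput = "logical"
))

setValidity("DenoiserConfig", function(object) {
  if (!object@architecture %in% c("dncnn", "resnet", "transformer"))
    return("architecture must be one of dncnn, resnet, transformer")
  counts <- c(object@dncnnChannels, object@resnetChannels, object@tfChannels,
              object@tfFF, object@tfBlocks, object@tfHeads)
  if (any(counts < 1L)) return("all channel/block counts must be >= 1")
  if (length(object@tfFF) != 2L)
    return("tfFF must be an ordered pair of channel counts")
  if (object@tfChannels %% object@tfHeads != 0L)
    return("tfChannels must be divisible by tfHeads")
  TRUE
})

#' Construct a DenoiserConfig
#'
#' @param architecture "dncnn", "resnet" or "transformer".
#' @param dncnnChannels,dncnnBlocks DnCNN hidden width and inner block count.
#' @param resnetChannels,resnetBlocks residual CNN width and block count.
#' @param tfChannels,tfFF,tfBlocks,tfHeads transformer base width,
#'   feed-forward widths (ordered pair), sequential block count and head
#'   count.
#' @param residualOutput predict the noise instead of the image.
#' @return A [DenoiserConfig-class] object.
#' @export
denoiserConfig <- function(architecture = c("dncnn", "resnet", "transformer"),
                           dncnnChannels = 64L, dncnnBlocks = 3L,
                           resnetChannels = 64L, resnetBlocks = 5L,
                           tfChannels = 8L, tfFF = c(16L, 32L),
                           tfBlocks = 4L, tfHeads = 1L,
                           residualOutput = FALSE) {
  architecture <- match.arg(architecture)
  new("DenoiserConfig", architecture = architecture,
      dncnnChannels = as.integer(dncnnChannels),
      dncnnBlocks = as.integer(dncnnBlocks),
      resnetChannels = as.integer(resnetChannels),
      resnetBlocks = as.integer(resnetBlocks),
      tfChannels = as.integer(tfChannels), tfFF = as.integer(tfFF),
      tfBlocks = as.integer(tfBlocks), tfHeads = as.integer(tfHeads),
      residualOutput = residualOutput)
}

#' A 3D denoising network
#'
#' @slot architecture "dncnn", "resnet" or "transformer".
#' @slot modules internal module list holding the trainable parameters.
#' @slot config the [DenoiserConfig-class] that built the network.
#' @export
setClass("Denoiser", representation(
  architecture = "character",
  modules = "list",
  config = "DenoiserConfig"
))

#' Region-of-interest crop specification
#'
#' The evaluation protocol crops a fixed cube from each dataset kind before
#' computing metrics: a 52^3 cube anchored at z offset 0 and in-plane offset
#' 70 for root-like volumes, and a centered 68^3 cube for angiography-like
#' volumes.
#'
#' @slot kind one of "root", "mra", "none".
#' @export
setClass("CropSpec", representation(kind = "character"))

setValidity("CropSpec", function(object) {
  if (!object@kind %in% c("root", "mra", "none"))
    return("kind must be one of root, mra, none")
  TRUE
})

#' Construct a CropSpec
#' @param kind "root", "mra" or "none".
#' @return A [CropSpec-class] object.
#' @export
cropSpec <- function(kind = c("none", "root", "mra")) {
  new("CropSpec", kind = match.arg(kind))
}

#' Per-image and aggregated evaluation metrics
#'
#' @slot perImage data.frame with columns seed, image, ssim, psnr, mse.
#' @slot aggregate list with per-metric mean/sd over the pooled per-image
#'   values ("pooled") and over seed-level means ("bySeed").
#' @slot region which crop was applied ("root", "mra" or "none").
#' @export
setClass("EvalResult", representation(
  perImage = "data.frame",
  aggregate = "list",
  region = "character"
))

#' Training configuration
#'
#' Defaults are the desk-scale settings used throughout the examples and
#' tests; [paperTrainConfig()] returns the full-scale settings of the original
#' study (30,000 iterations, batch 16, 96^3 crops), which require
#' GPU-class compute.
#'
#' @slot iterations optimizer steps.
#' @slot batchSize crops per step.
#' @slot learningRate Adam learning rate.
#' @slot optimizer currently "adam".
#' @slot cropSize random training crop edge.
#' @slot seed master experiment seed; independent sub-seeds for weight
#'   initialization, data order, noise and the loss network are derived from
#'   it (see [deriveSeed()]).
#' @slot loss one of "l1", "ssim", "upl".
#' @slot lossNet the [LossNetConfig-class] used when loss = "upl".
#' @slot noiseLevel Rician level as a fraction of peak intensity.
#' @slot valEvery validation period in iterations (0 = only at the end).
#' @slot precision "single" (default; the working precision of the
#'   convolutions during training) or "double".
#' @export
setClass("TrainConfig", representation(
  iterations = "integer",
  batchSize = "integer",
  learningRate = "numeric",
  optimizer = "character",
  cropSize = "integer",
  seed = "integer",
  loss = "character",
  lossNet = "LossNetConfig",
  noiseLevel = "numeric",
  valEvery = "integer",
  precision = "character"
))

setValidity("TrainConfig", function(object) {
  if (object@iterations < 1L) return("iterations must be >= 1")
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  if (!object@loss %in% c("l1", "ssim", "upl"))
    return("loss must be one of l1, ssim, upl")
  if (!object@optimizer %in% "adam") return("optimizer must be 'adam'")
  if (!object@precision %in% c("single", "double"))
    return("precision must be 'single' or 'double'")
  TRUE
})

#' Construct a TrainConfig
#'
#' @param iterations optimizer steps (desk default 300; full-scale 30000).
#' @param batchSize crops per step (desk default 4; full-scale 16).
#' @param learningRate Adam learning rate (default 0.001).
#' @param cropSize training crop edge (desk default 32; full-scale 96).
#' @param seed master experiment seed.
#' @param loss "l1", "ssim" or "upl".
#' @param lossNet loss-network configuration used when loss = "upl".
#' @param noiseLevel Rician level as a fraction of peak intensity.
#' @param valEvery validation period in iterations (0 = final only).
#' @param precision "single" or "double" convolution working precision.
#' @return A [TrainConfig-class] object.
#' @export
trainConfig <- function(iterations = 300L, batchSize = 4L,
                        learningRate = 0.001, cropSize = 32L, seed = 1L,
                        loss = c("upl", "l1", "ssim"),
                        lossNet = lossNetConfig(), noiseLevel = 0.1,
                        valEvery = 0L, precision = "single") {
  loss <- match.arg(loss)
  new("TrainConfig", iterations = as.integer(iterations),
      batchSize = as.integer(batchSize), learningRate = learningRate,
      optimizer = "adam", cropSize = as.integer(cropSize),
      seed = as.integer(seed), loss = loss, lossNet = lossNet,
      noiseLevel = noiseLevel, valEvery = as.integer(valEvery),
      precision = precision)
}

#' Full-scale training settings of the original study
#'
#' 30,000 iterations, batch 16, learning rate 0.001, random 96^3 crops.
#' These settings require GPU-class compute and are provided for completeness;
#' the desk-scale defaults of [trainConfig()] are used everywhere else.
#'
#' @param ... overrides passed on to [trainConfig()].
#' @return A [TrainConfig-class] object.
#' @export
paperTrainConfig <- function(...) {
  args <- list(...)
  defaults <- list(iterations = 30000L, batchSize = 16L, learningRate = 0.001,
                   cropSize = 96L)
  do.call(trainConfig, utils::modifyList(defaults, args))
}
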