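#' Extract the intensity array of a volume
#' @param x a [Volume3D-class].
#' @return The 3D numeric array, axis order (z, y, x).
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))

#' @rdname volData
setMethod("volData", "Volume3D", function(x) x@data)

#' Voxel spacing in mm per axis
#' @param x a [Volume3D-class].
#' @return Numeric length-3 vector (z, y, x) in mm.
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname voxelSpacing
setMethod("voxelSpacing", "Volume3D", function(x) x@spacing)

#' @export
setMethod("dim", "Volume3D", function(x) dim(x@data))

#' Number of exposed tap points of a feature extractor
#' @param x a [FeatureExtractor-class] or [FeatureMaps-class].
#' @return Integer count of tap points.
#' @export
setGeneric("nTapPoints", function(x) standardGeneric("nTapPoints"))

#' @rdname nTapPoints
setMethod("nTapPoints", "FeatureExtractor", function(x) length(x@tapLayers))

#' @rdname nTapPoints
setMethod("nTapPoints", "FeatureMaps", function(x) length(x@maps))

#' Per-tap feature dimensions (C, H, W, D)
#' @param x a [FeatureMaps-class].
#' @return Integer matrix, one row per tap point.
#' @export
setGeneric("featureDims", function(x) standardGeneric("featureDims"))

#' @rdname featureDims
setMethod("featureDims", "FeatureMaps", function(x) x@featureDims)

#' Total number of parameters of a network
#' @param x a [Denoiser-class] or [FeatureExtractor-class].
#' @return Integer parameter count (weights, biases, batch-norm affine terms,
#'   activation slopes and attention temperatures).
#' @export
setGeneric("parameterCount", function(x) standardGeneric("parameterCount"))

#' Flat copy of all parameter values of a network
#'
#' Useful for frozenness checks: the vector is bit-comparable before and
#' after a training run.
#' @param x a [Denoiser-class] or [FeatureExtractor-class].
#' @return Named numeric vector of all parameter values.
#' @export
setGeneric("parameterValues", function(x) standardGeneric("parameterValues"))

#' Denoise a volume with a trained network
#' @param model a [Denoiser-class].
#' @param vol a [Volume3D-class] with each axis >= 8.
#' @param ... further arguments (not used).
#' @return A [Volume3D-class]; output clamped to [0, 1], same dims as input.
#' @export
setGeneric("denoise", function(model, vol, ...) standardGeneric("denoise"))

setMethod("show", "Volume3D", function(object) {
  d <- dim(object@data)
  cat(sprintf("Volume3D %d x %d x %d (z, y, x), spacing %s mm\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = " x ")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

setMethod("show", "PhantomConfig", function(object) {
  cat(sprintf("PhantomConfig: %s voxels, %d tube(s), radius [%g, %g], branchProb %g\n",
              paste(object@shape, collapse = " x "), object@nTubes,
              object@radiusRange[1], object@radiusRange[2], object@branchProb))
})

setMethod("show", "LossNetConfig", function(object) {
  if (object@preset == "simple")
    cat(sprintf("LossNetConfig: simple, depth %d, kernel %d^3, %d features, init %s%s\n",
                object@depth, object@kernelSize, object@nFeatures,
                object@initMethod,
                if (length(object@poolingAfter))
                  paste0(", pooling after ",
                         paste(object@poolingAfter, collapse = ","))
                else ""))
  else
    cat(sprintf("LossNetConfig: preset %s, init %s\n", object@preset,
                object@initMethod))
})

setMethod("show", "FeatureExtractor", function(object) {
  cat(sprintf("FeatureExtractor (%s): %d tap point(s), %d parameters, frozen\n",
              object@config@preset, nTapPoints(object),
              parameterCount(object)))
})

setMethod("show", "FeatureMaps", function(object) {
  cat(sprintf("FeatureMaps: %d tap point(s)\n", nTapPoints(object)))
  fd <- object@featureDims
  for (j in seq_len(nrow(fd)))
    cat(sprintf("  tap %d: C=%d, H=%d, W=%d, D=%d\n", j,
                fd[j, 1], fd[j, 2], fd[j, 3], fd[j, 4]))
})

setMethod("show", "LossValue", function(object) {
  cat(sprintf("LossValue: %.6g over %d layer(s)\n", object@value,
              length(object@perLayer)))
})

setMethod("show", "Denoiser", function(object) {
  cat(sprintf("Denoiser: %s, %d parameters\n", object@architecture,
              parameterCount(object)))
})

setMethod("show", "EvalResult", function(object) {
  cat(sprintf("EvalResult: %d image evaluation(s), region '%s'\n",
              nrow(object@perImage), object@region))
  ag <- object@aggregate$pooled
  if (!is.null(ag))
    for (m in names(ag))
      cat(sprintf("  %s: %.4g +/- %.4g\n", m, ag[[m]]["mean"], ag[[m]]["sd"]))
})
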