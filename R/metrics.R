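# metrics: SSIM/PSNR/MSE, region-of-interest cropping, aggregation.

#' Mean structural similarity of two volumes
#'
#' Mean local SSIM over a sliding 3D Gaussian window (sigma 1.5, window 11^3
#' where it fits, otherwise the largest odd window that does; valid windows
#' only), with the standard constants \code{C1 = (0.01 * dataRange)^2} and
#' \code{C2 = (0.03 * dataRange)^2}. Symmetric; equals 1 exactly for
#' identical volumes; values lie in [-1, 1].
#'
#' @param a,b [Volume3D-class] objects (or 3D arrays) of identical dims.
#' @param dataRange intensity range (1 after normalization).
#' @param windowSize odd window edge (default 11).
#' @param sigma Gaussian window standard deviation in voxels (default 1.5).
#' @return Scalar mean SSIM.
#' @examples
#' v <- array(runif(12^3), c(12, 12, 12))
#' ssim3d(v, v)  # exactly 1
#' @export
ssim3d <- function(a, b, dataRange = 1, windowSize = 11L, sigma = 1.5) {
  .check_same_dims(a, b)
  if (dataRange <= 0) stop("dataRange must be > 0")
  av <- if (is(a, "Volume3D")) a@data else a
  bv <- if (is(b, "Volume3D")) b@data else b
  d <- dim(av)
  win <- min(windowSize, d)
  if (win %% 2L == 0L) win <- win - 1L
  if (win < 1L)
    stop(sprintf("SSIM window (%d) larger than the smallest volume extent (%d)",
                 windowSize, min(d)))
  g <- .gauss_weights(win, sigma)
  gm <- function(x) {
    x <- array(x, dim = c(dim(x), 1L, 1L))
    for (ax in 1:3) {
      kd <- c(1L, 1L, 1L); kd[ax] <- as.integer(win)
      x <- .conv3d_fw(x, dim(x), array(g, dim = c(kd, 1L, 1L)),
                      c(kd, 1L, 1L), 0, c(1L, 1L, 1L), c(0L, 0L, 0L), FALSE)
    }
    array(x, dim = dim(x)[1:3])
  }
  C1 <- (0.01 * dataRange)^2
  C2 <- (0.03 * dataRange)^2
  mu_a <- gm(av); mu_b <- gm(bv)
  va <- gm(av * av) - mu_a^2
  vb <- gm(bv * bv) - mu_b^2
  cab <- gm(av * bv) - mu_a * mu_b
  num <- (2 * mu_a * mu_b + C1) * (2 * cab + C2)
  den <- (mu_a^2 + mu_b^2 + C1) * (va + vb + C2)
  mean(num / den)
}

#' Mean squared error between two volumes
#' @param a,b [Volume3D-class] objects (or arrays) of identical dims.
#' @return Mean of squared voxel differences.
#' @export
mse <- function(a, b) {
  .check_same_dims(a, b)
  av <- if (is(a, "Volume3D")) a@data else a
  bv <- if (is(b, "Volume3D")) b@data else b
  mean((av - bv)^2)
}

#' Peak signal-to-noise ratio in dB
#'
#' \code{10 * log10(peak^2 / MSE)}; identical volumes give \code{Inf}
#' (serialized as the string "inf" in reports and excluded from means with a
#' warning).
#'
#' @param a,b [Volume3D-class] objects (or arrays) of identical dims.
#' @param peak peak intensity (1 after normalization).
#' @return Scalar dB value, possibly \code{Inf}.
#' @examples
#' psnr(array(0, c(4, 4, 4)), array(0.1, c(4, 4, 4)))  # 20 dB
#' @export
psnr <- function(a, b, peak = 1) {
  if (peak <= 0) stop("peak must be > 0")
  m <- mse(a, b)
  if (m == 0) return(Inf)
  10 * log10(peak^2 / m)
}

#' Crop the evaluation region of interest
#'
#' Root-like volumes: a 52^3 cube anchored at z offset 0 and in-plane
#' (y, x) offset 70. Angiography-like volumes: a 68^3 cube whose corner is
#' \code{floor((dim - 68) / 2)} per axis, i.e. centered with the floor
#' convention. \code{kind = "none"} returns the input unchanged. Windows that
#' do not fit raise an error naming the axis — never silent truncation.
#'
#' @param vol a [Volume3D-class].
#' @param spec a [CropSpec-class].
#' @return A [Volume3D-class].
#' @export
cropEvalRegion <- function(vol, spec) {
  stopifnot(is(vol, "Volume3D"), is(spec, "CropSpec"))
  validObject(spec)
  if (spec@kind == "none") return(vol)
  d <- dim(vol@data)
  if (spec@kind == "root") {
    edge <- 52L
    start0 <- c(0L, 70L, 70L)  # z anchored at 0, in-plane offset 70
  } else {
    edge <- 68L
    start0 <- as.integer((d - 68L) %/% 2L)
  }
  ax <- c("z", "y", "x")
  for (i in 1:3) .check_axis_fit(start0[i], edge, d[i], ax[i])
  idx <- lapply(start0, function(s) (s + 1L):(s + edge))
  Volume3D(vol@data[idx[[1]], idx[[2]], idx[[3]]], spacing = vol@spacing,
           metadata = vol@metadata)
}

.agg_stats <- function(x, metric) {
  fin <- is.finite(x)
  if (any(!fin))
    warning(sprintf("%d infinite %s value(s) excluded from the mean",
                    sum(!fin), metric))
  x <- x[fin]
  c(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else 0)
}

#' Bundle per-image metrics into an EvalResult
#'
#' @param perImage data.frame with columns seed, image, ssim, psnr, mse.
#' @param region crop kind the metrics were computed on.
#' @return An [EvalResult-class] with pooled and seed-level aggregates.
#' @export
evalResult <- function(perImage, region = "none") {
  stopifnot(all(c("seed", "image", "ssim", "psnr", "mse") %in%
                  names(perImage)))
  pooled <- list(ssim = .agg_stats(perImage$ssim, "ssim"),
                 psnr = .agg_stats(perImage$psnr, "psnr"),
                 mse = .agg_stats(perImage$mse, "mse"))
  seed_means <- do.call(rbind, lapply(split(perImage, perImage$seed),
                                      function(df) {
    data.frame(ssim = mean(df$ssim[is.finite(df$ssim)]),
               psnr = mean(df$psnr[is.finite(df$psnr)]),
               mse = mean(df$mse[is.finite(df$mse)]))
  }))
  bySeed <- list(ssim = .agg_stats(seed_means$ssim, "ssim"),
                 psnr = .agg_stats(seed_means$psnr, "psnr"),
                 mse = .agg_stats(seed_means$mse, "mse"))
  new("EvalResult", perImage = perImage,
      aggregate = list(pooled = pooled, bySeed = bySeed), region = region)
}

#' Evaluate one predicted volume against its ground truth
#'
#' Applies the crop to both volumes, then computes SSIM, PSNR and MSE.
#'
#' @param pred,truth [Volume3D-class] objects of identical dims.
#' @param crop a [CropSpec-class] (default: no crop).
#' @param dataRange intensity range (1 after normalization).
#' @return Named numeric vector (ssim, psnr, mse).
#' @export
evalMetrics <- function(pred, truth, crop = cropSpec("none"), dataRange = 1) {
  p <- cropEvalRegion(pred, crop)
  t <- cropEvalRegion(truth, crop)
  c(ssim = ssim3d(p, t, dataRange = dataRange),
    psnr = psnr(p, t, peak = dataRange),
    mse = mse(p, t))
}

#' Pool evaluation results over training seeds
#'
#' Concatenates the per-image tables of the inputs and reports mean/sd both
#' over the pooled per-image values and over seed-level means.
#'
#' @param results nonempty list of [EvalResult-class] objects with a
#'   consistent region.
#' @return An [EvalResult-class].
#' @export
aggregateResults <- function(results) {
  if (!length(results)) stop("empty result list")
  regions <- unique(vapply(results, function(r) r@region, character(1)))
  if (length(regions) != 1L)
    stop("inconsistent evaluation regions: ", paste(regions, collapse = ", "))
  perImage <- do.call(rbind, lapply(results, function(r) r@perImage))
  evalResult(perImage, region = regions)
}
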