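# pipeline: training and evaluation harness.

# ---- Adam -------------------------------------------------------------------

.adam_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  e <- new.env(parent = emptyenv())
  e$params <- params
  e$lr <- lr; e$beta1 <- beta1; e$beta2 <- beta2; e$eps <- eps
  e$t <- 0L
  e$m <- lapply(params, function(p) 0 * p$value)
  e$v <- lapply(params, function(p) 0 * p$value)
  e
}

.adam_step <- function(opt) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    g <- p$grad
    if (is.null(g)) next
    opt$m[[i]] <- opt$beta1 * opt$m[[i]] + (1 - opt$beta1) * g
    opt$v[[i]] <- opt$beta2 * opt$v[[i]] + (1 - opt$beta2) * g * g
    p$value <- p$value - opt$lr * (opt$m[[i]] / bc1) /
      (sqrt(opt$v[[i]] / bc2) + opt$eps)
  }
  invisible(NULL)
}

# run expr under a sampler-private RNG stream stored in `env`
.with_stream <- function(env, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  if (is.null(env$rng)) set.seed(env$seed)
  else assign(".Random.seed", env$rng, envir = globalenv())
  res <- force(expr)
  env$rng <- get(".Random.seed", envir = globalenv())
  res
}

#' Stream of aligned (noisy, clean) training crops
#'
#' Each clean volume is corrupted once (a fixed noise realization per volume,
#' as with really acquired data); each draw then picks a volume and a
#' uniformly random crop corner and cuts the clean and noisy versions at
#' identical coordinates. Deterministic given \code{seed}.
#'
#' @param cleanSet list of clean [Volume3D-class] volumes, each axis >=
#'   \code{cropSize}.
#' @param noise a [NoiseSpec-class]; per-volume sub-seeds are derived from
#'   its seed.
#' @param cropSize crop edge in voxels.
#' @param seed integer seed of the sampling stream.
#' @return A sampler: a list with \code{nextIndices(n)} (data.frame of volume
#'   index and 1-based crop corners) and \code{nextBatch(n)} (list with 5D
#'   arrays \code{noisy} and \code{clean} of shape crop^3 x 1 x n).
#' @export
makeTrainingPairs <- function(cleanSet, noise, cropSize, seed = 1L) {
  stopifnot(length(cleanSet) >= 1L, is(noise, "NoiseSpec"))
  cropSize <- as.integer(cropSize)
  dims <- lapply(cleanSet, dim)
  for (i in seq_along(dims))
    if (any(dims[[i]] < cropSize))
      stop(sprintf("crop size %d exceeds volume %d (%s)", cropSize, i,
                   paste(dims[[i]], collapse = "x")))
  noisySet <- lapply(seq_along(cleanSet), function(i)
    addRicianNoise(cleanSet[[i]],
                   noiseSpec(noise@level, deriveSeed(noise@seed, i)),
                   peak = 1))
  env <- new.env(parent = emptyenv())
  env$seed <- as.integer(seed)
  env$rng <- NULL
  nextIndices <- function(n) {
    .with_stream(env, {
      vi <- sample.int(length(cleanSet), n, replace = TRUE)
      corners <- vapply(seq_len(n), function(j) {
        d <- dims[[vi[j]]]
        vapply(1:3, function(ax) sample.int(d[ax] - cropSize + 1L, 1L),
               integer(1))
      }, integer(3))
      data.frame(vol = vi, z = corners[1, ], y = corners[2, ],
                 x = corners[3, ])
    })
  }
  nextBatch <- function(n) {
    idx <- nextIndices(n)
    noisy <- array(0, dim = c(cropSize, cropSize, cropSize, 1L, n))
    clean <- array(0, dim = c(cropSize, cropSize, cropSize, 1L, n))
    for (j in seq_len(n)) {
      zz <- idx$z[j] + 0:(cropSize - 1L)
      yy <- idx$y[j] + 0:(cropSize - 1L)
      xx <- idx$x[j] + 0:(cropSize - 1L)
      noisy[, , , 1L, j] <- noisySet[[idx$vol[j]]]@data[zz, yy, xx]
      clean[, , , 1L, j] <- cleanSet[[idx$vol[j]]]@data[zz, yy, xx]
    }
    list(noisy = noisy, clean = clean, indices = idx)
  }
  list(nextIndices = nextIndices, nextBatch = nextBatch,
       noisySet = noisySet, cropSize = cropSize)
}

#' Train a denoising network
#'
#' Runs exactly \code{iterations} Adam steps on random aligned crops. When
#' the loss is "upl" the frozen extractor is built before the first step and
#' its parameters are verified bit-identical afterwards. Fully deterministic
#' given the master seed: independent sub-seeds for weight initialization,
#' data order, noise and the loss network are derived from it via
#' [deriveSeed()]. A non-finite loss aborts with a diagnostic naming the
#' iteration.
#'
#' @param denoiserCfg a [DenoiserConfig-class].
#' @param trainCfg a [TrainConfig-class].
#' @param trainSet list of clean [Volume3D-class] volumes (each axis >=
#'   cropSize).
#' @param valSet list of clean [Volume3D-class] volumes used for validation
#'   SSIM (evaluated every \code{valEvery} iterations and at the end).
#' @return A list with elements \code{model} (the trained
#'   [Denoiser-class]), \code{history} (per-iteration loss, validation
#'   iterations/SSIM, and the noisy-input baseline SSIM), \code{extractor}
#'   (the frozen loss network, or NULL), \code{valNoisy} (the corrupted
#'   validation volumes) and \code{lossNetUnchanged} (frozenness check).
#' @export
train <- function(denoiserCfg, trainCfg, trainSet, valSet = list()) {
  stopifnot(is(denoiserCfg, "DenoiserConfig"), is(trainCfg, "TrainConfig"))
  validObject(trainCfg)
  single <- trainCfg@precision == "single"
  master <- trainCfg@seed
  model <- buildDenoiser(denoiserCfg, seed = deriveSeed(master, "init"))
  extractor <- NULL
  snapshot <- NULL
  if (trainCfg@loss == "upl") {
    lncfg <- trainCfg@lossNet
    lncfg@seed <- as.integer(
      (deriveSeed(master, "lossnet") + lncfg@seed - 1) %% 2147483646 + 1)
    extractor <- buildLossNetwork(lncfg)
    snapshot <- parameterValues(extractor)
  }
  noise <- noiseSpec(trainCfg@noiseLevel, deriveSeed(master, "noise"))
  sampler <- makeTrainingPairs(trainSet, noise, trainCfg@cropSize,
                               seed = deriveSeed(master, "data"))
  valNoisy <- lapply(seq_along(valSet), function(i)
    addRicianNoise(valSet[[i]],
                   noiseSpec(trainCfg@noiseLevel,
                             deriveSeed(noise@seed, 1000L + i)),
                   peak = 1))
  params <- .collect_params(model@modules)
  opt <- .adam_new(params, lr = trainCfg@learningRate)
  lossTrace <- numeric(trainCfg@iterations)
  valIter <- integer(0)
  valSSIM <- numeric(0)
  validate <- function() {
    if (!length(valSet)) return(NA_real_)
    mean(vapply(seq_along(valSet), function(i)
      ssim3d(denoise(model, valNoisy[[i]],
                     precision = trainCfg@precision), valSet[[i]]),
      numeric(1)))
  }
  for (it in seq_len(trainCfg@iterations)) {
    batch <- sampler$nextBatch(trainCfg@batchSize)
    out <- .forward_denoiser(model, ag_const(batch$noisy), training = TRUE,
                             single = single)
    lossNode <- switch(trainCfg@loss,
      l1 = .l1_node(out, batch$clean),
      ssim = .ssim_objective_node(out, batch$clean, single = single),
      upl = .pl_node(extractor, out, batch$clean, single = single))
    lv <- as.numeric(lossNode$value)
    if (!is.finite(lv))
      stop(sprintf("training diverged: non-finite loss at iteration %d", it))
    lossTrace[it] <- lv
    agZeroGrad(params)
    agBackward(lossNode)
    .adam_step(opt)
    if (trainCfg@valEvery > 0L && it %% trainCfg@valEvery == 0L &&
        length(valSet)) {
      valIter <- c(valIter, it)
      valSSIM <- c(valSSIM, validate())
    }
  }
  finalSSIM <- validate()
  noisySSIM <- if (length(valSet))
    mean(vapply(seq_along(valSet), function(i)
      ssim3d(valNoisy[[i]], valSet[[i]]), numeric(1))) else NA_real_
  unchanged <- if (!is.null(extractor))
    identical(snapshot, parameterValues(extractor)) else NA
  list(model = model,
       history = list(loss = lossTrace, valIterations = valIter,
                      valSSIM = valSSIM, finalValSSIM = finalSSIM,
                      noisyValSSIM = noisySSIM),
       extractor = extractor, valNoisy = valNoisy,
       lossNetUnchanged = unchanged)
}

#' @param precision "single" or "double" convolution working precision.
#' @rdname denoise
setMethod("denoise", "Denoiser", function(model, vol, precision = "single") {
  stopifnot(is(vol, "Volume3D"))
  if (any(dim(vol) < 8L))
    stop("volume too small to denoise: every axis must be >= 8")
  out <- .forward_denoiser(model, ag_const(.vol_to_batch(vol)),
                           training = FALSE,
                           single = identical(precision, "single"))$value
  out <- pmin(pmax(out, 0), 1)
  Volume3D(array(out, dim = dim(vol)), spacing = vol@spacing)
})

# ---- checkpointing ----------------------------------------------------------

#' Save / load a denoiser checkpoint
#'
#' The checkpoint embeds the architecture configuration, all parameter
#' values and the batch-norm running statistics, so evaluation is
#' self-describing.
#'
#' @param model a [Denoiser-class].
#' @param path .rds file path.
#' @return \code{saveDenoiser}: invisibly \code{path}; \code{loadDenoiser}:
#'   the reconstructed [Denoiser-class].
#' @export
saveDenoiser <- function(model, path) {
  stopifnot(is(model, "Denoiser"))
  ps <- .collect_params(model@modules)
  states <- .collect_bn_states(model@modules)
  saveRDS(list(config = model@config,
               params = lapply(ps, function(p) p$value),
               bn = lapply(states, function(s)
                 list(rm = s$running_mean, rv = s$running_var))),
          path)
  invisible(path)
}

.collect_bn_states <- function(x) {
  if (is.list(x) && identical(x$type, "bn")) return(list(x$state))
  if (is.list(x)) return(do.call(c, lapply(x, .collect_bn_states)))
  list()
}

#' @rdname saveDenoiser
#' @export
loadDenoiser <- function(path) {
  ck <- readRDS(path)
  model <- buildDenoiser(ck$config, seed = 1L)
  ps <- .collect_params(model@modules)
  stopifnot(length(ps) == length(ck$params))
  for (i in seq_along(ps)) ps[[i]]$value <- ck$params[[i]]
  states <- .collect_bn_states(model@modules)
  for (i in seq_along(states)) {
    states[[i]]$running_mean <- ck$bn[[i]]$rm
    states[[i]]$running_var <- ck$bn[[i]]$rv
  }
  model
}

# ---- experiment grid --------------------------------------------------------

.json_num <- function(x) {
  if (is.numeric(x) && length(x) == 1L && is.infinite(x))
    return(if (x > 0) "inf" else "-inf")
  x
}

#' Run a grid of denoising experiments
#'
#' Executes generate -> corrupt -> train -> denoise -> evaluate for every
#' cell of (architecture x loss x noise level x seed), writes one JSON report
#' per cell plus a merged table, and returns the merged table. Phantom train
#' and validation sets are shared across cells (generated from disjoint seed
#' ranges) so that cells differ only in the studied factors. Partial failures
#' are recorded per cell and the grid continues. Repeated runs with identical
#' configuration produce byte-identical reports.
#'
#' @param config a list (or path to a YAML file) with entries
#'   \code{archs}, \code{losses}, \code{noiseLevels}, \code{seeds},
#'   \code{nTrain}, \code{nVal}, \code{phantom} (a [PhantomConfig-class] or
#'   list of its arguments), \code{train} (a [TrainConfig-class] or list of
#'   overrides for [trainConfig()]), and optionally \code{crop} (a crop
#'   kind for evaluation, default "none").
#' @param outDir output directory for the JSON reports (created if missing).
#' @return Invisibly, a list with \code{table} (merged per-cell data.frame)
#'   and \code{aggregates} (per (arch, loss, noise) [EvalResult-class]
#'   objects over seeds).
#' @export
runExperiment <- function(config, outDir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  phantom <- config$phantom
  if (!is(phantom, "PhantomConfig"))
    phantom <- do.call(phantomConfig, as.list(phantom))
  baseTrain <- config$train
  if (!is(baseTrain, "TrainConfig"))
    baseTrain <- do.call(trainConfig, as.list(baseTrain))
  crop <- cropSpec(if (is.null(config$crop)) "none" else config$crop)
  nTrain <- if (is.null(config$nTrain)) 8L else as.integer(config$nTrain)
  nVal <- if (is.null(config$nVal)) 4L else as.integer(config$nVal)
  # disjoint seed ranges prevent train/validation leakage
  trainSet <- lapply(seq_len(nTrain), function(i)
    generatePhantom(phantom, seed = deriveSeed(1000L + i, "phantom")))
  valSet <- lapply(seq_len(nVal), function(i)
    generatePhantom(phantom, seed = deriveSeed(900000L + i, "phantom")))
  rows <- list()
  results <- list()
  for (arch in config$archs)
    for (loss in config$losses)
      for (noise in config$noiseLevels)
        for (seed in config$seeds) {
          cell <- sprintf("%s_%s_noise%03d_seed%d", arch, loss,
                          round(1000 * noise), seed)
          path <- file.path(outDir, paste0(cell, ".json"))
          res <- tryCatch({
            tc <- baseTrain
            tc@loss <- loss
            tc@noiseLevel <- as.numeric(noise)
            tc@seed <- as.integer(seed)
            fit <- train(denoiserConfig(arch), tc, trainSet, valSet)
            per <- do.call(rbind, lapply(seq_along(valSet), function(i) {
              m <- evalMetrics(denoise(fit$model, fit$valNoisy[[i]],
                                       precision = tc@precision),
                               valSet[[i]], crop = crop)
              mn <- evalMetrics(fit$valNoisy[[i]], valSet[[i]], crop = crop)
              data.frame(seed = seed, image = i, ssim = m["ssim"],
                         psnr = m["psnr"], mse = m["mse"],
                         ssimNoisy = mn["ssim"], row.names = NULL)
            }))
            report <- list(
              cell = cell, arch = arch, loss = loss, noise = noise,
              seed = seed,
              lossNetUnchanged = fit$lossNetUnchanged,
              perImage = lapply(seq_len(nrow(per)), function(r)
                lapply(as.list(per[r, ]), .json_num)),
              meanSSIM = mean(per$ssim), meanSSIMNoisy = mean(per$ssimNoisy),
              finalTrainLoss = utils::tail(fit$history$loss, 1))
            jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
            list(per = per, report = report)
          }, error = function(e) {
            jsonlite::write_json(list(cell = cell, error = conditionMessage(e)),
                                 path, auto_unbox = TRUE)
            NULL
          })
          if (is.null(res)) next
          key <- sprintf("%s_%s_noise%03d", arch, loss, round(1000 * noise))
          results[[key]] <- c(results[[key]],
                              list(evalResult(res$per[, c("seed", "image",
                                                          "ssim", "psnr",
                                                          "mse")],
                                              region = crop@kind)))
          rows[[cell]] <- data.frame(
            arch = arch, loss = loss, noise = noise, seed = seed,
            ssim = mean(res$per$ssim), psnr = mean(res$per$psnr),
            mse = mean(res$per$mse), ssimNoisy = mean(res$per$ssimNoisy),
            row.names = NULL)
        }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  aggregates <- lapply(results, aggregateResults)
  jsonlite::write_json(
    lapply(seq_len(nrow(table)), function(r)
      lapply(as.list(table[r, ]), .json_num)),
    file.path(outDir, "merged.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(table, file.path(outDir, "merged.csv"), row.names = FALSE)
  invisible(list(table = table, aggregates = aggregates))
}
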