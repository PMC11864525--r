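# Shared helpers: reproducible local RNG and seed derivation.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library calls never perturb user-level randomness.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Derive an independent sub-seed from a master seed
#'
#' A single experiment seed deterministically yields separate streams for
#' weight initialization, data order, noise realization and the loss network,
#' so that ablations vary exactly one factor. The map is a fixed affine hash
#' modulo the Mersenne prime 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param stream small integer naming the stream (0, 1, 2, ...), or one of
#'   the documented stream names.
#' @return An integer seed in 1 .. 2^31 - 2.
#' @examples
#' deriveSeed(1, "init")
#' deriveSeed(1, "noise")
#' @export
deriveSeed <- function(seed, stream = 0L) {
  streams <- c(init = 0L, data = 1L, noise = 2L, lossnet = 3L, phantom = 4L)
  if (is.character(stream)) {
    if (!stream %in% names(streams))
      stop("unknown stream name: ", stream)
    stream <- streams[[stream]]
  }
  m <- 2147483647  # 2^31 - 1
  x <- (as.numeric(seed) %% m) * 48271 + 11 * (as.numeric(stream) + 1)
  as.integer(x %% m + 1)
}

# axis-wise bounds check helper used by croppers
.check_axis_fit <- function(start0, edge, d, axis) {
  if (start0 < 0 || start0 + edge > d)
    stop(sprintf("crop window out of bounds on axis %s: [%d, %d) exceeds extent %d",
                 axis, start0, start0 + edge, d))
  invisible(NULL)
}
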