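# synthetic_data: tubular phantoms and Rician corruption.

# one persistent random walk with bounded per-step curvature; returns an
# n x 3 matrix of continuous voxel coordinates (1-based)
.walk_centerline <- function(start, dir, shape, curvature, max_steps,
                             step = 0.5) {
  pts <- matrix(0, nrow = max_steps + 1L, ncol = 3L)
  pts[1L, ] <- start
  p <- start
  n <- 1L
  for (i in seq_len(max_steps)) {
    # bounded random rotation of the direction
    r <- stats::rnorm(3)
    orth <- r - sum(r * dir) * dir
    no <- sqrt(sum(orth^2))
    if (no > 1e-12) {
      orth <- orth / no
      theta <- stats::runif(1, 0, curvature)
      dir <- cos(theta) * dir + sin(theta) * orth
      dir <- dir / sqrt(sum(dir^2))
    }
    p <- p + step * dir
    if (any(p < 2) || any(p > shape - 1)) break
    n <- n + 1L
    pts[n, ] <- p
  }
  pts[seq_len(n), , drop = FALSE]
}

# soft-edged stamping of a centerline into the volume (running max)
.render_tube <- function(vol, pts, radius, intensity) {
  shape <- dim(vol)
  reach <- ceiling(radius + 1)
  off <- as.matrix(expand.grid(-reach:reach, -reach:reach, -reach:reach))
  keep <- sqrt(rowSums(off^2)) <= radius + 1.75
  off <- off[keep, , drop = FALSE]
  nof <- nrow(off)
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    ctr <- round(p)
    vox <- off + rep(ctr, each = nof)
    ok <- vox[, 1] >= 1 & vox[, 1] <= shape[1] &
      vox[, 2] >= 1 & vox[, 2] <= shape[2] &
      vox[, 3] >= 1 & vox[, 3] <= shape[3]
    if (!any(ok)) next
    vox <- vox[ok, , drop = FALSE]
    d <- sqrt((vox[, 1] - p[1])^2 + (vox[, 2] - p[2])^2 + (vox[, 3] - p[3])^2)
    val <- intensity * pmin(pmax(radius + 0.5 - d, 0), 1)
    pos <- val > 0
    if (!any(pos)) next
    idx <- vox[pos, 1] + (vox[pos, 2] - 1L) * shape[1] +
      (vox[pos, 3] - 1L) * shape[1] * shape[2]
    val <- val[pos]
    cur <- vol[idx]
    upd <- val > cur
    if (any(upd)) vol[idx[upd]] <- val[upd]
  }
  vol
}

.min_dist_between <- function(a, b) {
  # smallest pairwise distance between two point sets (n x 3 each)
  best <- Inf
  for (i in seq_len(nrow(a))) {
    d2 <- (b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2 + (b[, 3] - a[i, 3])^2
    m <- min(d2)
    if (m < best) best <- m
  }
  sqrt(best)
}

#' Generate a clean phantom of branching tubes
#'
#' Emulates the geometry that motivates the method: sparse, connected,
#' line-like structures (roots, vessels) on a dark background. Each tube is a
#' persistent random walk with bounded curvature, dilated to its radius with
#' soft (anti-aliased) edges; branches inherit 0.7 times the parent radius.
#' Distinct primary tubes are placed with a separation margin (rejection
#' sampling) so that they form distinct connected components. Deterministic
#' given (config, seed).
#'
#' @param config a [PhantomConfig-class].
#' @param seed integer seed.
#' @return A [Volume3D-class] in [0, 1] whose metadata records the foreground
#'   fraction and the foreground threshold
#'   \code{(backgroundLevel + min tube intensity) / 2}.
#' @examples
#' ph <- generatePhantom(phantomConfig(shape = c(32, 32, 32), nTubes = 2), seed = 1)
#' ph@metadata$foregroundFraction
#' @export
generatePhantom <- function(config, seed = 1L) {
  stopifnot(is(config, "PhantomConfig"))
  validObject(config)
  shape <- config@shape
  rmax <- config@radiusRange[2]
  if (2 * (rmax + 2) >= min(shape))
    stop(sprintf("shape %s too small to contain tubes of radius %.2g",
                 paste(shape, collapse = "x"), rmax))
  with_seed(seed, {
    vol <- array(0, dim = shape)
    margin <- ceiling(rmax) + 2
    placed <- list()   # list of (pts, radius)
    max_steps <- 3L * max(shape)
    for (t in seq_len(config@nTubes)) {
      radius <- stats::runif(1, config@radiusRange[1], config@radiusRange[2])
      intensity <- stats::runif(1, config@tubeIntensityRange[1],
                                config@tubeIntensityRange[2])
      pts <- NULL
      for (try in 1:25) {
        start <- stats::runif(3, margin + 1, shape - margin)
        dir <- stats::rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        cand <- .walk_centerline(start, dir, shape, config@curvature, max_steps)
        ok <- TRUE
        for (pl in placed) {
          if (.min_dist_between(cand, pl$pts) <= radius + pl$radius + 1.5) {
            ok <- FALSE
            break
          }
        }
        pts <- cand
        if (ok) break
      }
      vol <- .render_tube(vol, pts, radius, intensity)
      placed[[length(placed) + 1L]] <- list(pts = pts, radius = radius)
      # optional child branch, attached to the parent centerline
      if (stats::runif(1) < config@branchProb && nrow(pts) > 10L) {
        at <- sample(seq(ceiling(nrow(pts) * 0.2), floor(nrow(pts) * 0.8)), 1L)
        pdir <- pts[min(at + 1L, nrow(pts)), ] - pts[max(at - 1L, 1L), ]
        pdir <- pdir / max(sqrt(sum(pdir^2)), 1e-12)
        r <- stats::rnorm(3)
        orth <- r - sum(r * pdir) * pdir
        orth <- orth / max(sqrt(sum(orth^2)), 1e-12)
        phi <- stats::runif(1, 0.5, 1.1)
        bdir <- cos(phi) * pdir + sin(phi) * orth
        bpts <- .walk_centerline(pts[at, ], bdir, shape, config@curvature,
                                 max_steps %/% 2L)
        vol <- .render_tube(vol, bpts, 0.7 * radius, intensity)
      }
    }
    vol <- pmax(vol, config@backgroundLevel)
    thr <- (config@backgroundLevel + config@tubeIntensityRange[1]) / 2
    Volume3D(vol, metadata = list(
      foregroundFraction = mean(vol > thr),
      foregroundThreshold = thr,
      seed = as.integer(seed)
    ))
  })
}

#' Corrupt a volume with Rician noise
#'
#' The standard magnitude-image construction: the output is
#' \code{sqrt((v + g1)^2 + g2^2)} with \code{g1}, \code{g2} independent
#' zero-mean Gaussian fields of standard deviation
#' \code{sigma = level * peak}, where \code{peak} defaults to the maximum of
#' the input (= 1 after [normalizeIntensity()]). The output is everywhere
#' nonnegative, and deterministic given the seed in \code{noise}.
#'
#' @param vol a [Volume3D-class], normalized to [0, 1].
#' @param noise a [NoiseSpec-class]; level 0 returns the input unchanged.
#' @param peak reference peak intensity defining sigma; defaults to
#'   \code{max(volData(vol))}. Supplying it explicitly makes sigma well
#'   defined for degenerate (e.g. all-zero) volumes.
#' @return A [Volume3D-class].
#' @examples
#' v <- Volume3D(array(0.5, c(16, 16, 16)))
#' n <- addRicianNoise(v, noiseSpec(0.10, seed = 7), peak = 1)
#' min(volData(n)) >= 0
#' @export
addRicianNoise <- function(vol, noise, peak = NULL) {
  stopifnot(is(vol, "Volume3D"), is(noise, "NoiseSpec"))
  validObject(noise)
  if (noise@level == 0) return(vol)
  mx <- max(vol@data)
  if (mx > 1 + 1e-6)
    stop(sprintf("input not normalized: max intensity %.4g > 1; run normalizeIntensity() first", mx))
  if (is.null(peak)) peak <- mx
  sigma <- noise@level * peak
  n <- length(vol@data)
  with_seed(noise@seed, {
    g <- stats::rnorm(2 * n, mean = 0, sd = sigma)
    out <- sqrt((vol@data + g[seq_len(n)])^2 + g[n + seq_len(n)]^2)
    dim(out) <- dim(vol@data)
    Volume3D(out, spacing = vol@spacing, metadata = vol@metadata)
  })
}
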