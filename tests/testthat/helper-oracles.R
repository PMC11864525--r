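# Independent brute-force oracles used by the tests. These deliberately share
# no code with the package internals: plain nested loops and direct formulas.

# direct-summation 3D convolution, layout (D1,D2,D3,Cin,N) / (K1,K2,K3,Cin,Cout)
naive_conv3d <- function(x, w, b, stride = c(1, 1, 1), pad = c(0, 0, 0)) {
  xd <- dim(x); wd <- dim(w)
  P <- array(0, dim = c(xd[1:3] + 2 * pad, xd[4], xd[5]))
  P[pad[1] + 1:xd[1], pad[2] + 1:xd[2], pad[3] + 1:xd[3], , ] <- x
  od <- (xd[1:3] + 2 * pad - wd[1:3]) %/% stride + 1
  out <- array(0, dim = c(od, wd[5], xd[5]))
  for (n in 1:xd[5]) for (co in 1:wd[5])
    for (o3 in 1:od[3]) for (o2 in 1:od[2]) for (o1 in 1:od[1]) {
      s <- 0
      for (ci in 1:xd[4])
        for (k3 in 1:wd[3]) for (k2 in 1:wd[2]) for (k1 in 1:wd[1])
          s <- s + P[(o1 - 1) * stride[1] + k1, (o2 - 1) * stride[2] + k2,
                     (o3 - 1) * stride[3] + k3, ci, n] * w[k1, k2, k3, ci, co]
      out[o1, o2, o3, co, n] <- s + b[co]
    }
  out
}

# nested-loop feature extraction for a "simple" extractor description:
# layers = list of list(w, b); ReLU after every conv; same padding
naive_simple_features <- function(layers, vol) {
  x <- array(vol, dim = c(dim(vol), 1, 1))
  maps <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    wd <- dim(layers[[i]]$w)
    x <- naive_conv3d(x, layers[[i]]$w, layers[[i]]$b,
                      pad = (wd[1:3] - 1) %/% 2)
    x <- pmax(x, 0)
    maps[[i]] <- x
  }
  maps
}

# explicit nested-loop evaluation of the layer-normalized feature loss
naive_perceptual <- function(maps_pred, maps_true) {
  total <- 0
  for (j in seq_along(maps_pred)) {
    a <- maps_pred[[j]]; b <- maps_true[[j]]
    d <- dim(a)
    s <- 0
    for (n in seq_len(d[5])) for (c in seq_len(d[4]))
      for (k3 in seq_len(d[3])) for (k2 in seq_len(d[2]))
        for (k1 in seq_len(d[1]))
          s <- s + (a[k1, k2, k3, c, n] - b[k1, k2, k3, c, n])^2
    total <- total + s / prod(d)
  }
  total
}

# sliding-window Gaussian-weighted SSIM over valid window positions only
naive_ssim3d <- function(a, b, data_range = 1, win = 11, sigma = 1.5) {
  d <- dim(a)
  win <- min(win, d)
  if (win %% 2 == 0) win <- win - 1
  half <- (win - 1) / 2
  g1 <- exp(-((-half:half)^2) / (2 * sigma^2)); g1 <- g1 / sum(g1)
  W <- outer(outer(g1, g1), g1)  # separable 3D window
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  vals <- c()
  for (z in 1:(d[1] - win + 1)) for (y in 1:(d[2] - win + 1))
    for (x in 1:(d[3] - win + 1)) {
      pa <- a[z:(z + win - 1), y:(y + win - 1), x:(x + win - 1)]
      pb <- b[z:(z + win - 1), y:(y + win - 1), x:(x + win - 1)]
      mua <- sum(W * pa); mub <- sum(W * pb)
      va <- sum(W * pa^2) - mua^2
      vb <- sum(W * pb^2) - mub^2
      cab <- sum(W * pa * pb) - mua * mub
      vals <- c(vals, ((2 * mua * mub + C1) * (2 * cab + C2)) /
                  ((mua^2 + mub^2 + C1) * (va + vb + C2)))
    }
  mean(vals)
}

# 26-connected component count of a logical 3D mask (BFS flood fill)
count_components_26 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, dim = d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  ncomp <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    ncomp <- ncomp + 1L
    queue <- start
    lab[start] <- ncomp
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      z <- (cur - 1L) %% d[1] + 1L
      y <- ((cur - 1L) %/% d[1]) %% d[2] + 1L
      x <- (cur - 1L) %/% (d[1] * d[2]) + 1L
      nz <- z + offs[, 1]; ny <- y + offs[, 2]; nx <- x + offs[, 3]
      ok <- nz >= 1 & nz <= d[1] & ny >= 1 & ny <= d[2] & nx >= 1 & nx <= d[3]
      ni <- nz[ok] + (ny[ok] - 1L) * d[1] + (nx[ok] - 1L) * d[1] * d[2]
      ni <- ni[mask[ni] & lab[ni] == 0L]
      if (length(ni)) {
        lab[ni] <- ncomp
        queue <- c(queue, ni)
      }
    }
  }
  ncomp
}

rand_volume <- function(d, seed) {
  set.seed(seed)
  array(runif(prod(d)), dim = d)
}
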