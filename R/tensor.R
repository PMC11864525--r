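# Reverse-mode automatic differentiation over dense arrays.
#
# Activations are 5D arrays laid out (D1, D2, D3, C, N) = (z, y, x, channel,
# sample); convolution weights are (K1, K2, K3, Cin, Cout). Each op returns a
# node (an environment) holding the value, its parents, and a closure mapping
# the incoming gradient to parent gradients. agBackward() walks the graph in
# reverse topological order. Nodes whose subgraph contains no trainable
# parameter are skipped entirely, which is what keeps frozen loss networks
# out of the gradient computation.

.ag <- new.env(parent = emptyenv())
.ag$counter <- 0L

ag_node <- function(value, parents = list(), backfn = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$backfn <- backfn
  e$leaf <- length(parents) == 0L
  e$requires <- any(vapply(parents, function(p) p$requires, logical(1)))
  .ag$counter <- .ag$counter + 1L
  e$id <- .ag$counter
  class(e) <- "ag_node"
  e
}

ag_param <- function(value, requires_grad = TRUE) {
  n <- ag_node(value)
  n$requires <- requires_grad
  n
}

ag_const <- function(value) ag_node(value)

as_node <- function(x) if (inherits(x, "ag_node")) x else ag_const(x)

is_node <- function(x) inherits(x, "ag_node")

agValue <- function(x) if (is_node(x)) x$value else x

agBackward <- function(root) {
  if (length(root$value) != 1L)
    stop("agBackward: root must be a scalar node")
  topo <- vector("list", 256L)
  ntopo <- 0L
  seen <- new.env(parent = emptyenv())
  visit <- function(n) {
    key <- as.character(n$id)
    if (!is.null(seen[[key]]) || !n$requires) return(invisible(NULL))
    assign(key, TRUE, envir = seen)
    for (p in n$parents) visit(p)
    ntopo <<- ntopo + 1L
    if (ntopo > length(topo)) length(topo) <<- 2L * ntopo
    topo[[ntopo]] <<- n
    invisible(NULL)
  }
  visit(root)
  if (ntopo == 0L) return(invisible(NULL))
  root$grad <- 1
  for (i in rev(seq_len(ntopo))) {
    n <- topo[[i]]
    if (is.null(n$backfn)) next
    gs <- n$backfn(n$grad)
    ps <- n$parents
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      if (p$requires && !is.null(gs[[j]]))
        p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
    }
    if (!n$leaf) n$grad <- NULL  # free intermediate gradients early
  }
  invisible(NULL)
}

agZeroGrad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- convolution ------------------------------------------------------------

# pad = "same" keeps spatial dims (odd kernels, stride 1); otherwise a length-3
# integer vector of zero-padding per axis.
ag_conv3d <- function(x, w, b, stride = c(1L, 1L, 1L), pad = "same",
                      single = FALSE) {
  x <- as_node(x); w <- as_node(w); b <- as_node(b)
  xd <- dim(x$value); wd <- dim(w$value)
  stride <- as.integer(rep(stride, length.out = 3L))
  if (identical(pad, "same")) {
    if (any(wd[1:3] %% 2L == 0L))
      stop("conv3d: 'same' padding requires odd kernel dimensions")
    if (any(stride != 1L))
      stop("conv3d: 'same' padding requires stride 1")
    pad <- (wd[1:3] - 1L) %/% 2L
  }
  pad <- as.integer(rep(pad, length.out = 3L))
  v <- .conv3d_fw(x$value, xd, w$value, wd, b$value, stride, pad, single)
  od <- dim(v)
  ag_node(v, parents = list(x, w, b), backfn = function(g) {
    dim(g) <- od
    gx <- if (x$requires)
      .conv3d_bw_input(g, od, w$value, wd, xd, stride, pad, single) else NULL
    if (w$requires || b$requires) {
      gwb <- .conv3d_bw_weight(x$value, xd, g, od, wd, stride, pad, single)
      list(gx, gwb$gw, gwb$gb)
    } else list(gx, NULL, NULL)
  })
}

ag_maxpool3d <- function(x, window = 2L, stride = window) {
  x <- as_node(x)
  xd <- dim(x$value)
  window <- as.integer(rep(window, length.out = 3L))
  stride <- as.integer(rep(stride, length.out = 3L))
  r <- .maxpool3d_fw(x$value, xd, window, stride)
  ag_node(r$out, parents = list(x), backfn = function(g) {
    gx <- .maxpool3d_bw(as.numeric(g), r$argmax, length(x$value))
    dim(gx) <- xd
    list(gx)
  })
}

# ---- activations ------------------------------------------------------------

ag_relu <- function(x) {
  x <- as_node(x)
  mask <- x$value > 0
  v <- x$value * mask
  ag_node(v, parents = list(x), backfn = function(g) list(g * mask))
}

ag_prelu <- function(x, alpha) {
  x <- as_node(x); alpha <- as_node(alpha)
  xv <- x$value
  pos <- xv > 0
  a <- as.numeric(alpha$value)
  v <- xv * pos + a * xv * !pos
  ag_node(v, parents = list(x, alpha), backfn = function(g) {
    list(g * (pos + a * !pos), sum(g * xv * !pos))
  })
}

ag_identity <- function(x) as_node(x)

# ---- elementwise algebra ----------------------------------------------------

ag_add <- function(x, y) {
  x <- as_node(x); y <- as_node(y)
  ag_node(x$value + y$value, parents = list(x, y),
          backfn = function(g) list(g, g))
}

ag_sub <- function(x, y) {
  x <- as_node(x); y <- as_node(y)
  ag_node(x$value - y$value, parents = list(x, y),
          backfn = function(g) list(g, -g))
}

ag_mul <- function(x, y) {
  x <- as_node(x); y <- as_node(y)
  ag_node(x$value * y$value, parents = list(x, y),
          backfn = function(g) list(g * y$value, g * x$value))
}

ag_div <- function(x, y) {
  x <- as_node(x); y <- as_node(y)
  ag_node(x$value / y$value, parents = list(x, y),
          backfn = function(g) list(g / y$value, -g * x$value / y$value^2))
}

ag_scale <- function(x, k) {
  x <- as_node(x)
  ag_node(x$value * k, parents = list(x), backfn = function(g) list(g * k))
}

ag_shift <- function(x, k) {
  x <- as_node(x)
  ag_node(x$value + k, parents = list(x), backfn = function(g) list(g))
}

ag_abs <- function(x) {
  x <- as_node(x)
  s <- sign(x$value)
  ag_node(abs(x$value), parents = list(x), backfn = function(g) list(g * s))
}

ag_sum <- function(x) {
  x <- as_node(x)
  d <- dim(x$value)
  ag_node(sum(x$value), parents = list(x),
          backfn = function(g) list(array(g, dim = d)))
}

ag_mean <- function(x) {
  x <- as_node(x)
  d <- dim(x$value)
  n <- length(x$value)
  ag_node(mean(x$value), parents = list(x),
          backfn = function(g) list(array(g / n, dim = d)))
}

# ---- channel ops ------------------------------------------------------------

ag_slice_channels <- function(x, idx) {
  x <- as_node(x)
  xd <- dim(x$value)
  idx <- as.integer(idx)
  v <- x$value[, , , idx, , drop = FALSE]
  ag_node(v, parents = list(x), backfn = function(g) {
    gx <- array(0, dim = xd)
    gx[, , , idx, ] <- g
    list(gx)
  })
}

# ---- batch normalization ----------------------------------------------------

# Normalizes over (spatial x batch) per channel (dim 4). `state` is an
# environment with running_mean / running_var (unbiased), updated in training
# mode with the given momentum, used as-is in eval mode.
ag_batchnorm <- function(x, gamma, beta, state, training = TRUE,
                         momentum = 0.1, eps = 1e-5) {
  x <- as_node(x); gamma <- as_node(gamma); beta <- as_node(beta)
  xd <- dim(x$value)
  C <- xd[4L]; N <- xd[5L]; m <- prod(xd[1:3])
  M <- matrix(x$value, nrow = m, ncol = C * N)
  ch <- rep(seq_len(C), times = N)  # channel of each column
  cmean <- .colMeans(M, m, C * N)
  cmean2 <- .colMeans(M * M, m, C * N)
  if (training) {
    mu <- rowMeans(matrix(cmean, C, N))
    ex2 <- rowMeans(matrix(cmean2, C, N))
    va <- pmax(ex2 - mu^2, 0)
    mn <- m * N
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var +
      momentum * va * mn / max(mn - 1, 1)
  } else {
    mu <- state$running_mean
    va <- state$running_var
  }
  invstd <- 1 / sqrt(va + eps)
  gv <- as.numeric(gamma$value); bv <- as.numeric(beta$value)
  xhat <- (M - rep(mu[ch], each = m)) * rep(invstd[ch], each = m)
  v <- xhat * rep(gv[ch], each = m) + rep(bv[ch], each = m)
  dim(v) <- xd
  ag_node(v, parents = list(x, gamma, beta), backfn = function(g) {
    G <- matrix(g, nrow = m, ncol = C * N)
    sg_c <- .colSums(G, m, C * N)
    sgx_c <- .colSums(G * xhat, m, C * N)
    sg <- rowSums(matrix(sg_c, C, N))     # per-channel sum of g
    sgx <- rowSums(matrix(sgx_c, C, N))   # per-channel sum of g * xhat
    ggamma <- if (gamma$requires) sgx else NULL
    gbeta <- if (beta$requires) sg else NULL
    gx <- if (x$requires) {
      if (training) {
        mn <- m * N
        GX <- (G - rep((sg / mn)[ch], each = m) -
                 xhat * rep((sgx / mn)[ch], each = m)) *
          rep((gv * invstd)[ch], each = m)
        dim(GX) <- xd
        GX
      } else {
        GX <- G * rep((gv * invstd)[ch], each = m)
        dim(GX) <- xd
        GX
      }
    } else NULL
    list(gx, ggamma, gbeta)
  })
}

# ---- channel attention (MDTA) -----------------------------------------------

# channel-normalized, temperature-scaled, row-softmaxed similarity; Q and K
# are L x C with one column per channel
.channel_attention <- function(Q, K, tv) {
  L <- nrow(Q); C <- ncol(Q)
  qn <- sqrt(.colSums(Q * Q, L, C) + 1e-24)
  kn <- sqrt(.colSums(K * K, L, C) + 1e-24)
  Qh <- sweep(Q, 2L, qn, "/")
  Kh <- sweep(K, 2L, kn, "/")
  S0 <- crossprod(Qh, Kh)            # C x C, before temperature
  S <- tv * S0
  S <- S - apply(S, 1L, max)         # row-stable softmax (C x C recycling)
  E <- exp(S)
  A <- E / rowSums(E)
  list(A = A, Qh = Qh, Kh = Kh, qn = qn, kn = kn, S0 = S0)
}

# Transposed self-attention: per sample, channels are L2-normalized over the
# flattened spatial axis, a channels x channels similarity matrix is scaled by
# a learnable temperature and softmaxed row-wise, and values are mixed across
# channels. Cost is quadratic in channels and linear in voxels.
ag_mdta <- function(q, k, v, temp) {
  q <- as_node(q); k <- as_node(k); v <- as_node(v); temp <- as_node(temp)
  xd <- dim(q$value)
  L <- prod(xd[1:3]); C <- xd[4L]; N <- xd[5L]
  tv <- as.numeric(temp$value)
  out <- array(0, dim = xd)
  cache <- vector("list", N)
  for (n in seq_len(N)) {
    Q <- matrix(q$value[, , , , n], L, C)
    K <- matrix(k$value[, , , , n], L, C)
    V <- matrix(v$value[, , , , n], L, C)
    ca <- .channel_attention(Q, K, tv)
    out[, , , , n] <- V %*% t(ca$A)
    cache[[n]] <- c(ca, list(V = V))
  }
  ag_node(out, parents = list(q, k, v, temp), backfn = function(g) {
    dim(g) <- xd
    gq <- if (q$requires) array(0, dim = xd) else NULL
    gk <- if (k$requires) array(0, dim = xd) else NULL
    gv <- if (v$requires) array(0, dim = xd) else NULL
    gt <- 0
    for (n in seq_len(N)) {
      cc <- cache[[n]]
      gO <- matrix(g[, , , , n], L, C)
      gA <- crossprod(gO, cc$V)            # C x C  (gA = t(gO) V since O = V A^T)
      if (!is.null(gv)) gv[, , , , n] <- gO %*% cc$A
      gS <- (gA - rowSums(gA * cc$A)) * cc$A
      gt <- gt + sum(gS * cc$S0)
      gQh <- tv * cc$Kh %*% t(gS)
      gKh <- tv * cc$Qh %*% gS
      if (!is.null(gq)) {
        dots <- .colSums(gQh * cc$Qh, L, C)
        gq[, , , , n] <- sweep(gQh - sweep(cc$Qh, 2L, dots, "*"), 2L, cc$qn, "/")
      }
      if (!is.null(gk)) {
        dots <- .colSums(gKh * cc$Kh, L, C)
        gk[, , , , n] <- sweep(gKh - sweep(cc$Kh, 2L, dots, "*"), 2L, cc$kn, "/")
      }
    }
    list(gq, gk, gv, if (temp$requires) gt else NULL)
  })
}

ag_concat_channels <- function(xs) {
  xs <- lapply(xs, as_node)
  dims <- lapply(xs, function(x) dim(x$value))
  Cs <- vapply(dims, function(d) d[4L], integer(1))
  d0 <- dims[[1L]]
  out <- array(0, dim = c(d0[1:3], sum(Cs), d0[5L]))
  at <- 0L
  for (i in seq_along(xs)) {
    out[, , , at + seq_len(Cs[i]), ] <- xs[[i]]$value
    at <- at + Cs[i]
  }
  ag_node(out, parents = xs, backfn = function(g) {
    dim(g) <- dim(out)
    at <- 0L
    gs <- vector("list", length(xs))
    for (i in seq_along(xs)) {
      gs[[i]] <- g[, , , at + seq_len(Cs[i]), , drop = FALSE]
      at <- at + Cs[i]
    }
    gs
  })
}
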