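# Finite-difference checks of the reverse-mode engine: every analytic
# gradient the training loop relies on is compared against central
# differences on small random problems.

up <- asNamespace("uperc3d")

num_grad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

rel_err <- function(a, b) max(abs(a - b)) / max(1e-8, max(abs(b)))

test_that("convolution gradients match finite differences", {
  set.seed(1)
  xs <- array(rnorm(4 * 4 * 4 * 2 * 2), c(4, 4, 4, 2, 2))
  ws <- array(rnorm(3 * 3 * 3 * 2 * 2) * 0.3, c(3, 3, 3, 2, 2))
  bs <- rnorm(2) * 0.1
  run <- function(xv, wv, bv) {
    xn <- up$ag_param(xv); wn <- up$ag_param(wv); bn <- up$ag_param(bv)
    o <- up$ag_conv3d(xn, wn, bn)
    out <- up$ag_mean(up$ag_mul(o, up$ag_shift(o, 0.3)))
    list(out = out, xn = xn, wn = wn, bn = bn)
  }
  r <- run(xs, ws, bs)
  up$agBackward(r$out)
  expect_lt(rel_err(r$xn$grad,
                    num_grad(function(v) run(v, ws, bs)$out$value, xs)), 1e-6)
  expect_lt(rel_err(r$wn$grad,
                    num_grad(function(v) run(xs, v, bs)$out$value, ws)), 1e-6)
  expect_lt(rel_err(r$bn$grad,
                    num_grad(function(v) run(xs, ws, v)$out$value, bs)), 1e-6)
})

test_that("batch-norm gradients match finite differences in training mode", {
  set.seed(2)
  xs <- array(rnorm(4 * 4 * 4 * 2 * 2), c(4, 4, 4, 2, 2))
  gv <- c(1.2, 0.8); bv <- c(0.1, -0.2)
  st <- function() {
    e <- new.env(); e$running_mean <- rep(0, 2); e$running_var <- rep(1, 2); e
  }
  run <- function(xv, g, b) {
    xn <- up$ag_param(xv); gn <- up$ag_param(g); bn <- up$ag_param(b)
    out <- up$ag_mean(up$ag_mul(
      up$ag_batchnorm(xn, gn, bn, st(), training = TRUE),
      up$ag_shift(xn, 1)))
    list(out = out, xn = xn, gn = gn, bn = bn)
  }
  r <- run(xs, gv, bv)
  up$agBackward(r$out)
  expect_lt(rel_err(r$xn$grad,
                    num_grad(function(v) run(v, gv, bv)$out$value, xs)), 1e-6)
  expect_lt(rel_err(r$gn$grad,
                    num_grad(function(v) run(xs, v, bv)$out$value, gv)), 1e-6)
  expect_lt(rel_err(r$bn$grad,
                    num_grad(function(v) run(xs, gv, v)$out$value, bv)), 1e-6)
})

test_that("PReLU and max-pool gradients match finite differences", {
  set.seed(3)
  xs <- array(rnorm(4 * 4 * 4 * 2 * 2), c(4, 4, 4, 2, 2))
  run_pr <- function(xv, av) {
    xn <- up$ag_param(xv); an <- up$ag_param(av)
    out <- up$ag_mean(up$ag_mul(up$ag_prelu(xn, an), up$ag_shift(xn, 0.5)))
    list(out = out, xn = xn, an = an)
  }
  r <- run_pr(xs, 0.25)
  up$agBackward(r$out)
  expect_lt(rel_err(r$xn$grad,
                    num_grad(function(v) run_pr(v, 0.25)$out$value, xs)), 1e-6)
  expect_lt(rel_err(r$an$grad,
                    num_grad(function(v) run_pr(xs, v)$out$value, 0.25)), 1e-6)

  run_mp <- function(xv) {
    xn <- up$ag_param(xv)
    p <- up$ag_maxpool3d(xn, 2L)
    out <- up$ag_mean(up$ag_mul(p, p))
    list(out = out, xn = xn)
  }
  r <- run_mp(xs)
  up$agBackward(r$out)
  expect_lt(rel_err(r$xn$grad,
                    num_grad(function(v) run_mp(v)$out$value, xs)), 1e-6)
})

test_that("channel-attention (MDTA) gradients match finite differences", {
  set.seed(4)
  d <- c(3, 3, 2, 4, 2)
  xq <- array(rnorm(prod(d)), d)
  xk <- array(rnorm(prod(d)), d)
  xv <- array(rnorm(prod(d)), d)
  run <- function(q, k, v, tv) {
    qn <- up$ag_param(q); kn <- up$ag_param(k)
    vn <- up$ag_param(v); tn <- up$ag_param(tv)
    out <- up$ag_mean(up$ag_mul(up$ag_mdta(qn, kn, vn, tn),
                                up$ag_shift(vn, 0.2)))
    list(out = out, qn = qn, kn = kn, vn = vn, tn = tn)
  }
  r <- run(xq, xk, xv, 1.3)
  up$agBackward(r$out)
  expect_lt(rel_err(r$qn$grad,
                    num_grad(function(v) run(v, xk, xv, 1.3)$out$value, xq)),
            1e-6)
  expect_lt(rel_err(r$kn$grad,
                    num_grad(function(v) run(xq, v, xv, 1.3)$out$value, xk)),
            1e-6)
  expect_lt(rel_err(r$vn$grad,
                    num_grad(function(v) run(xq, xk, v, 1.3)$out$value, xv)),
            1e-6)
  expect_lt(rel_err(r$tn$grad,
                    num_grad(function(v) run(xq, xk, xv, v)$out$value, 1.3)),
            1e-6)
})

test_that("the differentiable SSIM objective has correct gradients", {
  set.seed(5)
  xa <- array(runif(12^3), c(12, 12, 12, 1, 1))
  xb <- array(runif(12^3), c(12, 12, 12, 1, 1))
  run <- function(av) {
    an <- up$ag_param(av)
    list(out = up$.ssim_objective_node(an, xb), an = an)
  }
  r <- run(xa)
  up$agBackward(r$out)
  idx <- sample(length(xa), 30)
  ng <- vapply(idx, function(i) {
    e <- 1e-5
    xp <- xa; xp[i] <- xp[i] + e
    xm <- xa; xm[i] <- xm[i] - e
    (run(xp)$out$value - run(xm)$out$value) / (2 * e)
  }, numeric(1))
  expect_lt(max(abs(r$an$grad[idx] - ng)) / max(abs(ng)), 1e-5)
  # objective value agrees with the metrics-module SSIM
  expect_equal(r$out$value,
               1 - ssim3d(array(xa, c(12, 12, 12)), array(xb, c(12, 12, 12))),
               tolerance = 1e-10)
})

test_that("single-precision convolution agrees with double to float accuracy", {
  set.seed(6)
  x <- array(rnorm(8 * 8 * 8 * 4 * 2), c(8, 8, 8, 4, 2))
  w <- array(rnorm(3 * 3 * 3 * 4 * 4) * 0.2, c(3, 3, 3, 4, 4))
  b <- rnorm(4) * 0.1
  v1 <- up$.conv3d_fw(x, dim(x), w, dim(w), b, c(1L, 1L, 1L), c(1L, 1L, 1L),
                      FALSE)
  v2 <- up$.conv3d_fw(x, dim(x), w, dim(w), b, c(1L, 1L, 1L), c(1L, 1L, 1L),
                      TRUE)
  expect_lt(max(abs(v1 - v2)) / max(abs(v1)), 1e-4)
})
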