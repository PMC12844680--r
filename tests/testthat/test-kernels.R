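# The layer library is hand-derived; every backward pass is checked
# against central finite differences on small random instances.

test_that("conv2d forward/backward match finite differences", {
  set.seed(42)
  for (case in list(list(k = 3L, s = 1L, p = 1L, g = 1L),
                    list(k = 3L, s = 2L, p = 1L, g = 2L),
                    list(k = 1L, s = 1L, p = 0L, g = 1L),
                    list(k = 7L, s = 1L, p = 3L, g = 4L))) {
    x <- array(rnorm(6 * 6 * 4 * 2), c(6, 6, 4, 2))
    ly <- ns$ly_conv(4L, 4L, case$k, stride = case$s, pad = case$p,
                     groups = case$g, init_sd = 0.3)
    f <- function(xx) sum(sin(ns$fwd_conv(ly, xx)$y))
    r <- ns$fwd_conv(ly, x)
    ly$g <- list()
    dx <- ns$bwd_conv(ly, r$cache, cos(r$y))
    expect_lt(rel_err(dx, num_grad(f, x)), 1e-7)
    fW <- function(w) {
      W0 <- ly$p$W; ly$p$W <- array(w, dim(W0))
      on.exit(ly$p$W <- W0)
      sum(sin(ns$fwd_conv(ly, x)$y))
    }
    expect_lt(rel_err(ly$g$W, num_grad(fW, ly$p$W)), 1e-7)
  }
})

test_that("channel layernorm gradients are exact", {
  set.seed(7)
  lnm <- ns$ly_ln(5L)
  lnm$p$gamma <- rnorm(5)
  lnm$p$beta <- rnorm(5)
  x <- array(rnorm(4 * 3 * 5 * 2), c(4, 3, 5, 2))
  f <- function(xx) sum(sin(ns$fwd_ln(lnm, xx)$y))
  r <- ns$fwd_ln(lnm, x)
  lnm$g <- list()
  dx <- ns$bwd_ln(lnm, r$cache, cos(r$y))
  expect_lt(rel_err(dx, num_grad(f, x)), 1e-6)
  fg <- function(g) {
    g0 <- lnm$p$gamma; lnm$p$gamma <- g
    on.exit(lnm$p$gamma <- g0)
    sum(sin(ns$fwd_ln(lnm, x)$y))
  }
  expect_lt(rel_err(lnm$g$gamma, num_grad(fg, lnm$p$gamma)), 1e-7)
  # normalization: per-position channel mean 0, variance 1 at gamma=1
  ln1 <- ns$ly_ln(5L)
  y <- ns$fwd_ln(ln1, x)$y
  mu <- apply(y, c(1, 2, 4), mean)
  expect_lt(max(abs(mu)), 1e-10)
})

test_that("bilinear 2x upsampling backward is the exact adjoint", {
  set.seed(1)
  x <- array(rnorm(4 * 5 * 3 * 2), c(4, 5, 3, 2))
  y <- ns$up2x_fwd(x)
  expect_equal(dim(y), c(8L, 10L, 3L, 2L))
  # <Ax, u> == <x, A^T u> for random u
  u <- array(rnorm(length(y)), dim(y))
  lhs <- sum(y * u)
  rhs <- sum(x * ns$up2x_bwd(u, 4L, 5L))
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("transposed 2x2 convolution matches finite differences", {
  set.seed(3)
  W <- array(rnorm(2 * 2 * 3 * 3, 0, 0.4), c(2, 2, 3, 3))
  b <- rnorm(3)
  x <- array(rnorm(3 * 4 * 3 * 2), c(3, 4, 3, 2))
  y <- ns$cpp_deconv2x(x, W, b)
  expect_equal(dim(y), c(6L, 8L, 3L, 2L))
  r <- ns$cpp_deconv2x_bwd(x, W, cos(y))
  f <- function(xx) sum(sin(ns$cpp_deconv2x(xx, W, b)))
  expect_lt(rel_err(r$dx, num_grad(f, x)), 1e-7)
  fW <- function(w) sum(sin(ns$cpp_deconv2x(x, array(w, dim(W)), b)))
  expect_lt(rel_err(r$dw, num_grad(fW, W)), 1e-7)
})

test_that("exact GELU and its derivative agree with the normal CDF form", {
  x <- array(seq(-4, 4, length.out = 64), c(8, 8, 1, 1))
  expect_equal(ns$gelu_fwd(x), x * pnorm(x), tolerance = 1e-12)
  dy <- array(1, dim(x))
  expect_equal(ns$gelu_bwd(x, dy), pnorm(x) + x * dnorm(x),
               tolerance = 1e-12)
})

test_that("one Adam step reproduces the hand-computed update", {
  p <- c(1, -2)
  g <- c(0.5, 0.25)
  m <- numeric(2); v <- numeric(2)
  out <- ns$cpp_adam_step(p, g, m, v, lr = 0.1, beta1 = 0.9,
                          beta2 = 0.999, eps = 1e-8, wd = 0, t = 1L)
  # with t = 1 the bias-corrected moments equal g and g^2
  expect_equal(out, p - 0.1 * g / (abs(g) + 1e-8), tolerance = 1e-12)
  expect_equal(m, 0.1 * g)
  expect_equal(v, 0.001 * g^2)
  # weight decay adds wd * p to the gradient
  m2 <- numeric(2); v2 <- numeric(2)
  gd <- g + 0.01 * p
  out2 <- ns$cpp_adam_step(p, g, m2, v2, 0.1, 0.9, 0.999, 1e-8,
                           wd = 0.01, t = 1L)
  expect_equal(out2, p - 0.1 * gd / (abs(gd) + 1e-8), tolerance = 1e-12)
})
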