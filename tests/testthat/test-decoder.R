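# CBAM attention contracts and the Up-Concat decoding path.

test_that("channel attention lies in (0,1) and matches direct evaluation on constant input", {
  set.seed(3)
  cb <- cbam_module(8L, reduction = 4L)
  x <- array(rnorm(5 * 5 * 8 * 2, 0, 2), c(5, 5, 8, 2))
  Mc <- channel_attention(x, params = cb)
  expect_true(all(Mc > 0 & Mc < 1))
  expect_equal(dim(Mc), c(8L, 2L))
  # spatially constant input: avg and max pools agree, so
  # Mc = sigmoid(2 * MLP(c)) per channel
  cvec <- rnorm(8)
  xc <- array(rep(cvec, each = 25), c(5, 5, 8, 1))
  mlp_out <- cb$mlp$p$W2 %*% pmax(cb$mlp$p$W1 %*% cbind(cvec) +
                                    cb$mlp$p$b1, 0) + cb$mlp$p$b2
  expect_equal(as.numeric(channel_attention(xc, params = cb)),
               as.numeric(1 / (1 + exp(-2 * mlp_out))), tolerance = 1e-12)
  expect_error(cbam_module(10L, reduction = 4L), "divisible")
})

test_that("channel attention permutes with channels under shared per-channel init", {
  # diagonal MLP acting identically per channel: permuting input
  # channels permutes the attention weights the same way
  C <- 6L
  cb <- cbam_module(C, reduction = 1L)
  cb$mlp$p$W1 <- diag(C) * 0.8
  cb$mlp$p$W2 <- diag(C) * 1.1
  cb$mlp$p$b1 <- rep(0.1, C)
  cb$mlp$p$b2 <- rep(-0.2, C)
  set.seed(10)
  x <- array(rnorm(4 * 4 * C * 1), c(4, 4, C, 1))
  perm <- sample(C)
  Mc <- channel_attention(x, params = cb)
  Mcp <- channel_attention(x[, , perm, , drop = FALSE], params = cb)
  expect_equal(Mcp, Mc[perm, , drop = FALSE], tolerance = 1e-12)
})

test_that("spatial attention is constant on constant planes and exact at 1x1", {
  set.seed(4)
  cb <- cbam_module(4L, reduction = 2L)
  xc <- array(rep(rnorm(4), each = 81), c(9, 9, 4, 1))
  Ms <- spatial_attention(xc, params = cb)
  expect_true(all(Ms > 0 & Ms < 1))
  # interior of a constant plane (away from zero-padding) is constant
  interior <- Ms[4:6, 4:6, 1, 1]
  expect_lt(diff(range(interior)), 1e-12)
  # 1x1 input: sigma of the kernel center response on [avg; max]
  x1 <- array(rnorm(4), c(1, 1, 4, 1))
  a <- mean(x1); mx <- max(x1)
  k <- cb$sconv$p$W
  resp <- k[4, 4, 1, 1] * a + k[4, 4, 2, 1] * mx + cb$sconv$p$b
  expect_equal(as.numeric(spatial_attention(x1, params = cb)),
               as.numeric(1 / (1 + exp(-resp))), tolerance = 1e-12)
})

test_that("CBAM is a contraction, fixes zero, and composes its two factors", {
  set.seed(5)
  cb <- cbam_module(8L, reduction = 4L)
  x <- array(rnorm(6 * 6 * 8 * 2, 0, 3), c(6, 6, 8, 2))
  y <- cbam(x, params = cb)
  expect_true(all(abs(y) <= abs(x)))
  expect_equal(cbam(array(0, dim(x)), params = cb),
               array(0, dim(x)))
  # equals applying channel then spatial attention by hand
  Mc <- channel_attention(x, params = cb)
  X1 <- ns$mul_chan(x, Mc)
  Ms <- spatial_attention(X1, params = cb)
  expect_equal(y, ns$mul_spat(X1, Ms), tolerance = 1e-12)
  # parallel variant computes both maps on the raw input
  cbp <- cbam_module(8L, reduction = 4L, order = "parallel")
  cbp$mlp <- cb$mlp; cbp$sconv <- cb$sconv
  yp <- cbam(x, params = cbp)
  expect_equal(yp, ns$mul_spat(ns$mul_chan(x, Mc),
                               spatial_attention(x, params = cb)),
               tolerance = 1e-12)
})

test_that("up_concat upsamples, orders the concatenation, and is differentiable", {
  set.seed(6)
  uc <- up_concat_module(4L, 2L, 3L, cbam_reduction = 2L)
  deep <- array(rnorm(2 * 2 * 4 * 2), c(2, 2, 4, 2))
  skip <- array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2))
  r <- ns$uc_fwd(uc, deep, skip)
  expect_equal(dim(r$y), c(4L, 4L, 3L, 2L))
  # concatenation order: first c_deep channels come from the upsampled
  # deep input — zeroing the skip changes only the trailing block
  r2 <- ns$uc_fwd(uc, deep, skip * 0)
  expect_identical(r$cache$cat[, , 1:4, ], r2$cache$cat[, , 1:4, ])
  expect_false(identical(r$cache$cat[, , 5:6, ], r2$cache$cat[, , 5:6, ]))
  # gradient reaches both inputs
  for (m in ns$collect_mods(uc)) m$g <- list()
  b <- ns$uc_bwd(uc, r$cache, array(1, dim(r$y)))
  expect_gt(sum(abs(b$ddeep)), 0)
  expect_gt(sum(abs(b$dskip)), 0)
  expect_error(ns$uc_fwd(uc, deep, array(0, c(8, 8, 2, 2))),
               "does not match")
})

test_that("decoding restores input resolution through exactly four stages", {
  set.seed(7)
  for (cb_on in c(TRUE, FALSE)) {
    dec <- decoder_module(widths = c(4L, 8L, 12L, 16L), c1 = 2L,
                          cbam_reduction = 2L, cbam_enabled = cb_on)
    expect_length(grep("^uc", names(dec)), 4L)
    mk <- function(C, h) array(rnorm(h * h * C), c(h, h, C, 1))
    logits <- decode(dec, mk(16, 2), mk(12, 4), mk(8, 8), mk(4, 16),
                     mk(2, 32))
    expect_equal(dim(logits), c(64L, 64L, 2L, 1L))
  }
})

test_that("deconv upsampling variant preserves the decode contract", {
  set.seed(8)
  dec <- decoder_module(widths = c(4L, 8L, 12L, 16L), c1 = 2L,
                        cbam_reduction = 2L, upsample_mode = "deconv")
  mk <- function(C, h) array(rnorm(h * h * C), c(h, h, C, 1))
  logits <- decode(dec, mk(16, 2), mk(12, 4), mk(8, 8), mk(4, 16),
                   mk(2, 32))
  expect_equal(dim(logits), c(64L, 64L, 2L, 1L))
})
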