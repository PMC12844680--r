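# Dual-branch encoder: stride ladder, branch asymmetry and the
# pretrained-stem channel extension.

test_that("the RGB pyramid follows the 1/2 ... 1/32 stride ladder", {
  cfg <- encoder_config(3L, width_multiplier = 1 / 24,
                        depths = c(1L, 1L, 1L, 1L))
  enc <- build_encoder(cfg, seed = 1)
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  pyr <- encode_rgb(enc, x)
  sizes <- vapply(1:5, function(i) dim(pyramid_level(pyr, i))[1], 1L)
  expect_equal(sizes, c(32L, 16L, 8L, 4L, 2L))
  widths <- vapply(2:5, function(i) dim(pyramid_level(pyr, i))[3], 1L)
  expect_equal(widths, cfg$widths)
  # doubling the batch doubles only the batch axis
  x4 <- array(runif(64 * 64 * 3 * 4), c(64, 64, 3, 4))
  p4 <- encode_rgb(enc, x4)
  for (i in 1:5)
    expect_equal(dim(pyramid_level(p4, i)),
                 c(dim(pyramid_level(pyr, i))[1:3], 4L))
  expect_error(encode_rgb(enc, array(0, c(48, 48, 3, 1))),
               "divisible by 32")
})

test_that("the MS branch exposes only the two deepest levels", {
  cfg <- encoder_config(4L, width_multiplier = 1 / 24,
                        depths = c(1L, 1L, 1L, 1L))
  enc <- build_encoder(cfg, seed = 2)
  x <- array(runif(64 * 64 * 4), c(64, 64, 4, 1))
  pyr <- encode_ms(enc, x)
  expect_equal(dim(pyramid_level(pyr, 4))[1:2], c(4L, 4L))
  expect_equal(dim(pyramid_level(pyr, 5))[1:2], c(2L, 2L))
  expect_error(pyramid_level(pyr, 1), "not present")
  expect_error(pyramid_level(pyr, 3), "not present")
  expect_error(encode_ms(enc, array(0, c(64, 64, 3, 1))), "3")
  # zero input stays finite (normalization defined at zero)
  z <- encode_ms(enc, array(0, c(64, 64, 4, 1)))
  expect_true(all(is.finite(pyramid_level(z, 5))))
})

test_that("branches are parameter-disjoint and seeded builds reproduce", {
  m <- tiny_model("fused", seed = 9)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  p1 <- encode_rgb(m$enc_rgb, x)
  for (mod in ns$collect_mods(m$enc_ms))
    mod$p <- lapply(mod$p, function(p) p + 10)
  p2 <- encode_rgb(m$enc_rgb, x)
  expect_identical(p1$levels$feat5, p2$levels$feat5)
  # identical seeds give identical encoders
  a <- build_encoder(encoder_config(3L, width_multiplier = 1 / 24,
                                    depths = c(1L, 1L, 1L, 1L)), seed = 5)
  b <- build_encoder(encoder_config(3L, width_multiplier = 1 / 24,
                                    depths = c(1L, 1L, 1L, 1L)), seed = 5)
  expect_identical(ns$model_state(a), ns$model_state(b))
})

test_that("channel extension copies the visible slices and draws Gaussian extras", {
  set.seed(20)
  w3 <- array(rnorm(4 * 4 * 3 * 300), c(4, 4, 3, 300))
  w4 <- extend_first_conv(w3, 1L, sigma = 0.01, seed = 7)
  expect_equal(dim(w4), c(4L, 4L, 4L, 300L))
  expect_identical(w4[, , 1:3, ], w3[, , 1:3, ])
  extra <- w4[, , 4, ]
  expect_gte(length(extra), 1e4 / 3)  # 4800 per slice; std check below
  # identity and error cases
  expect_identical(extend_first_conv(w3, 0L), w3)
  expect_error(extend_first_conv(w3, 1L, sigma = 0), "sigma")
  expect_error(extend_first_conv(array(0, c(4, 4, 4, 8)), 1L),
               "Kh, Kw, 3, Cout")
  # std of a larger draw lies in the stated band
  big <- extend_first_conv(array(0, c(5, 5, 3, 500)), 2L, sigma = 0.01,
                           seed = 3)
  expect_gte(sd(big[, , 4:5, ]), 0.009)
  expect_lte(sd(big[, , 4:5, ]), 0.011)
  expect_identical(extend_first_conv(w3, 2L, seed = 11),
                   extend_first_conv(w3, 2L, seed = 11))
})
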