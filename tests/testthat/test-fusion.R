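# Cross-modal fusion: the attention math against a brute-force oracle,
# the residual/identity structure, and the dynamic weighting.

test_that("zero gains make the cross-attention block an exact identity", {
  set.seed(2)
  m <- cotsr_module(6L, qk_reduction = 2L, gamma_init = 0)
  X1 <- array(rnorm(4 * 4 * 6 * 2), c(4, 4, 6, 2))
  X2 <- array(rnorm(4 * 4 * 6 * 2), c(4, 4, 6, 2))
  r <- cotsr_forward(X1, X2, m)
  expect_identical(r$Y1, X1)
  expect_identical(r$Y2, X2)
})

test_that("a single-position toy reproduces the hand evaluation", {
  # 1x1 spatial, identity projections, X1 = 2, X2 = 3, gains 1:
  # softmax of one score is 1, so Y1 = 2 + 3 = 5 and Y2 = 3 + 2 = 5
  m <- identity_cotsr(1L, g1 = 1, g2 = 1)
  X1 <- array(2, c(1, 1, 1, 1))
  X2 <- array(3, c(1, 1, 1, 1))
  r <- cotsr_forward(X1, X2, m)
  expect_equal(as.numeric(r$Y1), 5)
  expect_equal(as.numeric(r$Y2), 5)
})

test_that("2x2 toys with identity projections match the brute-force oracle", {
  set.seed(9)
  for (rep in 1:5) {
    C <- 3L
    m <- identity_cotsr(C, g1 = 0.7, g2 = 1.3)
    X1 <- array(rnorm(2 * 2 * C * 2), c(2, 2, C, 2))
    X2 <- array(rnorm(2 * 2 * C * 2), c(2, 2, C, 2))
    r <- cotsr_forward(X1, X2, m)
    o <- brute_cotsr(X1, X2, 0.7, 1.3)
    expect_equal(r$Y1, o$Y1, tolerance = 1e-6)
    expect_equal(r$Y2, o$Y2, tolerance = 1e-6)
  }
  expect_error(cotsr_forward(array(0, c(2, 2, 3, 1)),
                             array(0, c(2, 2, 3, 2)),
                             identity_cotsr(3L)), "shapes differ")
})

test_that("attention rows are probability distributions", {
  set.seed(12)
  m <- cotsr_module(8L, qk_reduction = 4L, gamma_init = 0.5)
  X1 <- array(rnorm(4 * 4 * 8 * 3, 0, 3), c(4, 4, 8, 3))
  X2 <- array(rnorm(4 * 4 * 8 * 3, 0, 3), c(4, 4, 8, 3))
  r <- ns$cotsr_fwd(m, X1, X2)
  for (n in 1:3) {
    expect_lt(max(abs(rowSums(r$cache$A1[[n]]) - 1)), 1e-6)
    expect_lt(max(abs(rowSums(r$cache$A2[[n]]) - 1)), 1e-6)
    expect_true(all(r$cache$A1[[n]] >= 0))
  }
})

test_that("dynamic weighting is exact elementwise arithmetic", {
  u <- array(1, c(2, 2, 3, 1))
  w10 <- weight_fusion_module(alpha_init = 1, beta_init = 0)
  expect_identical(weight_fusion(2 * u, 5 * u, w10), 2 * u)
  whalf <- weight_fusion_module(0.5, 0.5)
  expect_equal(weight_fusion(2 * u, 4 * u, whalf), 3 * u)
  # with both inputs at unit value the fusion output equals alpha+beta,
  # e.g. learned deep-stage weights 1.107 and 0.971 sum to 2.078
  wl <- weight_fusion_module(1.107, 0.971)
  expect_equal(weight_fusion(u, u, wl), 2.078 * u, tolerance = 1e-12)
  expect_error(weight_fusion(u, array(1, c(2, 2, 4, 1)), w10), "shapes")
})

test_that("fusing pyramids applies independent stage parameters", {
  set.seed(4)
  mk <- function(C, h) array(rnorm(h * h * C * 2), c(h, h, C, 2))
  rgb_pyr <- ns$new_pyramid(list(feat4 = mk(4, 4), feat5 = mk(8, 2)), "rgb")
  ms_pyr <- ns$new_pyramid(list(feat4 = mk(4, 4), feat5 = mk(8, 2)), "ms")
  cif <- cif_module(4L, 8L, qk_reduction = 2L)
  r0 <- cif_forward(rgb_pyr, ms_pyr, cif)
  # gamma = 0, alpha = 1, beta = 0 => fused levels equal the RGB pyramid
  cif$wf4$beta$p$v <- 0; cif$wf5$beta$p$v <- 0
  r <- cif_forward(rgb_pyr, ms_pyr, cif)
  expect_equal(r$fused4, rgb_pyr$levels$feat4)
  expect_equal(r$fused5, rgb_pyr$levels$feat5)
  expect_equal(dim(r0$fused4), dim(rgb_pyr$levels$feat4))
  expect_equal(dim(r0$fused5), dim(rgb_pyr$levels$feat5))
  # perturbing feat5's alpha leaves fused4 unchanged
  cif$wf4$beta$p$v <- 1; cif$wf5$beta$p$v <- 1
  base <- cif_forward(rgb_pyr, ms_pyr, cif)
  cif$wf5$alpha$p$v <- 3
  pert <- cif_forward(rgb_pyr, ms_pyr, cif)
  expect_identical(pert$fused4, base$fused4)
  expect_false(identical(pert$fused5, base$fused5))
  # missing level errors
  expect_error(cif_forward(ns$new_pyramid(list(feat4 = mk(4, 4)), "rgb"),
                           ms_pyr, cif), "feat5")
})

test_that("gains and fusion weights all receive gradient under a scalar loss", {
  set.seed(6)
  cif <- cif_module(4L, 6L, qk_reduction = 2L, gamma_init = 0.3)
  mk <- function(C, h) array(rnorm(h * h * C * 2), c(h, h, C, 2))
  f4r <- mk(4, 4); f4m <- mk(4, 4); f5r <- mk(6, 2); f5m <- mk(6, 2)
  r <- ns$cif_fwd(cif, f4r, f4m, f5r, f5m)
  for (m in ns$collect_mods(cif)) m$g <- list()
  ns$cif_bwd(cif, r$cache, r$fused4 * 0 + 1, r$fused5 * 0 + 1)
  for (sc in list(cif$cotsr4$g1, cif$cotsr4$g2, cif$cotsr5$g1,
                  cif$cotsr5$g2, cif$wf4$alpha, cif$wf4$beta,
                  cif$wf5$alpha, cif$wf5$beta))
    expect_true(abs(sc$g$v) > 0)
})

test_that("batch permutation commutes with the fusion forward", {
  set.seed(8)
  m <- cotsr_module(4L, qk_reduction = 2L, gamma_init = 0.9)
  X1 <- array(rnorm(3 * 3 * 4 * 3), c(3, 3, 4, 3))
  X2 <- array(rnorm(3 * 3 * 4 * 3), c(3, 3, 4, 3))
  r <- cotsr_forward(X1, X2, m)
  perm <- c(3, 1, 2)
  rp <- cotsr_forward(X1[, , , perm, drop = FALSE],
                      X2[, , , perm, drop = FALSE], m)
  expect_equal(rp$Y1, r$Y1[, , , perm, drop = FALSE], tolerance = 1e-12)
  expect_equal(rp$Y2, r$Y2[, , , perm, drop = FALSE], tolerance = 1e-12)
})
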