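# Full-model composition contracts.

test_that("evaluation forward is deterministic and shape-correct", {
  m <- tiny_model()
  set.seed(1)
  rgb <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  ms <- array(runif(32 * 32 * 4 * 2), c(32, 32, 4, 2))
  o1 <- model_forward(m, rgb, ms)
  o2 <- model_forward(m, rgb, ms)
  expect_identical(o1$logits, o2$logits)
  expect_equal(dim(o1$logits), c(32L, 32L, 2L, 2L))
  expect_equal(dim(o1$mask), c(32L, 32L, 2L))
  expect_true(all(o1$mask %in% c(0, 1)))
  expect_true(all(o1$prob >= 0 & o1$prob <= 1))
  expect_error(model_forward(m, rgb, array(0, c(64, 64, 4, 2))),
               "co-registered")
})

test_that("argmax ties break toward background", {
  lg <- array(0, c(2, 2, 2, 1))  # exact tie everywhere
  out <- ns$logits_to_output(lg)
  expect_true(all(out$mask == 0))
  lg[1, 1, 2, 1] <- 1e-9
  expect_equal(ns$logits_to_output(lg)$mask[1, 1, 1], 1)
})

test_that("with zero gains and beta = 0 the fused model ignores the MS input", {
  m <- tiny_model("fused", seed = 4)
  m$cif$wf4$beta$p$v <- 0
  m$cif$wf5$beta$p$v <- 0
  set.seed(2)
  rgb <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  a <- model_forward(m, rgb, array(runif(32 * 32 * 4), c(32, 32, 4, 1)))
  b <- model_forward(m, rgb, array(runif(32 * 32 * 4), c(32, 32, 4, 1)))
  expect_equal(a$logits, b$logits, tolerance = 1e-12)
})

test_that("single-modality variants bypass the other branch", {
  mr <- tiny_model("rgb", seed = 5)
  set.seed(3)
  rgb <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  a <- model_forward(mr, rgb, array(runif(32 * 32 * 4), c(32, 32, 4, 1)))
  b <- model_forward(mr, rgb, NULL)
  expect_identical(a$logits, b$logits)
  mm <- tiny_model("ms", seed = 5)
  ms <- array(runif(32 * 32 * 4), c(32, 32, 4, 1))
  o <- model_forward(mm, NULL, ms)
  expect_equal(dim(o$logits), c(32L, 32L, 2L, 1L))
  # the fused model strictly contains the rgb-only variant's parameters
  mf <- tiny_model("fused", seed = 5)
  expect_gt(n_params(mf), n_params(mr))
  expect_error(build_model(model_config(), "hyperspectral"))
})

test_that("a training step updates every reachable parameter group", {
  # 64-px inputs keep the deepest attention at 2x2 positions: with a
  # single position the softmax is constantly 1 and the query/key
  # projections correctly receive zero gradient
  m <- tiny_model("fused", seed = 6, gamma_init = 0.2)
  set.seed(4)
  rgb <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  ms <- array(runif(64 * 64 * 4 * 2), c(64, 64, 4, 2))
  mask <- array(rbinom(64 * 64 * 2, 1, 0.3), c(64, 64, 2))
  ns$zero_grads(m)
  fw <- ns$model_fwd(m, rgb, ms, train = TRUE)
  ls <- softmax_ce(fw$logits, mask)
  ns$model_bwd(m, fw$cache, ls$dlogits)
  mods <- ns$collect_mods(m)
  # the MS branch's auxiliary shallow block is unused in fused mode;
  # every other module must receive gradient
  aux_ms <- ns$collect_mods(m$enc_ms$aux)
  used <- setdiff(seq_along(mods),
                  which(vapply(mods, function(x)
                    any(vapply(aux_ms, identical, TRUE, x)), TRUE)))
  for (i in used) {
    mod <- mods[[i]]
    expect_gt(sum(vapply(mod$g, function(g) sum(abs(g)), 1)), 0)
  }
})

test_that("checkpoints round-trip through disk", {
  m <- tiny_model("fused", seed = 8)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  set.seed(5)
  rgb <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  ms <- array(runif(32 * 32 * 4), c(32, 32, 4, 1))
  expect_identical(model_forward(m, rgb, ms)$logits,
                   model_forward(m2, rgb, ms)$logits)
  unlink(f)
})

test_that("cross-entropy matches a direct computation and its gradient sums to zero", {
  set.seed(6)
  lg <- array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2))
  lab <- array(rbinom(32, 1, 0.5), c(4, 4, 2))
  r <- softmax_ce(lg, lab)
  # direct evaluation
  ref <- 0
  for (n in 1:2) for (i in 1:4) for (j in 1:4) {
    p <- exp(lg[i, j, , n]); p <- p / sum(p)
    ref <- ref - log(p[lab[i, j, n] + 1])
  }
  expect_equal(r$loss, ref / 32, tolerance = 1e-12)
  # gradient of softmax-CE sums to zero over classes
  expect_lt(max(abs(r$dlogits[, , 1, ] + r$dlogits[, , 2, ])), 1e-12)
  # weighting the crown class shifts the loss toward crown errors
  rw <- softmax_ce(lg, lab, class_weights = c(1, 5))
  expect_false(isTRUE(all.equal(r$loss, rw$loss)))
})
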