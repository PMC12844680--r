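# Metrics against a per-pixel brute-force oracle and the algebraic
# identities that hold for binary confusion tables.

brute_counts <- function(pred, label) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && label[i] == 1) tp <- tp + 1
    else if (pred[i] == 1 && label[i] == 0) fp <- fp + 1
    else if (pred[i] == 0 && label[i] == 1) fn <- fn + 1
    else tn <- tn + 1
  }
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

test_that("confusion counts equal a per-pixel loop on random masks", {
  set.seed(31)
  for (rep in 1:20) {
    p <- matrix(rbinom(256, 1, runif(1)), 16, 16)
    l <- matrix(rbinom(256, 1, runif(1)), 16, 16)
    cc <- confusion(p, l)
    bc <- brute_counts(p, l)
    expect_equal(c(TP = cc$TP, FP = cc$FP, FN = cc$FN, TN = cc$TN), bc)
  }
  l <- matrix(rbinom(64, 1, 0.5), 8, 8)
  same <- confusion(l, l)
  expect_equal(same$FP + same$FN, 0)
  comp <- confusion(1 - l, l)
  expect_equal(comp$TP + comp$TN, 0)
  expect_error(confusion(matrix(0, 2, 2), matrix(0, 3, 3)), "differ")
  expect_error(confusion(matrix(2, 2, 2), matrix(0, 2, 2)), "binary")
})

test_that("the worked 4x4 all-positive example gives the textbook values", {
  label <- matrix(0, 4, 4); label[1:4] <- 1   # 4 positives
  pred <- matrix(1, 4, 4)
  cc <- confusion(pred, label)
  expect_equal(c(cc$TP, cc$FP, cc$FN, cc$TN), c(4, 12, 0, 0))
  expect_equal(as.numeric(iou(cc)), 25)
  expect_equal(as.numeric(pa(cc)), 25)
  expect_equal(as.numeric(precision(cc)), 25)
  expect_equal(as.numeric(recall(cc)), 100)
  expect_equal(as.numeric(f1(cc)), 40)
  expect_equal(as.numeric(mean_iou(cc)), 12.5)  # background IoU is 0
})

test_that("perfect predictions score 100 and degenerate ratios are flagged", {
  l <- matrix(rbinom(64, 1, 0.5), 8, 8)
  cc <- confusion(l, l)
  for (f in list(iou, pa, precision, recall, f1, mean_iou))
    expect_equal(as.numeric(f(cc)), 100)
  none <- confusion(matrix(0, 4, 4), matrix(0, 4, 4))
  expect_true(is.na(iou(none)))
  expect_true(attr(iou(none), "undefined"))
  expect_equal(as.numeric(pa(none)), 100)
  expect_equal(as.numeric(mean_iou(none)), 100)  # background class defined
})

test_that("F1 equals 2*IoU/(1+IoU) for random counts, and mIoU is label-symmetric", {
  set.seed(5)
  for (rep in 1:50) {
    cc <- ns$new_confusion(sample(0:50, 1) + 1, sample(0:50, 1),
                           sample(0:50, 1), sample(0:50, 1))
    i <- as.numeric(iou(cc)) / 100
    expect_equal(as.numeric(f1(cc)), 100 * 2 * i / (1 + i),
                 tolerance = 1e-12)
    expect_lte(as.numeric(iou(cc)),
               min(as.numeric(precision(cc)), as.numeric(recall(cc))) +
                 1e-9)
    # swapping class labels swaps the two per-class IoUs only
    sw <- ns$new_confusion(cc$TN, cc$FN, cc$FP, cc$TP)
    expect_equal(as.numeric(mean_iou(cc)), as.numeric(mean_iou(sw)),
                 tolerance = 1e-12)
  }
})

test_that("dataset evaluation pools counts additively and ignores order", {
  set.seed(17)
  sp <- tiny_spec()
  samples <- generate_dataset(sp, 3, seed = 21)$samples
  model <- tiny_model()
  ev <- evaluate_dataset(model, samples)
  # pooled counts equal the sum of per-tile counts
  cc <- lapply(samples, function(s) {
    out <- model_forward(model, array(s$rgb, c(dim(s$rgb)[1:2], 3, 1)),
                         array(s$ms, c(dim(s$ms)[1:2], 4, 1)))
    confusion(out$mask[, , 1], s$mask)
  })
  expect_equal(ev$counts$TP, sum(vapply(cc, `[[`, 1, "TP")))
  expect_equal(ev$counts$N, sum(vapply(cc, `[[`, 1, "N")))
  ev_rev <- evaluate_dataset(model, rev(samples))
  expect_equal(ev$pooled, ev_rev$pooled)
  # duplicating every tile leaves the pooled ratios unchanged
  ev_dup <- evaluate_dataset(model, c(samples, samples))
  expect_equal(ev$pooled, ev_dup$pooled, tolerance = 1e-12)
  expect_error(evaluate_dataset(model, list()), "empty")
})
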