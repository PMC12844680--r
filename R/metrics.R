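# Pixel-level evaluation: confusion counts and the four headline
# metrics (IoU, PA, Precision, F1) plus recall and class-mean IoU.
# Crown pixels (value 1) are the positive class. All metrics are
# returned as percentages. Ratios with a zero denominator return a
# flagged NA (never a silent 0); dataset-level aggregation is micro
# (pixel counts pooled first), which sidesteps per-tile undefined
# ratios.

#' Pixelwise confusion counts
#'
#' @param pred,label binary arrays/matrices of equal shape with values
#'   in \{0, 1\}; class 1 (crown) is the positive class.
#' @return a `confusion_counts` list with TP, FP, FN, TN and N.
#' @export
confusion <- function(pred, label) {
  if (!identical(dim(pred), dim(label)) || length(pred) != length(label))
    stop("pred and label shapes differ")
  pv <- as.vector(pred); lv <- as.vector(label)
  if (!all(pv %in% c(0, 1)) || !all(lv %in% c(0, 1)))
    stop("pred and label must be binary (0/1)")
  tp <- sum(pv == 1 & lv == 1)
  fp <- sum(pv == 1 & lv == 0)
  fn <- sum(pv == 0 & lv == 1)
  tn <- sum(pv == 0 & lv == 0)
  new_confusion(tp, fp, fn, tn)
}

new_confusion <- function(tp, fp, fn, tn) {
  structure(list(TP = tp, FP = fp, FN = fn, TN = tn,
                 N = tp + fp + fn + tn),
            class = "confusion_counts")
}

add_confusion <- function(a, b) {
  new_confusion(a$TP + b$TP, a$FP + b$FP, a$FN + b$FN, a$TN + b$TN)
}

ratio_pct <- function(num, den) {
  if (den == 0) return(structure(NA_real_, undefined = TRUE))
  100 * num / den
}

#' Segmentation metrics from confusion counts
#'
#' `iou` = TP/(TP+FP+FN), `pa` = (TP+TN)/N, `precision` = TP/(TP+FP),
#' `recall` = TP/(TP+FN), `f1` = harmonic mean of precision and recall;
#' all x100. A zero denominator yields `NA` with attribute
#' `undefined = TRUE`.
#'
#' @param c a `confusion_counts` object from [confusion()].
#' @return percentage value (possibly flagged NA).
#' @export
iou <- function(c) ratio_pct(c$TP, c$TP + c$FP + c$FN)

#' @rdname iou
#' @export
pa <- function(c) ratio_pct(c$TP + c$TN, c$N)

#' @rdname iou
#' @export
precision <- function(c) ratio_pct(c$TP, c$TP + c$FP)

#' @rdname iou
#' @export
recall <- function(c) ratio_pct(c$TP, c$TP + c$FN)

#' @rdname iou
#' @export
f1 <- function(c) {
  # computed from counts as 2TP/(2TP+FP+FN): identical to the harmonic
  # mean of precision and recall where both are defined, and extends
  # continuously to 0 when TP = 0 but errors exist
  ratio_pct(2 * c$TP, 2 * c$TP + c$FP + c$FN)
}

#' Class-mean IoU of a binary segmentation
#'
#' Unweighted mean of the background-class and crown-class IoU. A
#' binary confusion table determines both classes (background IoU is
#' TN/(TN+FP+FN)); classes whose IoU is undefined are dropped from the
#' mean, and the result is a flagged NA when both are undefined.
#'
#' @param per_class either a single `confusion_counts` (crown-positive)
#'   or a list of two `confusion_counts` (class 0, class 1).
#' @return percentage value.
#' @export
mean_iou <- function(per_class) {
  if (inherits(per_class, "confusion_counts")) {
    c1 <- per_class
    c0 <- new_confusion(c1$TN, c1$FN, c1$FP, c1$TP)
  } else {
    c0 <- per_class[[1]]; c1 <- per_class[[2]]
  }
  v <- c(iou(c0), iou(c1))
  if (all(is.na(v))) return(structure(NA_real_, undefined = TRUE))
  mean(v, na.rm = TRUE)
}

metric_row <- function(cc) {
  c(IoU = as.numeric(iou(cc)), PA = as.numeric(pa(cc)),
    Precision = as.numeric(precision(cc)), Recall = as.numeric(recall(cc)),
    F1 = as.numeric(f1(cc)), mIoU = as.numeric(mean_iou(cc)))
}

#' Evaluate a model over a set of multimodal samples
#'
#' Predicts every tile, pools pixel counts over the whole set (micro
#' aggregation) and computes the metrics once on the pooled counts;
#' per-tile metrics and a macro (mean-of-tiles) summary are also
#' reported.
#'
#' @param model a model from [build_model()].
#' @param samples non-empty list of `multimodal_sample` objects.
#' @param batch_size tiles per forward pass.
#' @return list with `pooled` (named metric vector), `per_tile`
#'   (data.frame), `macro` (mean of defined per-tile metrics) and
#'   `counts` (pooled `confusion_counts`).
#' @export
evaluate_dataset <- function(model, samples, batch_size = 4L) {
  if (length(samples) == 0L) stop("empty sample list")
  pooled <- new_confusion(0, 0, 0, 0)
  rows <- vector("list", length(samples))
  idx <- split(seq_along(samples),
               ceiling(seq_along(samples) / batch_size))
  for (b in idx) {
    batch <- stack_samples(samples[b])
    out <- model_forward(model, batch$rgb, batch$ms)
    for (k in seq_along(b)) {
      cc <- confusion(out$mask[, , k], batch$mask[, , k])
      pooled <- add_confusion(pooled, cc)
      rows[[b[k]]] <- metric_row(cc)
    }
  }
  per_tile <- as.data.frame(do.call(rbind, rows))
  per_tile <- cbind(tile = seq_along(samples), per_tile)
  list(pooled = metric_row(pooled), per_tile = per_tile,
       macro = colMeans(per_tile[, -1, drop = FALSE], na.rm = TRUE),
       counts = pooled)
}

#' Stack a list of multimodal samples into batch arrays
#'
#' @param samples list of `multimodal_sample` objects of equal size.
#' @return list with `rgb` (H, W, 3, N), `ms` (H, W, 4, N) and `mask`
#'   (H, W, N).
#' @export
stack_samples <- function(samples) {
  d <- dim(samples[[1]]$rgb)
  n <- length(samples)
  rgb <- array(0, c(d[1], d[2], 3L, n))
  ms <- array(0, c(d[1], d[2], 4L, n))
  mask <- array(0, c(d[1], d[2], n))
  for (i in seq_len(n)) {
    rgb[, , , i] <- samples[[i]]$rgb
    ms[, , , i] <- samples[[i]]$ms
    mask[, , i] <- samples[[i]]$mask
  }
  list(rgb = rgb, ms = ms, mask = mask)
}
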