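# Full segmentation model: dual-branch encoder -> cross-modal fusion ->
# attention-enhanced decoder, plus single-modality variants used for
# the modality-ablation study.

#' Model configuration
#'
#' Widths of fusion and decoder blocks derive from the encoder ladder,
#' so a single `width_multiplier` scales the whole model; reduced
#' multipliers give desk-scale models that train on a CPU.
#'
#' @param width_multiplier global channel-width scale (1 = full model).
#' @param depths blocks per encoder stage.
#' @param qk_reduction query/key width divisor in the cross-attention.
#' @param gamma_init initial cross-attention residual gain (0 =
#'   identity start).
#' @param alpha_init,beta_init initial dynamic fusion weights.
#' @param cbam_reduction,cbam_enabled,cbam_order,upsample_mode decoder
#'   options, see [up_concat_module()].
#' @param n_classes output classes (2).
#' @param drop_path stochastic-depth rate in encoder blocks.
#' @param seed seed for weight initialization.
#' @export
model_config <- function(width_multiplier = 1, depths = c(3L, 3L, 9L, 3L),
                         qk_reduction = 8L, gamma_init = 0,
                         alpha_init = 1, beta_init = 1,
                         cbam_reduction = 16L, cbam_enabled = TRUE,
                         cbam_order = "sequential",
                         upsample_mode = "bilinear", n_classes = 2L,
                         drop_path = 0, seed = 1L) {
  structure(list(width_multiplier = width_multiplier, depths = depths,
                 qk_reduction = qk_reduction, gamma_init = gamma_init,
                 alpha_init = alpha_init, beta_init = beta_init,
                 cbam_reduction = cbam_reduction,
                 cbam_enabled = cbam_enabled, cbam_order = cbam_order,
                 upsample_mode = upsample_mode,
                 n_classes = as.integer(n_classes),
                 drop_path = drop_path, seed = as.integer(seed)),
            class = "model_config")
}

#' Build a crown-segmentation model
#'
#' @param config a [model_config()].
#' @param mode `"fused"` (both modalities through the fusion module),
#'   `"rgb"` (RGB branch only, fusion bypassed) or `"ms"`
#'   (multispectral branch supplies all features, including the shallow
#'   skips through an auxiliary shallow path on the MS input).
#' @return a model object of class `dcaunet_model`.
#' @export
build_model <- function(config = model_config(),
                        mode = c("fused", "rgb", "ms")) {
  mode <- match.arg(mode)
  cfg <- config
  with_seed(cfg$seed, {
    ecfg_rgb <- encoder_config(3L, width_multiplier = cfg$width_multiplier,
                               depths = cfg$depths,
                               drop_path = cfg$drop_path)
    ecfg_ms <- encoder_config(4L, width_multiplier = cfg$width_multiplier,
                              depths = cfg$depths,
                              drop_path = cfg$drop_path)
    w <- ecfg_rgb$widths
    c1 <- ecfg_rgb$c1
    model <- list(config = cfg, mode = mode)
    if (mode %in% c("fused", "rgb"))
      model$enc_rgb <- convnext_backbone(ecfg_rgb)
    if (mode %in% c("fused", "ms"))
      model$enc_ms <- convnext_backbone(ecfg_ms)
    if (mode == "fused")
      model$cif <- cif_module(w[3], w[4], cfg$qk_reduction, cfg$gamma_init,
                              cfg$alpha_init, cfg$beta_init)
    model$dec <- decoder_module(w, c1, cfg$n_classes, cfg$cbam_reduction,
                                cfg$cbam_enabled, cfg$upsample_mode,
                                cfg$cbam_order)
    class(model) <- "dcaunet_model"
    model
  })
}

#' @export
print.dcaunet_model <- function(x, ...) {
  cat("crown-segmentation model (", x$mode, " mode), ",
      format(n_params(x), big.mark = ","), " parameters\n", sep = "")
  invisible(x)
}

# Training-capable forward: returns logits plus the cache tree.
model_fwd <- function(model, rgb, ms = NULL, train = FALSE) {
  mode <- model$mode
  if (mode %in% c("fused", "rgb")) check_input_dims(rgb, 3L)
  if (mode %in% c("fused", "ms")) {
    if (is.null(ms)) stop("this model requires a multispectral input")
    check_input_dims(ms, 4L)
  }
  if (mode == "fused" &&
      !identical(dim(rgb)[c(1, 2, 4)], dim(ms)[c(1, 2, 4)]))
    stop("rgb and ms batches must be co-registered (equal H, W, N)")
  if (mode == "fused") {
    rr <- backbone_fwd(model$enc_rgb, rgb, train, with_aux = TRUE)
    rm <- backbone_fwd(model$enc_ms, ms, train, with_aux = FALSE)
    cf <- cif_fwd(model$cif, rr$feats$feat4, rm$feats$feat4,
                  rr$feats$feat5, rm$feats$feat5)
    dc <- dec_fwd(model$dec, cf$fused5, cf$fused4, rr$feats$feat3,
                  rr$feats$feat2, rr$feats$feat1)
    list(logits = dc$logits,
         cache = list(rgb = rr$cache, ms = rm$cache, cif = cf$cache,
                      dec = dc$cache))
  } else if (mode == "rgb") {
    rr <- backbone_fwd(model$enc_rgb, rgb, train, with_aux = TRUE)
    dc <- dec_fwd(model$dec, rr$feats$feat5, rr$feats$feat4,
                  rr$feats$feat3, rr$feats$feat2, rr$feats$feat1)
    list(logits = dc$logits, cache = list(rgb = rr$cache, dec = dc$cache))
  } else {
    rm <- backbone_fwd(model$enc_ms, ms, train, with_aux = TRUE)
    dc <- dec_fwd(model$dec, rm$feats$feat5, rm$feats$feat4,
                  rm$feats$feat3, rm$feats$feat2, rm$feats$feat1)
    list(logits = dc$logits, cache = list(ms = rm$cache, dec = dc$cache))
  }
}

model_bwd <- function(model, cache, dlogits) {
  dd <- dec_bwd(model$dec, cache$dec, dlogits)
  if (model$mode == "fused") {
    dc <- cif_bwd(model$cif, cache$cif, dd$df4, dd$df5)
    backbone_bwd(model$enc_rgb, cache$rgb,
                 list(feat1 = dd$df1, feat2 = dd$df2, feat3 = dd$df3,
                      feat4 = dc$d4_rgb, feat5 = dc$d5_rgb))
    backbone_bwd(model$enc_ms, cache$ms,
                 list(feat4 = dc$d4_ms, feat5 = dc$d5_ms))
  } else if (model$mode == "rgb") {
    backbone_bwd(model$enc_rgb, cache$rgb,
                 list(feat1 = dd$df1, feat2 = dd$df2, feat3 = dd$df3,
                      feat4 = dd$df4, feat5 = dd$df5))
  } else {
    backbone_bwd(model$enc_ms, cache$ms,
                 list(feat1 = dd$df1, feat2 = dd$df2, feat3 = dd$df3,
                      feat4 = dd$df4, feat5 = dd$df5))
  }
  invisible(NULL)
}

#' Run the model forward and produce a segmentation
#'
#' @param model a model from [build_model()].
#' @param rgb RGB batch (H, W, 3, N); ignored by `"ms"`-mode models.
#' @param ms multispectral batch (H, W, 4, N), band order
#'   (Red, NIR, Green, RedEdge); ignored by `"rgb"`-mode models.
#' @return a `segmentation_output`: `logits` (H, W, 2, N), `prob`
#'   (crown-probability array (H, W, N)), and `mask` (H, W, N) over
#'   \{0, 1\} by argmax with ties broken toward background.
#' @export
model_forward <- function(model, rgb = NULL, ms = NULL) {
  r <- model_fwd(model, rgb, ms, train = FALSE)
  logits_to_output(r$logits)
}

logits_to_output <- function(logits) {
  d <- dim(logits)
  l0 <- array(logits[, , 1, ], c(d[1], d[2], d[4]))
  l1 <- array(logits[, , 2, ], c(d[1], d[2], d[4]))
  m <- pmax(l0, l1)
  prob <- exp(l1 - m) / (exp(l0 - m) + exp(l1 - m))
  mask <- array(as.numeric(l1 > l0), c(d[1], d[2], d[4]))
  structure(list(logits = logits, prob = prob, mask = mask),
            class = "segmentation_output")
}

#' @export
predict.dcaunet_model <- function(object, rgb = NULL, ms = NULL, ...) {
  model_forward(object, rgb, ms)
}

#' Two-class pixelwise cross-entropy on logits
#'
#' @param logits array (H, W, 2, N).
#' @param labels array (H, W, N) with values in \{0, 1\}.
#' @param class_weights optional length-2 weight vector
#'   (background, crown) for imbalance experiments.
#' @return list with scalar `loss` and `dlogits` of the mean loss.
#' @export
softmax_ce <- function(logits, labels, class_weights = NULL) {
  d <- dim(logits)
  l0 <- array(logits[, , 1, ], c(d[1], d[2], d[4]))
  l1 <- array(logits[, , 2, ], c(d[1], d[2], d[4]))
  m <- pmax(l0, l1)
  lse <- m + log(exp(l0 - m) + exp(l1 - m))
  lab <- array(labels, c(d[1], d[2], d[4]))
  w <- if (is.null(class_weights)) array(1, dim(lab))
       else array(class_weights[lab + 1], dim(lab))
  sw <- sum(w)
  loss <- sum(w * (lse - (lab * l1 + (1 - lab) * l0))) / sw
  p1 <- exp(l1 - lse)
  p0 <- exp(l0 - lse)
  dl <- array(0, d)
  dl[, , 1, ] <- w * (p0 - (1 - lab)) / sw
  dl[, , 2, ] <- w * (p1 - lab) / sw
  list(loss = loss, dlogits = dl)
}
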