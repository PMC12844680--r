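# Cross-Modal Interactive Fusion (CIF).
#
# At the two deepest encoder levels, a bidirectional cross-attention
# block (CotSR) lets each branch's queries attend over the other
# branch's keys/values across all spatial positions, added back
# residually with a learnable scalar gain; the two enhanced maps are
# then combined elementwise with learnable scalar weights alpha (RGB)
# and beta (MS). No softmax temperature or multi-head splitting is
# used: the attention is the literal single-head form
#   Y1 = X1 + gamma1 * softmax(Q1 K2^T) V2  (rows = positions of X1)
# and symmetrically for the second branch.

softmax_rows <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

#' Construct a CotSR cross-attention block
#'
#' @param C channel width of both input feature maps.
#' @param qk_reduction integer divisor for the query/key projection
#'   width (DANet convention, default 8); values keep full width.
#' @param gamma_init initial value of the residual gains (default 0, so
#'   the block starts as the identity).
#' @return a module usable with [cotsr_forward()].
#' @export
cotsr_module <- function(C, qk_reduction = 8L, gamma_init = 0) {
  dq <- max(1L, C %/% qk_reduction)
  list(q1 = ly_conv(C, dq, 1L), k1 = ly_conv(C, dq, 1L),
       v1 = ly_conv(C, C, 1L),
       q2 = ly_conv(C, dq, 1L), k2 = ly_conv(C, dq, 1L),
       v2 = ly_conv(C, C, 1L),
       g1 = ly_scalar(gamma_init), g2 = ly_scalar(gamma_init),
       C = C, dq = dq)
}

as_posmat <- function(x, n) {
  d <- dim(x)
  matrix(x[, , , n], d[1] * d[2], d[3])
}

cotsr_fwd <- function(m, X1, X2) {
  d <- dim(X1)
  if (!identical(dim(X1), dim(X2)))
    stop("cotsr: branch shapes differ: ", paste(dim(X1), collapse = "x"),
         " vs ", paste(dim(X2), collapse = "x"))
  q1 <- fwd_conv(m$q1, X1); k1 <- fwd_conv(m$k1, X1); v1 <- fwd_conv(m$v1, X1)
  q2 <- fwd_conv(m$q2, X2); k2 <- fwd_conv(m$k2, X2); v2 <- fwd_conv(m$v2, X2)
  N <- d[4]; HW <- d[1] * d[2]
  O1 <- array(0, d); O2 <- array(0, d)
  A1 <- vector("list", N); A2 <- vector("list", N)
  for (n in seq_len(N)) {
    Q1m <- as_posmat(q1$y, n); K1m <- as_posmat(k1$y, n)
    V1m <- as_posmat(v1$y, n)
    Q2m <- as_posmat(q2$y, n); K2m <- as_posmat(k2$y, n)
    V2m <- as_posmat(v2$y, n)
    A1[[n]] <- softmax_rows(Q1m %*% t(K2m))
    A2[[n]] <- softmax_rows(Q2m %*% t(K1m))
    O1[, , , n] <- array(A1[[n]] %*% V2m, d[1:3])
    O2[, , , n] <- array(A2[[n]] %*% V1m, d[1:3])
  }
  Y1 <- X1 + m$g1$p$v * O1
  Y2 <- X2 + m$g2$p$v * O2
  list(Y1 = Y1, Y2 = Y2,
       cache = list(X1 = X1, X2 = X2, Q1 = q1$y, K1 = k1$y, V1 = v1$y,
                    Q2 = q2$y, K2 = k2$y, V2 = v2$y, A1 = A1, A2 = A2,
                    O1 = O1, O2 = O2))
}

cotsr_bwd <- function(m, cache, dY1, dY2) {
  d <- dim(cache$X1)
  N <- d[4]
  acc_grad(m$g1, "v", sum(dY1 * cache$O1))
  acc_grad(m$g2, "v", sum(dY2 * cache$O2))
  dO1 <- m$g1$p$v * dY1
  dO2 <- m$g2$p$v * dY2
  dQ1 <- array(0, dim(cache$Q1)); dK1 <- array(0, dim(cache$K1))
  dV1 <- array(0, dim(cache$V1))
  dQ2 <- array(0, dim(cache$Q2)); dK2 <- array(0, dim(cache$K2))
  dV2 <- array(0, dim(cache$V2))
  for (n in seq_len(N)) {
    dO1m <- as_posmat(dO1, n); dO2m <- as_posmat(dO2, n)
    V1m <- as_posmat(cache$V1, n); V2m <- as_posmat(cache$V2, n)
    Q1m <- as_posmat(cache$Q1, n); K1m <- as_posmat(cache$K1, n)
    Q2m <- as_posmat(cache$Q2, n); K2m <- as_posmat(cache$K2, n)
    A1 <- cache$A1[[n]]; A2 <- cache$A2[[n]]
    dV2[, , , n] <- array(crossprod(A1, dO1m), dim(dV2)[1:3])
    dV1[, , , n] <- array(crossprod(A2, dO2m), dim(dV1)[1:3])
    dA1 <- tcrossprod(dO1m, V2m)
    dA2 <- tcrossprod(dO2m, V1m)
    dS1 <- A1 * (dA1 - rowSums(dA1 * A1))
    dS2 <- A2 * (dA2 - rowSums(dA2 * A2))
    dQ1[, , , n] <- array(dS1 %*% K2m, dim(dQ1)[1:3])
    dK2[, , , n] <- array(crossprod(dS1, Q1m), dim(dK2)[1:3])
    dQ2[, , , n] <- array(dS2 %*% K1m, dim(dQ2)[1:3])
    dK1[, , , n] <- array(crossprod(dS2, Q2m), dim(dK1)[1:3])
  }
  dX1 <- dY1 +
    bwd_conv(m$q1, cache$X1, dQ1) +
    bwd_conv(m$k1, cache$X1, dK1) +
    bwd_conv(m$v1, cache$X1, dV1)
  dX2 <- dY2 +
    bwd_conv(m$q2, cache$X2, dQ2) +
    bwd_conv(m$k2, cache$X2, dK2) +
    bwd_conv(m$v2, cache$X2, dV2)
  list(dX1 = dX1, dX2 = dX2)
}

#' Bidirectional cross-modal attention between two feature maps
#'
#' Each branch's queries attend over the other branch's keys and values
#' across all spatial positions; the attended component is added back
#' residually, scaled by the branch's learnable gain. With both gains at
#' their default initial value 0 the operation is the exact identity.
#'
#' @param X1,X2 feature maps, arrays (H, W, C, N) of equal shape.
#' @param params a module from [cotsr_module()].
#' @return list with enhanced maps `Y1`, `Y2`.
#' @export
cotsr_forward <- function(X1, X2, params) {
  r <- cotsr_fwd(params, X1, X2)
  list(Y1 = r$Y1, Y2 = r$Y2)
}

#' Construct a dynamic weight-fusion stage
#'
#' @param alpha_init,beta_init initial values of the learnable RGB and
#'   multispectral fusion weights (default 1, near the magnitudes such
#'   weights converge to in practice).
#' @export
weight_fusion_module <- function(alpha_init = 1, beta_init = 1) {
  list(alpha = ly_scalar(alpha_init), beta = ly_scalar(beta_init))
}

wf_fwd <- function(m, Frgb, Fms) {
  if (!identical(dim(Frgb), dim(Fms)))
    stop("weight_fusion: shapes differ")
  list(y = m$alpha$p$v * Frgb + m$beta$p$v * Fms,
       cache = list(Frgb = Frgb, Fms = Fms))
}

wf_bwd <- function(m, cache, dy) {
  acc_grad(m$alpha, "v", sum(dy * cache$Frgb))
  acc_grad(m$beta, "v", sum(dy * cache$Fms))
  list(dFrgb = m$alpha$p$v * dy, dFms = m$beta$p$v * dy)
}

#' Elementwise dynamic-weight fusion of two modality features
#'
#' Computes `alpha * F_rgb + beta * F_ms` with the stage's learnable
#' scalar weights; no channel expansion takes place.
#'
#' @param F_rgb,F_ms feature maps of equal shape.
#' @param w a stage from [weight_fusion_module()].
#' @export
weight_fusion <- function(F_rgb, F_ms, w) {
  wf_fwd(w, F_rgb, F_ms)$y
}

#' Construct the full fusion module for the two deep stages
#'
#' @param C4,C5 channel widths at the feat4 and feat5 levels.
#' @param qk_reduction,gamma_init,alpha_init,beta_init see
#'   [cotsr_module()] and [weight_fusion_module()].
#' @export
cif_module <- function(C4, C5, qk_reduction = 8L, gamma_init = 0,
                       alpha_init = 1, beta_init = 1) {
  list(cotsr4 = cotsr_module(C4, qk_reduction, gamma_init),
       cotsr5 = cotsr_module(C5, qk_reduction, gamma_init),
       wf4 = weight_fusion_module(alpha_init, beta_init),
       wf5 = weight_fusion_module(alpha_init, beta_init))
}

cif_fwd <- function(m, f4_rgb, f4_ms, f5_rgb, f5_ms) {
  r4 <- cotsr_fwd(m$cotsr4, f4_rgb, f4_ms)
  r5 <- cotsr_fwd(m$cotsr5, f5_rgb, f5_ms)
  w4 <- wf_fwd(m$wf4, r4$Y1, r4$Y2)
  w5 <- wf_fwd(m$wf5, r5$Y1, r5$Y2)
  list(fused4 = w4$y, fused5 = w5$y,
       cache = list(c4 = r4$cache, c5 = r5$cache, w4 = w4$cache,
                    w5 = w5$cache))
}

cif_bwd <- function(m, cache, dfused4, dfused5) {
  dw4 <- wf_bwd(m$wf4, cache$w4, dfused4)
  dw5 <- wf_bwd(m$wf5, cache$w5, dfused5)
  d4 <- cotsr_bwd(m$cotsr4, cache$c4, dw4$dFrgb, dw4$dFms)
  d5 <- cotsr_bwd(m$cotsr5, cache$c5, dw5$dFrgb, dw5$dFms)
  list(d4_rgb = d4$dX1, d4_ms = d4$dX2, d5_rgb = d5$dX1, d5_ms = d5$dX2)
}

#' Fuse two feature pyramids at the deep stages
#'
#' Applies cross-modal attention then dynamic weight fusion
#' independently at feat4 and feat5, with stage-specific parameters.
#'
#' @param rgb_pyr,ms_pyr feature pyramids exposing feat4 and feat5.
#' @param params a module from [cif_module()].
#' @return list with `fused4` and `fused5` feature maps.
#' @export
cif_forward <- function(rgb_pyr, ms_pyr, params) {
  r <- cif_fwd(params,
               pyramid_level(rgb_pyr, 4), pyramid_level(ms_pyr, 4),
               pyramid_level(rgb_pyr, 5), pyramid_level(ms_pyr, 5))
  list(fused4 = r$fused4, fused5 = r$fused5)
}

#' Report the learned dynamic fusion weights
#'
#' @param model a model from [build_model()] (fused mode).
#' @return data.frame with one row per fusion stage and columns
#'   `stage`, `alpha`, `beta`.
#' @export
fusion_weights <- function(model) {
  if (is.null(model$cif)) stop("model has no fusion module")
  data.frame(stage = c("feat4", "feat5"),
             alpha = c(model$cif$wf4$alpha$p$v, model$cif$wf5$alpha$p$v),
             beta = c(model$cif$wf4$beta$p$v, model$cif$wf5$beta$p$v))
}
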