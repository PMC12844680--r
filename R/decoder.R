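# Attention-Enhanced Decoder (AED).
#
# Four Up-Concat stages rebuild full-resolution logits from the fused
# deep features: each stage upsamples 2x (bilinear + conv by default,
# transposed conv as a variant), concatenates the matching skip
# (upsampled-deep first, then skip), recalibrates the concatenation
# with CBAM (channel attention from pooled descriptors through a shared
# bottleneck MLP, then spatial attention from channel-pooled planes
# through a 7x7 convolution), and applies a double conv-norm-GELU
# block. A final 2x bilinear upsample and 1x1 classifier head produce
# two-class logits at input resolution.

largest_divisor_leq <- function(C, r) {
  for (d in seq(min(r, C), 1L)) if (C %% d == 0L) return(as.integer(d))
  1L
}

#' Construct a CBAM attention module
#'
#' @param C channel width of the maps to refine; must be divisible by
#'   `reduction`.
#' @param reduction bottleneck factor of the shared channel MLP.
#' @param spatial_kernel odd kernel size of the spatial-attention
#'   convolution (default 7).
#' @param order `"sequential"` (spatial attention computed on the
#'   channel-refined map, the default) or `"parallel"` (both maps
#'   computed on the raw input and multiplied together).
#' @export
cbam_module <- function(C, reduction = 16L, spatial_kernel = 7L,
                        order = c("sequential", "parallel")) {
  order <- match.arg(order)
  if (C %% reduction != 0L)
    stop("channel width ", C, " is not divisible by reduction ", reduction)
  if (spatial_kernel %% 2L != 1L) stop("spatial kernel must be odd")
  list(mlp = ly_cmlp(C, max(1L, C %/% reduction)),
       sconv = ly_conv(2L, 1L, as.integer(spatial_kernel),
                       pad = (as.integer(spatial_kernel) - 1L) %/% 2L),
       C = as.integer(C), order = order)
}

ca_fwd <- function(m, x) {
  gp <- cpp_gpool(x)
  r1 <- fwd_cmlp(m$mlp, gp$avg)
  r2 <- fwd_cmlp(m$mlp, gp$max)
  Mc <- sigmoid(r1$y + r2$y)
  list(Mc = Mc,
       cache = list(d = dim(x), avgc = r1$cache, maxc = r2$cache,
                    idx = gp$idx, Mc = Mc))
}

ca_bwd <- function(m, cache, dMc) {
  dz <- dMc * cache$Mc * (1 - cache$Mc)
  davg <- bwd_cmlp(m$mlp, cache$avgc, dz)
  dmax <- bwd_cmlp(m$mlp, cache$maxc, dz)
  cpp_gpool_bwd(davg, dmax, cache$idx, as.integer(cache$d))
}

sa_fwd <- function(m, x) {
  cp <- cpp_cpool(x)
  s <- concat_chan(cp$mean, cp$max)
  rc <- fwd_conv(m$sconv, s)
  Ms <- sigmoid(rc$y)
  list(Ms = Ms, cache = list(d = dim(x), s = s, idx = cp$idx, Ms = Ms))
}

sa_bwd <- function(m, cache, dMs) {
  dpre <- dMs * cache$Ms * (1 - cache$Ms)
  ds <- bwd_conv(m$sconv, cache$s, dpre)
  sp <- split_chan(ds, 1L)
  cpp_cpool_bwd(sp$a, sp$b, cache$idx, as.integer(cache$d))
}

cbam_fwd <- function(m, x) {
  ca <- ca_fwd(m, x)
  if (m$order == "sequential") {
    X1 <- mul_chan(x, ca$Mc)
    sa <- sa_fwd(m, X1)
    y <- mul_spat(X1, sa$Ms)
    cache <- list(x = x, X1 = X1, ca = ca$cache, sa = sa$cache,
                  Mc = ca$Mc, Ms = sa$Ms, order = m$order)
  } else {
    sa <- sa_fwd(m, x)
    y <- mul_spat(mul_chan(x, ca$Mc), sa$Ms)
    cache <- list(x = x, ca = ca$cache, sa = sa$cache,
                  Mc = ca$Mc, Ms = sa$Ms, order = m$order)
  }
  list(y = y, cache = cache)
}

cbam_bwd <- function(m, cache, dy) {
  if (cache$order == "sequential") {
    dX1 <- mul_spat(dy, cache$Ms) +
      sa_bwd(m, cache$sa, cpp_mulsum_spat(dy, cache$X1))
    mul_chan(dX1, cache$Mc) +
      ca_bwd(m, cache$ca, cpp_mulsum_chan(dX1, cache$x))
  } else {
    xc <- mul_chan(cache$x, cache$Mc)
    dxc <- mul_spat(dy, cache$Ms)
    dx <- mul_chan(dxc, cache$Mc) +
      ca_bwd(m, cache$ca, cpp_mulsum_chan(dxc, cache$x)) +
      sa_bwd(m, cache$sa, cpp_mulsum_spat(dy, xc))
    dx
  }
}

#' Channel attention weights of a feature map
#'
#' Pools the map globally by average and by maximum, passes both
#' descriptors through a shared two-layer bottleneck MLP, sums, and
#' squashes with a sigmoid; all weights lie strictly in (0, 1).
#'
#' @param X feature map (H, W, C, N).
#' @param reduction bottleneck factor (C must be divisible by it).
#' @param params optionally a [cbam_module()] holding the MLP weights;
#'   a randomly initialized one is created when omitted.
#' @return matrix (C, N) of channel weights.
#' @export
channel_attention <- function(X, reduction = 16L, params = NULL) {
  if (is.null(params)) params <- cbam_module(dim(X)[3], reduction)
  ca_fwd(params, X)$Mc
}

#' Spatial attention weights of a feature map
#'
#' Averages and maximizes over the channel axis, stacks the two planes,
#' and passes them through a same-padded 7x7 convolution and sigmoid.
#'
#' @param X feature map (H, W, C, N).
#' @param params optionally a [cbam_module()].
#' @return array (H, W, 1, N) of per-position weights in (0, 1).
#' @export
spatial_attention <- function(X, params = NULL) {
  if (is.null(params)) params <- cbam_module(dim(X)[3], 1L)
  sa_fwd(params, X)$Ms
}

#' Apply CBAM refinement to a feature map
#'
#' Sequentially recalibrates channels then spatial positions (or, in the
#' parallel variant, multiplies both attention maps computed on the raw
#' input). Both attention factors lie in (0, 1), so the output never
#' exceeds the input in magnitude.
#'
#' @inheritParams channel_attention
#' @export
cbam <- function(X, reduction = 16L, params = NULL) {
  if (is.null(params)) params <- cbam_module(dim(X)[3], reduction)
  cbam_fwd(params, X)$y
}

ly_deconv <- function(C, init_sd = NULL) {
  if (is.null(init_sd)) init_sd <- sqrt(2 / (4 * C))
  new_mod("deconv",
          list(W = array(rnorm(4 * C * C, 0, init_sd), c(2L, 2L, C, C)),
               b = numeric(C)),
          hyper = list(C = C), decay = c(W = TRUE, b = FALSE))
}

#' Construct one Up-Concat decoder stage
#'
#' @param c_deep channels of the deep input (upsampled 2x).
#' @param c_skip channels of the skip connection.
#' @param c_out output width of the stage.
#' @param cbam_reduction requested CBAM bottleneck factor; clamped to
#'   the largest divisor of the concatenated width.
#' @param cbam_enabled logical ablation switch.
#' @param upsample_mode `"bilinear"` (bilinear + conv) or `"deconv"`
#'   (2x2 stride-2 transposed convolution).
#' @param cbam_order see [cbam_module()].
#' @export
up_concat_module <- function(c_deep, c_skip, c_out, cbam_reduction = 16L,
                             cbam_enabled = TRUE,
                             upsample_mode = c("bilinear", "deconv"),
                             cbam_order = "sequential") {
  upsample_mode <- match.arg(upsample_mode)
  ccat <- c_deep + c_skip
  list(up = if (upsample_mode == "bilinear")
              ly_conv(c_deep, c_deep, 3L, pad = 1L)
            else ly_deconv(c_deep),
       cbam = if (cbam_enabled)
                cbam_module(ccat, largest_divisor_leq(ccat, cbam_reduction),
                            order = cbam_order),
       conv1 = ly_conv(ccat, c_out, 3L, pad = 1L), ln1 = ly_ln(c_out),
       conv2 = ly_conv(c_out, c_out, 3L, pad = 1L), ln2 = ly_ln(c_out),
       mode = upsample_mode, c_deep = c_deep, c_skip = c_skip,
       c_out = c_out)
}

uc_fwd <- function(m, deep, skip) {
  dd <- dim(deep); ds <- dim(skip)
  if (2L * dd[1] != ds[1] || 2L * dd[2] != ds[2])
    stop("up_concat: deep ", dd[1], "x", dd[2], " upsampled 2x does not ",
         "match skip ", ds[1], "x", ds[2])
  if (m$mode == "bilinear") {
    u0 <- up2x_fwd(deep)
    ru <- fwd_conv(m$up, u0)
    u <- ru$y
    upc <- list(u0 = u0)
  } else {
    u <- cpp_deconv2x(deep, m$up$p$W, m$up$p$b)
    upc <- list(deep = deep)
  }
  cat <- concat_chan(u, skip)
  if (!is.null(m$cbam)) {
    rb <- cbam_fwd(m$cbam, cat)
    a <- rb$y
    bc <- rb$cache
  } else {
    a <- cat
    bc <- NULL
  }
  r1 <- fwd_conv(m$conv1, a)
  l1 <- fwd_ln(m$ln1, r1$y)
  g1 <- gelu_fwd(l1$y)
  r2 <- fwd_conv(m$conv2, g1)
  l2 <- fwd_ln(m$ln2, r2$y)
  y <- gelu_fwd(l2$y)
  list(y = y,
       cache = list(upc = upc, cat = cat, bc = bc, conv1_in = a,
                    ln1 = l1$cache, g1_in = l1$y, conv2_in = g1,
                    ln2 = l2$cache, g2_in = l2$y, dd = dd))
}

uc_bwd <- function(m, cache, dy) {
  dg2 <- gelu_bwd(cache$g2_in, dy)
  dl2 <- bwd_ln(m$ln2, cache$ln2, dg2)
  dc2 <- bwd_conv(m$conv2, cache$conv2_in, dl2)
  dg1 <- gelu_bwd(cache$g1_in, dc2)
  dl1 <- bwd_ln(m$ln1, cache$ln1, dg1)
  da <- bwd_conv(m$conv1, cache$conv1_in, dl1)
  dcat <- if (!is.null(m$cbam)) cbam_bwd(m$cbam, cache$bc, da) else da
  sp <- split_chan(dcat, m$c_deep)
  if (m$mode == "bilinear") {
    du0 <- bwd_conv(m$up, cache$upc$u0, sp$a)
    ddeep <- up2x_bwd(du0, cache$dd[1], cache$dd[2])
  } else {
    r <- cpp_deconv2x_bwd(cache$upc$deep, m$up$p$W, sp$a)
    acc_grad(m$up, "W", r$dw)
    acc_grad(m$up, "b", r$db)
    ddeep <- r$dx
  }
  list(ddeep = ddeep, dskip = sp$b)
}

#' Decoder configuration and construction
#'
#' Builds the four Up-Concat stages consuming skips in order
#' (fused4, feat3, feat2, feat1) plus the final upsample + 1x1 head.
#'
#' @param widths four backbone stage widths (feat2..feat5 channels).
#' @param c1 channels of the shallow feat1 skip.
#' @param n_classes number of output classes (2: background, crown).
#' @param cbam_reduction,cbam_enabled,upsample_mode,cbam_order see
#'   [up_concat_module()].
#' @export
decoder_module <- function(widths, c1, n_classes = 2L, cbam_reduction = 16L,
                           cbam_enabled = TRUE, upsample_mode = "bilinear",
                           cbam_order = "sequential") {
  w <- widths
  list(uc1 = up_concat_module(w[4], w[3], w[3], cbam_reduction,
                              cbam_enabled, upsample_mode, cbam_order),
       uc2 = up_concat_module(w[3], w[2], w[2], cbam_reduction,
                              cbam_enabled, upsample_mode, cbam_order),
       uc3 = up_concat_module(w[2], w[1], w[1], cbam_reduction,
                              cbam_enabled, upsample_mode, cbam_order),
       uc4 = up_concat_module(w[1], c1, c1, cbam_reduction,
                              cbam_enabled, upsample_mode, cbam_order),
       head = ly_conv(c1, as.integer(n_classes), 1L),
       n_classes = as.integer(n_classes))
}

dec_fwd <- function(m, f5, f4, f3, f2, f1) {
  r1 <- uc_fwd(m$uc1, f5, f4)
  r2 <- uc_fwd(m$uc2, r1$y, f3)
  r3 <- uc_fwd(m$uc3, r2$y, f2)
  r4 <- uc_fwd(m$uc4, r3$y, f1)
  u <- up2x_fwd(r4$y)
  rh <- fwd_conv(m$head, u)
  list(logits = rh$y,
       cache = list(c1 = r1$cache, c2 = r2$cache, c3 = r3$cache,
                    c4 = r4$cache, head_in = u, d4 = dim(r4$y)))
}

dec_bwd <- function(m, cache, dlogits) {
  dh <- bwd_conv(m$head, cache$head_in, dlogits)
  du <- up2x_bwd(dh, cache$d4[1], cache$d4[2])
  b4 <- uc_bwd(m$uc4, cache$c4, du)
  b3 <- uc_bwd(m$uc3, cache$c3, b4$ddeep)
  b2 <- uc_bwd(m$uc2, cache$c2, b3$ddeep)
  b1 <- uc_bwd(m$uc1, cache$c1, b2$ddeep)
  list(df5 = b1$ddeep, df4 = b1$dskip, df3 = b2$dskip, df2 = b3$dskip,
       df1 = b4$dskip)
}

#' Decode fused deep features and RGB skips into segmentation logits
#'
#' @param decoder a module from [decoder_module()].
#' @param fused5,fused4 fused deep feature maps (1/32 and 1/16 scale).
#' @param feat3_rgb,feat2_rgb,feat1_rgb RGB-branch skip features at
#'   1/8, 1/4 and 1/2 scale.
#' @return logits array (H, W, n_classes, N) at input resolution.
#' @export
decode <- function(decoder, fused5, fused4, feat3_rgb, feat2_rgb,
                   feat1_rgb) {
  dec_fwd(decoder, fused5, fused4, feat3_rgb, feat2_rgb, feat1_rgb)$logits
}
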