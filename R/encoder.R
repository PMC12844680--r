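# Dual-branch hierarchical encoder (DBE).
#
# Each branch is a ConvNeXt-style backbone: a 4x4/stride-4 patchify stem,
# four stages of depthwise-7x7 + inverted-bottleneck MLP blocks with
# channel LayerNorm, GELU and per-channel layer scale, separated by
# LayerNorm + 2x2/stride-2 downsampling convolutions. The RGB branch
# exposes five feature levels (feat1 at 1/2 resolution from an auxiliary
# stride-2 stem, feat2..feat5 from the four stages at 1/4..1/32); the
# multispectral branch exposes only the two deepest levels.

#' Encoder configuration
#'
#' @param in_channels 3 (RGB) or 4 (multispectral).
#' @param widths channel widths of the four backbone stages
#'   (ConvNeXt-Tiny ladder by default).
#' @param depths number of blocks per stage.
#' @param width_multiplier global width scale; reduced values give
#'   desk-scale models for CPU experiments.
#' @param drop_path stochastic-depth rate applied to residual branches
#'   during training (0 disables).
#' @param pretrained logical; when `TRUE` the caller is expected to load
#'   externally obtained backbone weights via [load_state()] (no weights
#'   ship with the package). Initialization is always random Gaussian.
#' @param extend_sigma std-dev of the Gaussian init for input-channel
#'   slices beyond the third when extending a 3-channel stem (see
#'   [extend_first_conv()]).
#' @param band_order names of the multispectral bands in input order.
#' @return a list of class `encoder_config`.
#' @export
encoder_config <- function(in_channels = 3L,
                           widths = c(96L, 192L, 384L, 768L),
                           depths = c(3L, 3L, 9L, 3L),
                           width_multiplier = 1,
                           drop_path = 0,
                           pretrained = FALSE,
                           extend_sigma = 0.01,
                           band_order = c("red", "nir", "green", "rededge")) {
  if (!in_channels %in% c(3L, 4L))
    stop("in_channels must be 3 or 4, got ", in_channels)
  widths <- as.integer(round(widths * width_multiplier))
  if (any(widths <= 0) || any(diff(widths) < 0))
    stop("stage widths must be positive and non-decreasing")
  if (length(depths) != 4L || any(depths < 1L))
    stop("depths must be four positive integers")
  structure(list(in_channels = as.integer(in_channels), widths = widths,
                 depths = as.integer(depths), drop_path = drop_path,
                 pretrained = isTRUE(pretrained),
                 extend_sigma = extend_sigma, band_order = band_order,
                 c1 = max(1L, widths[1] %/% 2L)),
            class = "encoder_config")
}

convnext_block <- function(C, drop_path = 0) {
  list(dw = ly_conv(C, C, 7L, pad = 3L, groups = C),
       ln = ly_ln(C),
       pw1 = ly_conv(C, 4L * C, 1L),
       pw2 = ly_conv(4L * C, C, 1L),
       ls = ly_scale(C, init = 1e-6),
       rate = drop_path)
}

block_fwd <- function(blk, x, train = FALSE) {
  r1 <- fwd_conv(blk$dw, x)
  r2 <- fwd_ln(blk$ln, r1$y)
  r3 <- fwd_conv(blk$pw1, r2$y)
  g <- gelu_fwd(r3$y)
  r4 <- fwd_conv(blk$pw2, g)
  r5 <- fwd_scale(blk$ls, r4$y)
  res <- r5$y
  keep <- NULL
  if (train && blk$rate > 0) {
    d <- dim(x)
    keep <- (runif(d[4]) >= blk$rate) / (1 - blk$rate)
    res <- res * rep(keep, each = d[1] * d[2] * d[3])
  }
  list(y = x + res,
       cache = list(x = x, ln = r2$cache, pw1_in = r2$y, gelu_in = r3$y,
                    pw2_in = g, ls_in = r4$y, keep = keep))
}

block_bwd <- function(blk, cache, dy, need_dx = TRUE) {
  dres <- dy
  if (!is.null(cache$keep)) {
    d <- dim(cache$x)
    dres <- dres * rep(cache$keep, each = d[1] * d[2] * d[3])
  }
  d5 <- bwd_scale(blk$ls, cache$ls_in, dres)
  d4 <- bwd_conv(blk$pw2, cache$pw2_in, d5)
  d3 <- gelu_bwd(cache$gelu_in, d4)
  d2 <- bwd_conv(blk$pw1, cache$pw1_in, d3)
  d1 <- bwd_ln(blk$ln, cache$ln, d2)
  d0 <- bwd_conv(blk$dw, cache$x, d1, need_dx)
  if (need_dx) d0 + dy else NULL
}

convnext_backbone <- function(cfg) {
  w <- cfg$widths
  stages <- lapply(seq_len(4), function(s)
    lapply(seq_len(cfg$depths[s]), function(b)
      convnext_block(w[s], cfg$drop_path)))
  downs <- lapply(seq_len(3), function(s)
    list(ln = ly_ln(w[s]), conv = ly_conv(w[s], w[s + 1], 2L, stride = 2L)))
  list(stem = list(conv = ly_conv(cfg$in_channels, w[1], 4L, stride = 4L),
                   ln = ly_ln(w[1])),
       stages = stages, downs = downs,
       aux = list(conv = ly_conv(cfg$in_channels, cfg$c1, 3L, stride = 2L,
                                 pad = 1L),
                  ln = ly_ln(cfg$c1)),
       cfg = cfg)
}

check_input_dims <- function(x, in_channels) {
  d <- dim(x)
  if (length(d) != 4L)
    stop("expected a (H, W, C, N) array, got dims: ", paste(d, collapse = "x"))
  if (d[3] != in_channels)
    stop("expected ", in_channels, " input channels, got ", d[3])
  if (d[1] %% 32L != 0L || d[2] %% 32L != 0L)
    stop("spatial size (", d[1], "x", d[2],
         ") must be divisible by 32")
  invisible(d)
}

stage_fwd <- function(stage, x, train) {
  caches <- vector("list", length(stage))
  for (i in seq_along(stage)) {
    r <- block_fwd(stage[[i]], x, train)
    x <- r$y
    caches[[i]] <- r$cache
  }
  list(y = x, cache = caches)
}

stage_bwd <- function(stage, caches, dy, need_dx = TRUE) {
  for (i in rev(seq_along(stage))) {
    nd <- need_dx || i > 1L
    dy <- block_bwd(stage[[i]], caches[[i]], dy, nd)
  }
  dy
}

# Full backbone forward. Returns all five taps plus the cache tree
# needed for the backward pass (cache = NULL in eval mode keeps memory
# low but the structure identical).
backbone_fwd <- function(bb, x, train = FALSE, with_aux = TRUE) {
  check_input_dims(x, bb$cfg$in_channels)
  rs <- fwd_conv(bb$stem$conv, x)
  rl <- fwd_ln(bb$stem$ln, rs$y)
  feats <- list()
  caches <- list(stem_conv = rs$cache, stem_ln = rl$cache)
  h <- rl$y
  for (s in seq_len(4)) {
    r <- stage_fwd(bb$stages[[s]], h, train)
    feats[[paste0("feat", s + 1L)]] <- r$y
    caches[[paste0("stage", s)]] <- r$cache
    if (s < 4L) {
      dln <- fwd_ln(bb$downs[[s]]$ln, r$y)
      dcv <- fwd_conv(bb$downs[[s]]$conv, dln$y)
      caches[[paste0("down", s, "_ln")]] <- dln$cache
      caches[[paste0("down", s, "_conv")]] <- dln$y
      h <- dcv$y
    }
  }
  if (with_aux) {
    ra <- fwd_conv(bb$aux$conv, x)
    rn <- fwd_ln(bb$aux$ln, ra$y)
    feats$feat1 <- gelu_fwd(rn$y)
    caches$aux_conv <- ra$cache
    caches$aux_ln <- rn$cache
    caches$aux_gelu_in <- rn$y
  }
  list(feats = feats, cache = caches)
}

# Backward through the backbone given gradients at any subset of taps
# (named list; missing/NULL taps contribute nothing).
backbone_bwd <- function(bb, cache, dfeats) {
  dh <- NULL
  for (s in rev(seq_len(4))) {
    dtap <- dfeats[[paste0("feat", s + 1L)]]
    dout <- if (is.null(dh)) dtap else if (is.null(dtap)) dh else dh + dtap
    if (is.null(dout)) next
    dh <- stage_bwd(bb$stages[[s]], cache[[paste0("stage", s)]], dout,
                    need_dx = TRUE)
    if (s > 1L) {
      dcv <- bwd_conv(bb$downs[[s - 1L]]$conv,
                      cache[[paste0("down", s - 1L, "_conv")]], dh)
      dh <- bwd_ln(bb$downs[[s - 1L]]$ln,
                   cache[[paste0("down", s - 1L, "_ln")]], dcv)
    }
  }
  if (!is.null(dh)) {
    dl <- bwd_ln(bb$stem$ln, cache$stem_ln, dh)
    bwd_conv(bb$stem$conv, cache$stem_conv, dl, need_dx = FALSE)
  }
  if (!is.null(dfeats$feat1)) {
    dg <- gelu_bwd(cache$aux_gelu_in, dfeats$feat1)
    dn <- bwd_ln(bb$aux$ln, cache$aux_ln, dg)
    bwd_conv(bb$aux$conv, cache$aux_conv, dn, need_dx = FALSE)
  }
  invisible(NULL)
}

new_pyramid <- function(feats, branch) {
  structure(list(levels = feats, branch = branch), class = "feature_pyramid")
}

#' Extract a level from a feature pyramid
#'
#' @param pyr a `feature_pyramid` as returned by [encode_rgb()] or
#'   [encode_ms()].
#' @param i level index 1..5.
#' @export
pyramid_level <- function(pyr, i) {
  nm <- paste0("feat", i)
  lv <- pyr$levels[[nm]]
  if (is.null(lv))
    stop("level ", nm, " is not present in this ", pyr$branch,
         "-branch pyramid")
  lv
}

#' Encode an RGB batch into a five-level feature pyramid
#'
#' Runs the RGB backbone in evaluation mode and returns feature maps at
#' scales 1/2, 1/4, 1/8, 1/16 and 1/32 of the input.
#'
#' @param encoder an encoder branch, e.g. `model$enc_rgb` from
#'   [build_model()], or a standalone branch from [build_encoder()].
#' @param x image batch, array (H, W, 3, N) with H, W divisible by 32.
#' @return a `feature_pyramid` with levels feat1..feat5.
#' @export
encode_rgb <- function(encoder, x) {
  if (encoder$cfg$in_channels != 3L)
    stop("encoder was built for ", encoder$cfg$in_channels, " channels")
  r <- backbone_fwd(encoder, x, train = FALSE, with_aux = TRUE)
  new_pyramid(r$feats[c("feat1", "feat2", "feat3", "feat4", "feat5")], "rgb")
}

#' Encode a multispectral batch into deep features
#'
#' Runs the 4-channel backbone fully but exposes only the two deepest
#' levels (feat4, feat5): shallow multispectral features are considered
#' noise-prone and are not used downstream.
#'
#' @param encoder a 4-channel encoder branch.
#' @param x image batch, array (H, W, 4, N), band order
#'   (Red, NIR, Green, RedEdge).
#' @return a `feature_pyramid` with levels feat4 and feat5 only.
#' @export
encode_ms <- function(encoder, x) {
  if (encoder$cfg$in_channels != 4L)
    stop("encoder was built for ", encoder$cfg$in_channels, " channels")
  r <- backbone_fwd(encoder, x, train = FALSE, with_aux = FALSE)
  new_pyramid(r$feats[c("feat4", "feat5")], "ms")
}

#' Build a standalone encoder branch
#'
#' @param cfg an [encoder_config()].
#' @param seed integer seed for reproducible random initialization.
#' @export
build_encoder <- function(cfg, seed = 1L) {
  with_seed(seed, convnext_backbone(cfg))
}

#' Extend a 3-channel stem filter bank to additional input channels
#'
#' The slices for the first three input channels are copied unchanged
#' (so pretrained visible-band filters transfer); each additional
#' channel slice is initialized i.i.d. Gaussian with mean zero and the
#' given standard deviation, matching the fresh-band initialization used
#' when a visible-spectrum backbone is extended to a RedEdge band.
#'
#' @param weights3 array (Kh, Kw, 3, Cout): stem filters for 3 channels.
#' @param n_extra number of channels to append (0 returns the input).
#' @param sigma standard deviation of the Gaussian init (> 0).
#' @param seed integer seed controlling the random slices.
#' @return array (Kh, Kw, 3 + n_extra, Cout).
#' @export
extend_first_conv <- function(weights3, n_extra, sigma = 0.01, seed = 1L) {
  d <- dim(weights3)
  if (length(d) != 4L || d[3] != 3L)
    stop("weights3 must be a (Kh, Kw, 3, Cout) array")
  if (sigma <= 0) stop("sigma must be positive, got ", sigma)
  n_extra <- as.integer(n_extra)
  if (n_extra < 0L) stop("n_extra must be non-negative")
  if (n_extra == 0L) return(weights3)
  out <- array(0, c(d[1], d[2], 3L + n_extra, d[4]))
  out[, , 1:3, ] <- weights3
  out[, , 3L + seq_len(n_extra), ] <-
    with_seed(seed, array(rnorm(d[1] * d[2] * n_extra * d[4], 0, sigma),
                          c(d[1], d[2], n_extra, d[4])))
  out
}
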