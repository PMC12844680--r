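#' @useDynLib dcaunet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif setNames
#' @keywords internal
"_PACKAGE"

# ---- module containers -----------------------------------------------------
#
# Every parameterized block is an environment ("dcamod") holding:
#   $p    named list of parameter arrays
#   $g    gradient accumulators (same names; NULL when zeroed)
#   $opt  optimizer state (lazily created by the Adam step)
#   $hyper structural hyperparameters
#   $decay named logical: which parameters receive weight decay
# Composite modules are plain nested lists of dcamods; collect_mods()
# walks the structure so the optimizer and (de)serialization see a flat
# list of parameter holders.

new_mod <- function(type, params = list(), hyper = list(),
                    decay = NULL) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$p <- params
  e$g <- list()
  e$opt <- NULL
  e$hyper <- hyper
  e$decay <- if (is.null(decay)) setNames(rep(FALSE, length(params)), names(params)) else decay
  class(e) <- c(paste0("mod_", type), "dcamod")
  e
}

acc_grad <- function(mod, name, val) {
  g <- mod$g[[name]]
  mod$g[[name]] <- if (is.null(g)) val else g + val
  invisible(NULL)
}

is_mod <- function(x) inherits(x, "dcamod")

collect_mods <- function(x) {
  if (is_mod(x)) return(list(x))
  if (is.list(x)) return(do.call(c, lapply(x, collect_mods)))
  list()
}

zero_grads <- function(model) {
  for (m in collect_mods(model)) m$g <- list()
  invisible(model)
}

#' Count trainable parameters of a model or module
#'
#' @param model a model object (nested list of parameter modules).
#' @return integer scalar, total number of scalar parameters.
#' @export
n_params <- function(model) {
  sum(vapply(collect_mods(model),
             function(m) sum(vapply(m$p, length, 1L)), 1))
}

#' Extract or restore the parameter state of a model
#'
#' `model_state()` returns a plain list of parameter arrays (a
#' checkpointable snapshot); `load_state()` writes such a snapshot back
#' into a structurally identical model.
#'
#' @param model a model object.
#' @return for `model_state`, a list of parameter lists (one per module).
#' @export
model_state <- function(model) {
  lapply(collect_mods(model), function(m) m$p)
}

#' @rdname model_state
#' @param state a snapshot previously produced by [model_state()].
#' @export
load_state <- function(model, state) {
  mods <- collect_mods(model)
  stopifnot(length(mods) == length(state))
  for (i in seq_along(mods)) {
    stopifnot(identical(names(mods[[i]]$p), names(state[[i]])))
    mods[[i]]$p <- state[[i]]
  }
  invisible(model)
}

# Run code under a fixed RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic derivation of per-item seeds from a master seed,
# kept inside 32-bit integer range.
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) * 7919 + as.numeric(i) * 104729) %%
               2147483647)
}

# ---- primitive layers ------------------------------------------------------

# 2-D convolution over (H, W, C, N) arrays. Default init is fan-in
# scaled Gaussian (He), which keeps signal variance stable through the
# shallow from-scratch models this package trains; zero bias.
ly_conv <- function(cin, cout, k, stride = 1L, pad = 0L, groups = 1L,
                    init_sd = NULL, bias = TRUE) {
  stopifnot(cin %% groups == 0, cout %% groups == 0)
  if (is.null(init_sd))
    init_sd <- sqrt(2 / (k * k * (cin %/% groups)))
  W <- array(rnorm(k * k * (cin %/% groups) * cout, 0, init_sd),
             c(k, k, cin %/% groups, cout))
  p <- list(W = W)
  if (bias) p$b <- numeric(cout)
  new_mod("conv", p,
          hyper = list(cin = cin, cout = cout, k = k, stride = as.integer(stride),
                       pad = as.integer(pad), groups = as.integer(groups)),
          decay = c(W = TRUE, if (bias) c(b = FALSE)))
}

fwd_conv <- function(mod, x) {
  h <- mod$hyper
  y <- cpp_conv2d(x, mod$p$W, if (is.null(mod$p$b)) numeric(0) else mod$p$b,
                  h$stride, h$pad, h$groups)
  list(y = y, cache = x)
}

bwd_conv <- function(mod, cache, dy, need_dx = TRUE) {
  h <- mod$hyper
  r <- cpp_conv2d_bwd(cache, mod$p$W, dy, h$stride, h$pad, h$groups, need_dx)
  acc_grad(mod, "W", r$dw)
  if (!is.null(mod$p$b)) acc_grad(mod, "b", r$db)
  if (need_dx) r$dx else NULL
}

# Channel-wise LayerNorm (per spatial position, over channels).
ly_ln <- function(C, eps = 1e-6) {
  new_mod("ln", list(gamma = rep(1, C), beta = numeric(C)),
          hyper = list(C = C, eps = eps),
          decay = c(gamma = FALSE, beta = FALSE))
}

fwd_ln <- function(mod, x) {
  r <- cpp_ln_fwd(x, mod$p$gamma, mod$p$beta, mod$hyper$eps)
  list(y = r$y, cache = list(x = x, mu = r$mu, invstd = r$invstd))
}

bwd_ln <- function(mod, cache, dy) {
  r <- cpp_ln_bwd(cache$x, mod$p$gamma, cache$mu, cache$invstd, dy)
  acc_grad(mod, "gamma", r$dgamma)
  acc_grad(mod, "beta", r$dbeta)
  r$dx
}

# Per-channel learnable scale (layer scale).
ly_scale <- function(C, init = 1e-6) {
  new_mod("scale", list(s = rep(init, C)), hyper = list(C = C),
          decay = c(s = FALSE))
}

fwd_scale <- function(mod, x) {
  list(y = cpp_scale_chan(x, mod$p$s), cache = x)
}

bwd_scale <- function(mod, cache, dy) {
  r <- cpp_scale_chan_bwd(cache, dy, mod$p$s)
  acc_grad(mod, "s", r$ds)
  r$dx
}

# Learnable scalar (attention gains gamma, fusion weights alpha/beta).
ly_scalar <- function(init, name = "v") {
  new_mod("scalar", setNames(list(init), name),
          decay = setNames(FALSE, name))
}

# Shared two-layer channel MLP used by channel attention; acts on
# (C, N) matrices of pooled descriptors.
ly_cmlp <- function(C, hidden) {
  new_mod("cmlp",
          list(W1 = matrix(rnorm(hidden * C, 0, sqrt(2 / C)), hidden, C),
               b1 = numeric(hidden),
               W2 = matrix(rnorm(C * hidden, 0, sqrt(2 / hidden)), C,
                           hidden),
               b2 = numeric(C)),
          hyper = list(C = C, hidden = hidden),
          decay = c(W1 = TRUE, b1 = FALSE, W2 = TRUE, b2 = FALSE))
}

fwd_cmlp <- function(mod, x) {  # x: (C, N)
  a <- mod$p$W1 %*% x + mod$p$b1
  h <- pmax(a, 0)
  y <- mod$p$W2 %*% h + mod$p$b2
  list(y = y, cache = list(x = x, a = a, h = h))
}

bwd_cmlp <- function(mod, cache, dy) {
  dh <- crossprod(mod$p$W2, dy)
  acc_grad(mod, "W2", tcrossprod(dy, cache$h))
  acc_grad(mod, "b2", rowSums(dy))
  da <- dh * (cache$a > 0)
  acc_grad(mod, "W1", tcrossprod(da, cache$x))
  acc_grad(mod, "b1", rowSums(da))
  crossprod(mod$p$W1, da)
}

# ---- parameter-free ops ----------------------------------------------------

gelu_fwd <- function(x) cpp_gelu(x)

gelu_bwd <- function(x, dy) cpp_gelu_bwd(x, dy)

sigmoid <- function(x) 1 / (1 + exp(-x))

up2x_fwd <- function(x) {
  d <- dim(x)
  cpp_resize_bilinear(x, 2L * d[1], 2L * d[2])
}

up2x_bwd <- function(dy, H, W) cpp_resize_bilinear_adj(dy, H, W)

concat_chan <- function(a, b) cpp_concat_chan(a, b)

split_chan <- function(dy, c1) cpp_split_chan(dy, as.integer(c1))

# broadcast multiply of per-channel weights (C,N) onto (H,W,C,N)
mul_chan <- function(x, mc) cpp_mul_chan(x, mc)

# broadcast multiply of spatial weights (H,W,1,N) onto (H,W,C,N)
mul_spat <- function(x, ms) cpp_mul_spat(x, ms)
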