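# Shared fixtures and independent oracles used across the suite.

ns <- asNamespace("dcaunet")

# central finite-difference gradient of a scalar function
num_grad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

rel_err <- function(a, b) {
  max(abs(a - b)) / max(1e-8, max(abs(a)), max(abs(b)))
}

# brute-force bidirectional cross-attention, written independently of
# the package: plain loops over positions
brute_cotsr <- function(X1, X2, g1, g2) {
  d <- dim(X1)
  HW <- d[1] * d[2]
  out <- list(Y1 = X1, Y2 = X2)
  for (n in seq_len(d[4])) {
    M1 <- matrix(X1[, , , n], HW, d[3])
    M2 <- matrix(X2[, , , n], HW, d[3])
    att <- function(Q, K, V) {
      O <- matrix(0, HW, d[3])
      for (i in seq_len(HW)) {
        s <- numeric(HW)
        for (j in seq_len(HW)) s[j] <- sum(Q[i, ] * K[j, ])
        a <- exp(s - max(s)); a <- a / sum(a)
        for (j in seq_len(HW)) O[i, ] <- O[i, ] + a[j] * V[j, ]
      }
      O
    }
    out$Y1[, , , n] <- array(M1 + g1 * att(M1, M2, M2), d[1:3])
    out$Y2[, , , n] <- array(M2 + g2 * att(M2, M1, M1), d[1:3])
  }
  out
}

# CotSR module whose Q/K/V projections are exact identities
identity_cotsr <- function(C, g1 = 1, g2 = 1) {
  m <- dcaunet::cotsr_module(C, qk_reduction = 1L, gamma_init = 0)
  eye <- array(0, c(1, 1, C, C))
  for (i in seq_len(C)) eye[1, 1, i, i] <- 1
  for (nm in c("q1", "k1", "v1", "q2", "k2", "v2")) m[[nm]]$p$W <- eye
  m$g1$p$v <- g1
  m$g2$p$v <- g2
  m
}

# small multimodal fixtures, generated once per session
tiny_spec <- function(px = 64L, ...) {
  dcaunet::scene_spec(px, px, n_crowns = 3L,
                      crown_radius_range = c(6, 12), n_distractors = 4L,
                      ...)
}

tiny_model <- function(mode = "fused", seed = 3L, ...) {
  dcaunet::build_model(
    dcaunet::model_config(width_multiplier = 1 / 24,
                          depths = c(1L, 1L, 1L, 1L), seed = seed, ...),
    mode = mode)
}
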