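# Neural-network primitives with explicit forward/backward passes.
# Feature maps are numeric arrays of shape (D, H, W, C); parameters live in
# nested named lists of arrays, and gradients mirror that structure exactly.
# 3D convolutions run through im2col + GEMM in C++ (src/ops.cpp); the
# remaining ops (group norm, SiLU, tanh, nearest upsampling) are vectorized R.

.he_init <- function(k, cin, cout) {
  sd <- sqrt(2 / (k * k * k * cin))
  list(W = array(stats::rnorm(k^3 * cin * cout, 0, sd), c(k, k, k, cin, cout)),
       b = numeric(cout))
}

.gn_init <- function(ch) list(gamma = rep(1, ch), beta = numeric(ch))

.conv_fwd <- function(x, p, stride = 1L) {
  k <- dim(p$W)[1]
  cin <- dim(p$W)[4]; cout <- dim(p$W)[5]
  pad <- (k - 1L) %/% 2L
  y <- cpp_conv3d_fwd(as.double(x), dim(x)[1:3], as.double(p$W), k, cin, cout,
                      p$b, as.integer(stride), pad)
  list(y = y, x = x)
}

.conv_bwd <- function(p, cache, dy, stride = 1L) {
  k <- dim(p$W)[1]
  cin <- dim(p$W)[4]; cout <- dim(p$W)[5]
  pad <- (k - 1L) %/% 2L
  r <- cpp_conv3d_bwd(as.double(cache$x), dim(cache$x)[1:3], as.double(p$W),
                      k, cin, cout, as.double(dy), dim(dy)[1:3],
                      as.integer(stride), pad)
  list(dx = r$dx, grads = list(W = r$dW, b = r$db))
}

.gn_fwd <- function(x, p, groups) {
  dims <- dim(x)
  C <- dims[4]
  stopifnot(C %% groups == 0)
  xm <- matrix(x, ncol = C)
  per <- C %/% groups
  mu <- numeric(groups); sg <- numeric(groups)
  xhat <- xm
  eps <- 1e-5
  for (g in seq_len(groups)) {
    cols <- ((g - 1) * per + 1):(g * per)
    v <- xm[, cols]
    mu[g] <- mean(v)
    sg[g] <- sqrt(mean((v - mu[g])^2) + eps)
    xhat[, cols] <- (v - mu[g]) / sg[g]
  }
  y <- sweep(xhat, 2, p$gamma, "*")
  y <- sweep(y, 2, p$beta, "+")
  list(y = array(y, dims), cache = list(xhat = xhat, sg = sg, dims = dims,
                                        groups = groups, per = per))
}

.gn_bwd <- function(p, cache, dy) {
  dims <- cache$dims
  C <- dims[4]
  dym <- matrix(dy, ncol = C)
  xhat <- cache$xhat
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2, p$gamma, "*")
  dx <- dxhat
  for (g in seq_len(cache$groups)) {
    cols <- ((g - 1) * cache$per + 1):(g * cache$per)
    dh <- dxhat[, cols]; xh <- xhat[, cols]
    m1 <- mean(dh); m2 <- mean(dh * xh)
    dx[, cols] <- (dh - m1 - xh * m2) / cache$sg[g]
  }
  list(dx = array(dx, dims), grads = list(gamma = dgamma, beta = dbeta))
}

.silu_fwd <- function(x) {
  s <- 1 / (1 + exp(-x))
  list(y = x * s, s = s, x = x)
}

.silu_bwd <- function(cache, dy) {
  dy * (cache$s * (1 + cache$x * (1 - cache$s)))
}

.tanh_fwd <- function(x) {
  y <- tanh(x)
  list(y = y)
}

.tanh_bwd <- function(cache, dy) dy * (1 - cache$y^2)

.upsample_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2),
    rep(seq_len(d[3]), each = 2), , drop = FALSE]
}

.upsample_bwd <- function(dy) {
  d <- dim(dy)
  out <- array(0, c(d[1] %/% 2, d[2] %/% 2, d[3] %/% 2, d[4]))
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    out <- out + dy[seq(1 + a, d[1], 2), seq(1 + b, d[2], 2),
                    seq(1 + cc, d[3], 2), , drop = FALSE]
  }
  out
}

# residual block: x + (conv -> gn -> SiLU -> conv -> gn), then SiLU
.resblock_init <- function(ch) {
  list(conv1 = .he_init(3L, ch, ch), gn1 = .gn_init(ch),
       conv2 = .he_init(3L, ch, ch), gn2 = .gn_init(ch))
}

.resblock_fwd <- function(x, p, groups) {
  c1 <- .conv_fwd(x, p$conv1)
  g1 <- .gn_fwd(c1$y, p$gn1, groups)
  a1 <- .silu_fwd(g1$y)
  c2 <- .conv_fwd(a1$y, p$conv2)
  g2 <- .gn_fwd(c2$y, p$gn2, groups)
  s <- g2$y + x
  a2 <- .silu_fwd(s)
  list(y = a2$y, cache = list(c1 = c1, g1 = g1, a1 = a1, c2 = c2, g2 = g2,
                              a2 = a2))
}

.resblock_bwd <- function(p, cache, dy, groups) {
  ds <- .silu_bwd(cache$a2, dy)
  g2 <- .gn_bwd(p$gn2, cache$g2$cache, ds)
  c2 <- .conv_bwd(p$conv2, cache$c2, g2$dx)
  da1 <- .silu_bwd(cache$a1, c2$dx)
  g1 <- .gn_bwd(p$gn1, cache$g1$cache, da1)
  c1 <- .conv_bwd(p$conv1, cache$c1, g1$dx)
  dx <- c1$dx + ds  # skip connection
  list(dx = dx,
       grads = list(conv1 = c1$grads, gn1 = g1$grads,
                    conv2 = c2$grads, gn2 = g2$grads))
}

# ---- Adam over nested parameter lists ----------------------------------

.zeros_like <- function(p) {
  if (is.list(p)) lapply(p, .zeros_like)
  else { z <- p; z[] <- 0; z }
}

adam_init <- function(params) list(m = .zeros_like(params),
                                   v = .zeros_like(params), t = 0L)

.adam_rec <- function(p, g, m, v, lr, b1, b2, eps, bc1, bc2) {
  if (is.list(p)) {
    out_p <- p; out_m <- m; out_v <- v
    keys <- if (!is.null(names(p))) names(p) else seq_along(p)
    for (i in keys) {
      r <- .adam_rec(p[[i]], g[[i]], m[[i]], v[[i]], lr, b1, b2, eps,
                     bc1, bc2)
      out_p[[i]] <- r$p; out_m[[i]] <- r$m; out_v[[i]] <- r$v
    }
    list(p = out_p, m = out_m, v = out_v)
  } else {
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
}

adam_step <- function(params, grads, state, lr, betas = c(0.5, 0.999),
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - betas[1]^state$t
  bc2 <- 1 - betas[2]^state$t
  r <- .adam_rec(params, grads, state$m, state$v, lr, betas[1], betas[2],
                 eps, bc1, bc2)
  state$m <- r$m; state$v <- r$v
  list(params = r$p, state = state)
}

.grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.list(a)) mapply(.grads_add, a, b, SIMPLIFY = FALSE)
  else a + b
}

.grads_scale <- function(a, s) {
  if (is.list(a)) lapply(a, .grads_scale, s = s)
  else a * s
}

.grads_max_abs <- function(a) {
  if (is.list(a)) max(vapply(a, .grads_max_abs, numeric(1)))
  else max(abs(a))
}
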