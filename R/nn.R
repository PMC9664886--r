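# Minimal explicit-gradient layer library for the conditional GAN.
# Images are H x W x C numeric arrays; convolutions run through the
# compiled im2col kernels. Every layer stores its parameters, Adam state
# and (optionally) a spectral-normalisation power-iteration vector.

new_conv_layer <- function(name, k, cin, cout, stride = 1, pad = NULL,
                           rng, spectral_norm = FALSE) {
  if (is.null(pad)) pad <- (k - 1) %/% 2
  w <- array(rng$norm(k * k * cin * cout, 0, 0.02), dim = c(k, k, cin, cout))
  list(name = name, k = k, cin = cin, cout = cout, stride = stride,
       pad = pad, w = w, b = rep(0, cout),
       sn = spectral_norm,
       u = if (spectral_norm) rng$norm(cout) else NULL,
       m_w = array(0, dim(w)), v_w = array(0, dim(w)),
       m_b = rep(0, cout), v_b = rep(0, cout), t = 0L)
}

# Spectral normalisation: one power iteration per call on the natural
# (k*k*cin x cout) weight matrix (the column-major flattening of the R
# array); returns the normalised weight, the singular pair and sigma.
sn_weight <- function(layer) {
  wm <- matrix(layer$w, ncol = layer$cout)
  u <- layer$u                       # cout-space singular vector
  v <- drop(wm %*% u); v <- v / sqrt(sum(v^2) + 1e-12)
  u <- drop(crossprod(wm, v)); nu <- sqrt(sum(u^2) + 1e-12); u <- u / nu
  sigma <- max(drop(crossprod(v, wm %*% u)), 1e-12)
  list(w = layer$w / sigma, u = u, v = v, sigma = sigma)
}

conv_forward <- function(layer, x) {
  if (isTRUE(layer$sn)) {
    s <- sn_weight(layer)
    w_eff <- s$w
    attrs <- list(u = s$u, v = s$v, sigma = s$sigma)
  } else {
    w_eff <- layer$w
    attrs <- list(sigma = 1)
  }
  y <- conv2d_forward(x, w_eff, layer$b, layer$stride, layer$pad)
  list(y = y, x = x, w_eff = w_eff, sn_state = attrs)
}

conv_backward <- function(layer, cache, dy) {
  g <- conv2d_backward(cache$x, cache$w_eff, dy, layer$stride, layer$pad)
  if (isTRUE(layer$sn)) {
    # full gradient through W/sigma with sigma = v' W u (Danskin):
    # dL/dW = G/sigma - (<G, W/sigma>/sigma) v u'
    sn <- cache$sn_state
    Gm <- matrix(g$dw, ncol = layer$cout)
    Wh <- matrix(cache$w_eff, ncol = layer$cout)
    dWm <- Gm / sn$sigma - (sum(Gm * Wh) / sn$sigma) * tcrossprod(sn$v, sn$u)
    g$dw <- array(dWm, dim = c(layer$k, layer$k, layer$cin, layer$cout))
  }
  g
}

lrelu_forward <- function(x, slope = 0.2) {
  list(y = lrelu_fwd(x, slope), slope = slope)
}
lrelu_backward <- function(cache, dy) lrelu_bwd(cache$y, dy, cache$slope)

tanh_forward <- function(x) { y <- tanh(x); list(y = y) }
tanh_backward <- function(cache, dy) dy * (1 - cache$y^2)

upsample2_forward <- function(x) {
  d <- dim(x)
  out <- array(0, dim = c(2, d[1], 2, d[2], d[3]))
  out[1, , 1, , ] <- x; out[2, , 1, , ] <- x
  out[1, , 2, , ] <- x; out[2, , 2, , ] <- x
  dim(out) <- c(2 * d[1], 2 * d[2], d[3])
  out
}
upsample2_backward <- function(dy) {
  d <- dim(dy)
  dim(dy) <- c(2, d[1] / 2, 2, d[2] / 2, d[3])
  out <- dy[1, , 1, , ] + dy[2, , 1, , ] + dy[1, , 2, , ] + dy[2, , 2, , ]
  dim(out) <- c(d[1] / 2, d[2] / 2, d[3])
  out
}

# Instance normalisation: per-channel standardisation over the spatial
# dimensions with learned scale (w) and shift (b).
new_in_layer <- function(name, cc) {
  list(name = name, cc = cc, w = rep(1, cc), b = rep(0, cc),
       m_w = rep(0, cc), v_w = rep(0, cc), m_b = rep(0, cc),
       v_b = rep(0, cc), t = 0L)
}

in_forward <- function(layer, x) {
  d <- dim(x)
  m <- matrix(x, ncol = d[3])
  mu <- colMeans(m)
  xc <- sweep(m, 2, mu)
  s <- sqrt(colMeans(xc^2) + 1e-5)
  xh <- sweep(xc, 2, s, `/`)
  y <- sweep(sweep(xh, 2, layer$w, `*`), 2, layer$b, `+`)
  dim(y) <- d
  list(y = y, xh = xh, s = s, d = d)
}

in_backward <- function(layer, cache, dy) {
  d <- cache$d
  dym <- matrix(dy, ncol = d[3])
  dgamma <- colSums(dym * cache$xh)
  dbeta <- colSums(dym)
  t1 <- sweep(dym, 2, colMeans(dym))
  t2 <- sweep(cache$xh, 2, colMeans(dym * cache$xh), `*`)
  dx <- sweep(t1 - t2, 2, layer$w / cache$s, `*`)
  dim(dx) <- d
  list(dx = dx, dw = dgamma, db = dbeta)
}

# Adam step; beta1 = 0.5 as is conventional for adversarial training.
adam_step <- function(layer, dw, db, lr, beta1 = 0.5, beta2 = 0.999,
                      eps = 1e-8) {
  layer$t <- layer$t + 1L
  uw <- adam_update(layer$w, dw, layer$m_w, layer$v_w, lr, beta1, beta2,
                    eps, layer$t)
  layer$w <- uw$w; layer$m_w <- uw$m; layer$v_w <- uw$v
  ub <- adam_update(layer$b, db, layer$m_b, layer$v_b, lr, beta1, beta2,
                    eps, layer$t)
  layer$b <- ub$w; layer$m_b <- ub$m; layer$v_b <- ub$v
  layer
}
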