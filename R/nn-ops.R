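# Internal neural-network primitives: forward/backward passes for the
# layers used by the autoencoder, plus the Adam optimiser. All arrays use
# the layout (batch, position/time, channels); weights for 1-D (transposed)
# convolutions are stored as (kernel_tap * in_channels) x filters matrices
# with tap-major row order, so tap q occupies rows ((q-1)*C + 1):(q*C).

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot_uniform <- function(nrow, ncol, fan_in, fan_out) {
  limit <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -limit, limit), nrow, ncol)
}

## ---- 1-D convolution (valid padding, stride 1) ----

conv1d_forward <- function(X, W, b, k) {
  d <- dim(X)
  B <- d[1L]; L <- d[2L]; C <- d[3L]
  Lout <- L - k + 1L
  Xcol <- array(0, c(B, Lout, k * C))
  for (q in seq_len(k))
    Xcol[, , ((q - 1L) * C + 1L):(q * C)] <- X[, q:(q + Lout - 1L), , drop = FALSE]
  m <- matrix(Xcol, B * Lout, k * C)
  out <- m %*% W
  out <- sweep(out, 2L, b, "+")
  list(out = array(out, c(B, Lout, ncol(W))), m = m, dims = c(B, L, C, k))
}

conv1d_backward <- function(cache, W, dOut) {
  B <- cache$dims[1L]; L <- cache$dims[2L]; C <- cache$dims[3L]; k <- cache$dims[4L]
  Lout <- L - k + 1L
  Fo <- ncol(W)
  dm_out <- matrix(dOut, B * Lout, Fo)
  dW <- crossprod(cache$m, dm_out)
  db <- colSums(dm_out)
  dcol <- dm_out %*% t(W)                     # (B*Lout) x (k*C)
  dX <- array(0, c(B, L, C))
  dcol <- array(dcol, c(B, Lout, k * C))
  for (q in seq_len(k))
    dX[, q:(q + Lout - 1L), ] <- dX[, q:(q + Lout - 1L), , drop = FALSE] +
      dcol[, , ((q - 1L) * C + 1L):(q * C), drop = FALSE]
  list(dX = dX, dW = dW, db = db)
}

## ---- 1-D transposed convolution (stride 1, no padding) ----

convt1d_forward <- function(X, W, b, k) {
  d <- dim(X)
  B <- d[1L]; L <- d[2L]; C <- d[3L]
  Fo <- ncol(W)
  Lout <- L + k - 1L
  Xmat <- matrix(X, B * L, C)
  out <- array(0, c(B, Lout, Fo))
  for (q in seq_len(k)) {
    Wq <- W[((q - 1L) * C + 1L):(q * C), , drop = FALSE]
    out[, q:(q + L - 1L), ] <- out[, q:(q + L - 1L), , drop = FALSE] +
      array(Xmat %*% Wq, c(B, L, Fo))
  }
  out <- out + rep(b, each = B * Lout)
  list(out = out, Xmat = Xmat, dims = c(B, L, C, k))
}

convt1d_backward <- function(cache, W, dOut) {
  B <- cache$dims[1L]; L <- cache$dims[2L]; C <- cache$dims[3L]; k <- cache$dims[4L]
  Fo <- ncol(W)
  dW <- matrix(0, k * C, Fo)
  dXmat <- matrix(0, B * L, C)
  for (q in seq_len(k)) {
    Wq <- W[((q - 1L) * C + 1L):(q * C), , drop = FALSE]
    dseg <- matrix(dOut[, q:(q + L - 1L), , drop = FALSE], B * L, Fo)
    dW[((q - 1L) * C + 1L):(q * C), ] <- crossprod(cache$Xmat, dseg)
    dXmat <- dXmat + dseg %*% t(Wq)
  }
  db <- colSums(matrix(dOut, ncol = Fo))
  list(dX = array(dXmat, c(B, L, C)), dW = dW, db = db)
}

## ---- plain LSTM over a sequence (returns full hidden sequence) ----
## Gate order in weight columns: input, forget, cell, output.

lstm_forward <- function(X, Wx, Wh, b, keep_cache = TRUE) {
  d <- dim(X)
  B <- d[1L]; Tn <- d[2L]; D <- d[3L]
  U <- ncol(Wh) / 4L
  h <- matrix(0, B, U); cc <- matrix(0, B, U)
  H <- array(0, c(B, Tn, U))
  cache <- if (keep_cache) vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    xt <- matrix(X[, t, ], B, D)
    z <- xt %*% Wx + h %*% Wh
    z <- sweep(z, 2L, b, "+")
    gi <- sigmoid(z[, 1:U, drop = FALSE])
    gf <- sigmoid(z[, (U + 1):(2 * U), drop = FALSE])
    gg <- tanh(z[, (2 * U + 1):(3 * U), drop = FALSE])
    go <- sigmoid(z[, (3 * U + 1):(4 * U), drop = FALSE])
    c_prev <- cc
    cc <- gf * c_prev + gi * gg
    tc <- tanh(cc)
    h_prev_t <- h
    h <- go * tc
    H[, t, ] <- h
    if (keep_cache)
      cache[[t]] <- list(xt = xt, h_prev = h_prev_t, c_prev = c_prev,
                         i = gi, f = gf, g = gg, o = go, tc = tc)
  }
  list(H = H, cache = cache, dims = c(B, Tn, D, U))
}

lstm_backward <- function(fw, Wx, Wh, dH) {
  B <- fw$dims[1L]; Tn <- fw$dims[2L]; D <- fw$dims[3L]; U <- fw$dims[4L]
  dWx <- matrix(0, D, 4L * U); dWh <- matrix(0, U, 4L * U); db <- numeric(4L * U)
  dh_next <- matrix(0, B, U); dc_next <- matrix(0, B, U)
  dX <- array(0, c(B, Tn, D))
  for (t in rev(seq_len(Tn))) {
    cs <- fw$cache[[t]]
    dh <- matrix(dH[, t, ], B, U) + dh_next
    dc <- dc_next + dh * cs$o * (1 - cs$tc^2)
    d_i <- dc * cs$g * cs$i * (1 - cs$i)
    d_f <- dc * cs$c_prev * cs$f * (1 - cs$f)
    d_g <- dc * cs$i * (1 - cs$g^2)
    d_o <- dh * cs$tc * cs$o * (1 - cs$o)
    dz <- cbind(d_i, d_f, d_g, d_o)
    dWx <- dWx + crossprod(cs$xt, dz)
    dWh <- dWh + crossprod(cs$h_prev, dz)
    db <- db + colSums(dz)
    dX[, t, ] <- dz %*% t(Wx)
    dh_next <- dz %*% t(Wh)
    dc_next <- dc * cs$f
  }
  list(dX = dX, dWx = dWx, dWh = dWh, db = db)
}

## ---- convolutional LSTM along the electrode axis ----
## Input: (B, S, 4) — at each time step a length-4 electrode vector with one
## feature. Input-to-gate convolution: kernel 2, valid, 4 -> 3 positions;
## recurrent convolution: kernel 2, same padding on the 3 hidden positions.
## 20 filters per gate. The three spatial positions are stacked into a
## "super-batch" of 3B rows (position-major blocks) so each time step is two
## matrix products plus elementwise gate maps.

convlstm_forward <- function(X, Wx, Wh, b, keep_cache = TRUE) {
  d <- dim(X)
  B <- d[1L]; S <- d[2L]
  U <- ncol(Wh) / 4L                    # filters (20)
  B3 <- 3L * B
  j2 <- (B + 1L):(2L * B); j3 <- (2L * B + 1L):B3
  h <- matrix(0, B3, U); cc <- matrix(0, B3, U)
  cache <- if (keep_cache) vector("list", S) else NULL
  zeroB <- matrix(0, B, U)
  for (t in seq_len(S)) {
    xt <- matrix(X[, t, ], B, 4L)
    Pin <- rbind(xt[, 1:2, drop = FALSE],
                 xt[, 2:3, drop = FALSE],
                 xt[, 3:4, drop = FALSE])           # B3 x 2
    h_shift <- rbind(h[j2, , drop = FALSE], h[j3, , drop = FALSE], zeroB)
    z <- Pin %*% Wx + cbind(h, h_shift) %*% Wh
    z <- sweep(z, 2L, b, "+")
    gi <- sigmoid(z[, 1:U, drop = FALSE])
    gf <- sigmoid(z[, (U + 1):(2 * U), drop = FALSE])
    gg <- tanh(z[, (2 * U + 1):(3 * U), drop = FALSE])
    go <- sigmoid(z[, (3 * U + 1):(4 * U), drop = FALSE])
    c_prev <- cc
    cc <- gf * c_prev + gi * gg
    tc <- tanh(cc)
    h_prev <- h
    h <- go * tc
    if (keep_cache)
      cache[[t]] <- list(Pin = Pin, h_prev = h_prev, c_prev = c_prev,
                         i = gi, f = gf, g = gg, o = go, tc = tc)
  }
  list(h = h, cache = cache, dims = c(B, S, U))
}

convlstm_backward <- function(fw, Wx, Wh, dh_final) {
  B <- fw$dims[1L]; S <- fw$dims[2L]; U <- fw$dims[3L]
  B3 <- 3L * B
  j1 <- 1:B; j2 <- (B + 1L):(2L * B); j3 <- (2L * B + 1L):B3
  dWx <- matrix(0, 2L, 4L * U); dWh <- matrix(0, 2L * U, 4L * U)
  db <- numeric(4L * U)
  dh_next <- dh_final                 # B3 x U, gradient w.r.t. final h
  dc_next <- matrix(0, B3, U)
  dX <- array(0, c(B, S, 4L))
  Wh_self <- Wh[1:U, , drop = FALSE]
  Wh_up <- Wh[(U + 1):(2 * U), , drop = FALSE]
  for (t in rev(seq_len(S))) {
    cs <- fw$cache[[t]]
    dh <- dh_next
    dc <- dc_next + dh * cs$o * (1 - cs$tc^2)
    d_i <- dc * cs$g * cs$i * (1 - cs$i)
    d_f <- dc * cs$c_prev * cs$f * (1 - cs$f)
    d_g <- dc * cs$i * (1 - cs$g^2)
    d_o <- dh * cs$tc * cs$o * (1 - cs$o)
    dz <- cbind(d_i, d_f, d_g, d_o)                 # B3 x 4U
    dWx <- dWx + crossprod(cs$Pin, dz)
    h_shift <- rbind(cs$h_prev[j2, , drop = FALSE],
                     cs$h_prev[j3, , drop = FALSE],
                     matrix(0, B, U))
    dWh <- dWh + crossprod(cbind(cs$h_prev, h_shift), dz)
    db <- db + colSums(dz)
    dPin <- dz %*% t(Wx)                            # B3 x 2
    dxt <- matrix(0, B, 4L)
    dxt[, 1:2] <- dPin[j1, , drop = FALSE]
    dxt[, 2:3] <- dxt[, 2:3] + dPin[j2, , drop = FALSE]
    dxt[, 3:4] <- dxt[, 3:4] + dPin[j3, , drop = FALSE]
    dX[, t, ] <- dxt
    # recurrent path: h_j feeds position j (self tap) and position j-1 (up tap)
    dh_self <- dz %*% t(Wh_self)
    dh_up <- dz %*% t(Wh_up)
    dh_next <- dh_self
    dh_next[j2, ] <- dh_next[j2, , drop = FALSE] + dh_up[j1, , drop = FALSE]
    dh_next[j3, ] <- dh_next[j3, , drop = FALSE] + dh_up[j2, , drop = FALSE]
    dc_next <- dc * cs$f
  }
  list(dX = dX, dWx = dWx, dWh = dWh, db = db)
}

## ---- optimisers (SGD with momentum, Adam), global-norm gradient clipping ----

zero_like <- function(p) if (is.list(p)) lapply(p, zero_like) else p * 0

sgd_init <- function(params) list(v = zero_like(params))

sgd_step <- function(params, grads, state, lr = 0.01, momentum = 0.9,
                     clip_norm = 5) {
  gn <- sqrt(sum(.flatten_grads(grads)^2))
  scale <- if (is.finite(gn) && gn > clip_norm) clip_norm / gn else 1
  upd <- function(p, g, v) {
    if (is.list(p)) {
      out <- mapply(upd, p, g, v, SIMPLIFY = FALSE)
      return(list(p = lapply(out, `[[`, "p"), v = lapply(out, `[[`, "v")))
    }
    v <- momentum * v + g * scale
    list(p = p - lr * v, v = v)
  }
  out <- upd(params, grads, state$v)
  list(params = out$p, state = list(v = out$v))
}

adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

.flatten_grads <- function(g) {
  if (is.list(g)) unlist(lapply(g, .flatten_grads), use.names = FALSE) else as.numeric(g)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, clip_norm = 5) {
  gn <- sqrt(sum(.flatten_grads(grads)^2))
  scale <- if (is.finite(gn) && gn > clip_norm) clip_norm / gn else 1
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- mapply(upd, p, g, m, v, SIMPLIFY = FALSE)
      return(list(p = lapply(out, `[[`, "p"),
                  m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    g <- g * scale
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  out <- upd(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = t))
}
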