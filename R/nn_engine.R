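# Minimal neural-network engine.
#
# No deep-learning backend exists in this R environment, so the two networks
# of the pipeline (the accelerometer CNN and the ADL LSTM) are built on this
# small set of hand-derived layers: im2col 1-D convolutions, max pooling,
# dense layers, a full-sequence LSTM with backpropagation through time, and an
# Adam optimizer. Batch tensors are (N, L, C) arrays; dense activations are
# (N, F) matrices. Every layer is a plain list holding parameters and the
# shapes it needs; forward passes return caches that the matching backward
# pass consumes. Gradients are checked against finite differences in the test
# suite.

glorot <- function(n_in, n_out, fan_in = n_in, fan_out = n_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

## ---- dense -----------------------------------------------------------------

dense_init <- function(n_in, n_out) {
  list(type = "dense", W = glorot(n_in, n_out), b = numeric(n_out))
}

dense_forward <- function(layer, x) {
  y <- x %*% layer$W
  y <- sweep(y, 2, layer$b, "+")
  list(y = y, cache = list(x = x))
}

dense_backward <- function(layer, cache, dy) {
  list(dW = crossprod(cache$x, dy),
       db = colSums(dy),
       dx = tcrossprod(dy, layer$W))
}

## ---- activations -----------------------------------------------------------

relu_forward <- function(x) {
  y <- x * (x > 0)
  list(y = y, cache = x > 0)
}

relu_backward <- function(cache, dy) dy * cache

sigmoid <- function(x) 1 / (1 + exp(-x))

## ---- 1-D convolution (same padding) ----------------------------------------

conv1d_init <- function(c_in, c_out, kernel) {
  fan_in <- kernel * c_in
  lim <- sqrt(6 / (fan_in + c_out))
  list(type = "conv1d", kernel = kernel, c_in = c_in, c_out = c_out,
       W = matrix(stats::runif(fan_in * c_out, -lim, lim), fan_in, c_out),
       b = numeric(c_out))
}

# x: (N, L, Cin) -> padded (N, L + k - 1, Cin)
conv1d_pad <- function(x, k) {
  d <- dim(x)
  p_left <- (k - 1) %/% 2
  xp <- array(0, c(d[1], d[2] + k - 1, d[3]))
  xp[, p_left + seq_len(d[2]), ] <- x
  xp
}

# im2col: (N, L + k - 1, Cin) -> (N * L, k * Cin); rows ordered n-fastest.
conv1d_im2col <- function(xp, L, k) {
  N <- dim(xp)[1]; c_in <- dim(xp)[3]
  cols <- vector("list", k)
  for (j in seq_len(k)) {
    cols[[j]] <- matrix(xp[, j:(j + L - 1), , drop = FALSE], nrow = N * L)
  }
  do.call(cbind, cols)
}

conv1d_forward <- function(layer, x) {
  d <- dim(x)
  k <- layer$kernel
  xp <- conv1d_pad(x, k)
  x2 <- conv1d_im2col(xp, d[2], k)
  y2 <- x2 %*% layer$W
  y2 <- sweep(y2, 2, layer$b, "+")
  list(y = array(y2, c(d[1], d[2], layer$c_out)),
       cache = list(x2 = x2, dims = d))
}

conv1d_backward <- function(layer, cache, dy) {
  d <- cache$dims
  N <- d[1]; L <- d[2]; c_in <- d[3]
  k <- layer$kernel
  dy2 <- matrix(dy, nrow = N * L)
  dW <- crossprod(cache$x2, dy2)
  db <- colSums(dy2)
  dx2 <- tcrossprod(dy2, layer$W)
  dxp <- array(0, c(N, L + k - 1, c_in))
  for (j in seq_len(k)) {
    sl <- array(dx2[, ((j - 1) * c_in + 1):(j * c_in), drop = FALSE],
                c(N, L, c_in))
    dxp[, j:(j + L - 1), ] <- dxp[, j:(j + L - 1), , drop = FALSE] + sl
  }
  p_left <- (k - 1) %/% 2
  list(dW = dW, db = db, dx = dxp[, p_left + seq_len(L), , drop = FALSE])
}

## ---- max pooling over time (size 2) -----------------------------------------

maxpool2_forward <- function(x) {
  d <- dim(x)
  if (d[2] %% 2 != 0) stop("maxpool2 needs an even time dimension")
  a <- x[, seq(1, d[2], by = 2), , drop = FALSE]
  b <- x[, seq(2, d[2], by = 2), , drop = FALSE]
  take_a <- a >= b # ties -> earlier step
  list(y = pmax(a, b), cache = list(take_a = take_a, dims = d))
}

maxpool2_backward <- function(cache, dy) {
  d <- cache$dims
  dx <- array(0, d)
  da <- dy * cache$take_a
  db <- dy * !cache$take_a
  dx[, seq(1, d[2], by = 2), ] <- da
  dx[, seq(2, d[2], by = 2), ] <- db
  dx
}

## ---- LSTM (returns the full sequence) ---------------------------------------

lstm_init <- function(n_in, units) {
  # forget-gate bias starts at 1 (standard initialization)
  b <- numeric(4 * units)
  b[(units + 1):(2 * units)] <- 1
  list(type = "lstm", n_in = n_in, units = units,
       Wx = glorot(n_in, 4 * units, fan_in = n_in, fan_out = units),
       Wh = glorot(units, 4 * units, fan_in = units, fan_out = units),
       b = b)
}

# x: (N, L, n_in) -> H: (N, L, units). Gate layout along columns: i, f, g, o.
lstm_forward <- function(layer, x) {
  d <- dim(x)
  N <- d[1]; L <- d[2]; U <- layer$units
  H <- array(0, c(N, L, U))
  Cc <- array(0, c(N, L, U))
  G <- array(0, c(N, L, 4 * U)) # post-activation gates
  h <- matrix(0, N, U)
  cst <- matrix(0, N, U)
  iu <- seq_len(U); fu <- U + iu; gu <- 2 * U + iu; ou <- 3 * U + iu
  for (t in seq_len(L)) {
    xt <- matrix(x[, t, , drop = FALSE], N, d[3])
    z <- xt %*% layer$Wx + h %*% layer$Wh
    z <- sweep(z, 2, layer$b, "+")
    ig <- sigmoid(z[, iu, drop = FALSE])
    fg <- sigmoid(z[, fu, drop = FALSE])
    gg <- tanh(z[, gu, drop = FALSE])
    og <- sigmoid(z[, ou, drop = FALSE])
    cst <- fg * cst + ig * gg
    h <- og * tanh(cst)
    H[, t, ] <- h
    Cc[, t, ] <- cst
    G[, t, ] <- cbind(ig, fg, gg, og)
  }
  list(y = H, cache = list(x = x, H = H, C = Cc, G = G))
}

lstm_backward <- function(layer, cache, dH) {
  x <- cache$x
  d <- dim(x)
  N <- d[1]; L <- d[2]; U <- layer$units
  iu <- seq_len(U); fu <- U + iu; gu <- 2 * U + iu; ou <- 3 * U + iu
  dWx <- matrix(0, nrow(layer$Wx), ncol(layer$Wx))
  dWh <- matrix(0, nrow(layer$Wh), ncol(layer$Wh))
  db <- numeric(4 * U)
  dx <- array(0, d)
  dh_next <- matrix(0, N, U)
  dc_next <- matrix(0, N, U)
  for (t in rev(seq_len(L))) {
    g <- matrix(cache$G[, t, , drop = FALSE], N, 4 * U)
    ig <- g[, iu, drop = FALSE]; fg <- g[, fu, drop = FALSE]
    gg <- g[, gu, drop = FALSE]; og <- g[, ou, drop = FALSE]
    cst <- matrix(cache$C[, t, , drop = FALSE], N, U)
    c_prev <- if (t > 1) matrix(cache$C[, t - 1, , drop = FALSE], N, U) else
      matrix(0, N, U)
    h_prev <- if (t > 1) matrix(cache$H[, t - 1, , drop = FALSE], N, U) else
      matrix(0, N, U)
    tc <- tanh(cst)
    dh <- matrix(dH[, t, , drop = FALSE], N, U) + dh_next
    do_ <- dh * tc
    dc <- dc_next + dh * og * (1 - tc^2)
    di <- dc * gg
    dg <- dc * ig
    df <- dc * c_prev
    dz <- cbind(di * ig * (1 - ig),
                df * fg * (1 - fg),
                dg * (1 - gg^2),
                do_ * og * (1 - og))
    xt <- matrix(x[, t, , drop = FALSE], N, d[3])
    dWx <- dWx + crossprod(xt, dz)
    dWh <- dWh + crossprod(h_prev, dz)
    db <- db + colSums(dz)
    dx[, t, ] <- tcrossprod(dz, layer$Wx)
    dh_next <- tcrossprod(dz, layer$Wh)
    dc_next <- dc * fg
  }
  list(dWx = dWx, dWh = dWh, db = db, dx = dx)
}

## ---- softmax + weighted categorical cross-entropy ----------------------------

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# y: integer class index per row; class_w: per-class weights.
softmax_ce <- function(z, y, class_w = NULL) {
  p <- softmax_rows(z)
  n <- nrow(z)
  if (is.null(class_w)) class_w <- rep(1, ncol(z))
  w <- class_w[y]
  eps <- 1e-12
  loss <- -sum(w * log(pmax(p[cbind(seq_len(n), y)], eps))) / n
  onehot <- matrix(0, n, ncol(z))
  onehot[cbind(seq_len(n), y)] <- 1
  dz <- (p - onehot) * (w / n)
  list(loss = loss, p = p, dz = dz)
}

## ---- Adam --------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0)
}

adam_step <- function(state, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, params = params)
}

# Flatten a nested layer list into a named parameter list and back. Layer
# parameters are the matrix/vector entries named W, b, Wx, Wh.
.param_names <- c("W", "b", "Wx", "Wh")

collect_params <- function(layers) {
  out <- list()
  for (ln in names(layers)) {
    for (pn in intersect(names(layers[[ln]]), .param_names)) {
      out[[paste(ln, pn, sep = ".")]] <- layers[[ln]][[pn]]
    }
  }
  out
}

assign_params <- function(layers, params) {
  for (key in names(params)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    layers[[parts[1]]][[parts[2]]] <- params[[key]]
  }
  layers
}
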