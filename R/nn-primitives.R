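# Internal neural-network primitives.
#
# Batches are stored as dense matrices of shape (B*L) x C, sequence-major:
# sequence s occupies rows ((s-1)*L + 1):(s*L). Convolutions are computed
# as im2col + GEMM so the heavy lifting lands in BLAS; every primitive has
# an explicit hand-derived backward used by the trainers and checked
# against finite differences in the test suite.

add_bias <- function(Y, b) {
  cpp_add_bias(Y, b)
}

scale_cols <- function(Y, s) {
  cpp_scale_cols(Y, s)
}

# ---- 1D convolution (same-length, zero padding at sequence edges) --------

nn_conv_init <- function(cin, cout, k) {
  # He initialisation for ReLU stacks
  sd <- sqrt(2 / (k * cin))
  list(
    W = matrix(rnorm(k * cin * cout, 0, sd), nrow = k * cin, ncol = cout),
    b = numeric(cout)
  )
}

nn_conv_fwd <- function(X, p, B, L) {
  k <- nrow(p$W) %/% ncol(X)
  list(
    out = cpp_conv_fwd(X, p$W, p$b, B, L, k),
    cache = list(X = X, B = B, L = L, k = k)
  )
}

nn_conv_bwd <- function(dY, p, cache) {
  r <- cpp_conv_bwd(dY, cache$X, p$W, cache$B, cache$L, cache$k)
  list(dX = r$dX, grads = list(W = r$dW, b = r$db))
}

# ---- Pointwise linear (1x1 convolution / classifier head) ----------------

nn_linear_init <- function(cin, cout, relu = FALSE) {
  sd <- if (relu) sqrt(2 / cin) else sqrt(1 / cin)
  list(
    W = matrix(rnorm(cin * cout, 0, sd), nrow = cin, ncol = cout),
    b = numeric(cout)
  )
}

nn_linear_fwd <- function(X, p) {
  list(out = add_bias(X %*% p$W, p$b), cache = list(X = X))
}

nn_linear_bwd <- function(dY, p, cache) {
  list(
    dX = tcrossprod(dY, p$W),
    grads = list(W = crossprod(cache$X, dY), b = colSums(dY))
  )
}

# ---- Batch normalisation (per channel over all positions in the batch) ---

# Package-local knob so a batch-norm recalibration pass can average batch
# statistics exactly (momentum 1/i for the i-th batch) without threading a
# momentum argument through every architecture.
.nn_opts <- new.env(parent = emptyenv())
.nn_opts$bn_momentum <- 0.1

nn_bn_init <- function(c) {
  list(gamma = rep(1, c), beta = rep(0, c))
}

nn_bn_state <- function(c) {
  list(mean = rep(0, c), var = rep(1, c))
}

nn_bn_fwd <- function(X, p, state, training,
                      momentum = .nn_opts$bn_momentum, eps = 1e-5) {
  n <- nrow(X)
  if (training) {
    mom <- cpp_col_moments(X)
    mu <- mom$mean
    v <- pmax(mom$meansq - mu * mu, 0)
    unbiased <- if (n > 1) v * n / (n - 1) else v
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * unbiased
  } else {
    mu <- state$mean
    v <- state$var
  }
  invstd <- 1 / sqrt(v + eps)
  ap <- cpp_bn_apply(X, mu, invstd, p$gamma, p$beta)
  list(
    out = ap$out, state = state,
    cache = list(
      xhat = ap$xhat, invstd = invstd, gamma = p$gamma, training = training
    )
  )
}

nn_bn_bwd <- function(dY, cache) {
  r <- cpp_bn_backward(dY, cache$xhat, cache$invstd, cache$gamma, cache$training)
  list(dX = r$dX, grads = list(gamma = r$dgamma, beta = r$dbeta))
}

# ---- ReLU / dropout ------------------------------------------------------

nn_relu_fwd <- function(X) {
  r <- cpp_relu_fwd(X)
  list(out = r$out, cache = r$keep)
}

nn_relu_bwd <- function(dY, keep) {
  dY * keep
}

nn_dropout_fwd <- function(X, p, training) {
  if (!training || p <= 0) {
    return(list(out = X, cache = NULL))
  }
  keep <- matrix(
    (runif(length(X)) >= p) / (1 - p),
    nrow = nrow(X), ncol = ncol(X)
  )
  list(out = X * keep, cache = keep)
}

nn_dropout_bwd <- function(dY, keep) {
  if (is.null(keep)) dY else dY * keep
}

# ---- Max pooling, kernel 2 stride 2 --------------------------------------

nn_maxpool_fwd <- function(X, B, L) {
  stopifnot(L %% 2L == 0L)
  r <- cpp_maxpool_fwd(X)
  list(out = r$out, cache = list(take_a = r$take_a))
}

nn_maxpool_bwd <- function(dY, cache) {
  cpp_maxpool_bwd(dY, cache$take_a)
}

# ---- Transposed convolution, kernel 2 stride 2 (length doubling) ---------

nn_up_init <- function(cin, cout) {
  sd <- sqrt(2 / cin)
  list(
    W1 = matrix(rnorm(cin * cout, 0, sd), cin, cout),
    W2 = matrix(rnorm(cin * cout, 0, sd), cin, cout),
    b = numeric(cout)
  )
}

nn_up_fwd <- function(X, p) {
  n <- nrow(X)
  cout <- ncol(p$W1)
  out <- matrix(0, 2L * n, cout)
  odd <- seq.int(1L, 2L * n, by = 2L)
  out[odd, ] <- X %*% p$W1
  out[odd + 1L, ] <- X %*% p$W2
  list(out = add_bias(out, p$b), cache = list(X = X))
}

nn_up_bwd <- function(dY, p, cache) {
  n <- nrow(cache$X)
  odd <- seq.int(1L, 2L * n, by = 2L)
  d1 <- dY[odd, , drop = FALSE]
  d2 <- dY[odd + 1L, , drop = FALSE]
  list(
    dX = tcrossprod(d1, p$W1) + tcrossprod(d2, p$W2),
    grads = list(
      W1 = crossprod(cache$X, d1),
      W2 = crossprod(cache$X, d2),
      b = colSums(dY)
    )
  )
}

# ---- Additive attention gate (Attention-U-Net style, per position) -------

nn_att_init <- function(c_feat) {
  ci <- max(1L, c_feat %/% 2L)
  sd <- sqrt(1 / c_feat)
  list(
    Wg = matrix(rnorm(c_feat * ci, 0, sd), c_feat, ci),
    Wx = matrix(rnorm(c_feat * ci, 0, sd), c_feat, ci),
    b = numeric(ci),
    psi = matrix(rnorm(ci, 0, sqrt(1 / ci)), ci, 1),
    bpsi = 0
  )
}

nn_att_fwd <- function(skip, gate, p) {
  if (nrow(skip) != nrow(gate)) {
    stop("attention gate: skip and gating signals have different lengths",
      call. = FALSE
    )
  }
  pre <- add_bias(gate %*% p$Wg + skip %*% p$Wx, p$b)
  act <- pre * (pre > 0)
  q <- act %*% p$psi + p$bpsi
  alpha <- 1 / (1 + exp(-q))
  out <- skip * as.vector(alpha)
  list(
    out = out,
    cache = list(
      skip = skip, gate = gate, act = act, relu_keep = pre > 0, alpha = alpha
    )
  )
}

nn_att_bwd <- function(dY, p, cache) {
  alpha <- as.vector(cache$alpha)
  dskip <- dY * alpha
  dalpha <- rowSums(dY * cache$skip)
  dq <- dalpha * alpha * (1 - alpha)
  dpsi <- crossprod(cache$act, dq)
  dbpsi <- sum(dq)
  dact <- matrix(dq, ncol = 1) %*% t(p$psi)
  dpre <- dact * cache$relu_keep
  list(
    dskip = dskip + tcrossprod(dpre, p$Wx),
    dgate = tcrossprod(dpre, p$Wg),
    grads = list(
      Wg = crossprod(cache$gate, dpre),
      Wx = crossprod(cache$skip, dpre),
      b = colSums(dpre),
      psi = dpsi,
      bpsi = dbpsi
    )
  )
}

# ---- LSTM (single direction; bidirectional = two passes) -----------------

nn_lstm_init <- function(cin, h) {
  sd_x <- sqrt(1 / cin)
  sd_h <- sqrt(1 / h)
  b <- numeric(4 * h)
  b[(h + 1):(2 * h)] <- 1 # forget-gate bias starts open
  list(
    Wx = matrix(rnorm(cin * 4 * h, 0, sd_x), cin, 4 * h),
    Wh = matrix(rnorm(h * 4 * h, 0, sd_h), h, 4 * h),
    b = b
  )
}

sigmoid <- function(x) 1 / (1 + exp(-x))

nn_lstm_fwd <- function(X, p, B, L, reverse = FALSE) {
  h_dim <- ncol(p$Wh)
  h <- h_dim %/% 4L
  G <- X %*% p$Wx # input contribution for every position at once
  order_t <- if (reverse) rev(seq_len(L)) else seq_len(L)
  rows0 <- L * (0:(B - 1L))
  Hout <- matrix(0, nrow(X), h)
  hs <- matrix(0, B, h)
  cs <- matrix(0, B, h)
  cache <- vector("list", L)
  for (step in seq_len(L)) {
    t <- order_t[step]
    rows <- rows0 + t
    A <- add_bias(G[rows, , drop = FALSE] + hs %*% p$Wh, p$b)
    i <- sigmoid(A[, 1:h, drop = FALSE])
    f <- sigmoid(A[, (h + 1):(2 * h), drop = FALSE])
    g <- tanh(A[, (2 * h + 1):(3 * h), drop = FALSE])
    o <- sigmoid(A[, (3 * h + 1):(4 * h), drop = FALSE])
    c_prev <- cs
    h_prev <- hs
    cs <- f * c_prev + i * g
    tc <- tanh(cs)
    hs <- o * tc
    Hout[rows, ] <- hs
    cache[[step]] <- list(
      rows = rows, i = i, f = f, g = g, o = o,
      c_prev = c_prev, h_prev = h_prev, tc = tc
    )
  }
  list(out = Hout, cache = list(steps = cache, B = B, L = L, h = h))
}

nn_lstm_bwd <- function(dH, X, p, cache) {
  B <- cache$B
  L <- cache$L
  h <- cache$h
  dWx <- matrix(0, nrow(p$Wx), ncol(p$Wx))
  dWh <- matrix(0, nrow(p$Wh), ncol(p$Wh))
  db <- numeric(length(p$b))
  dX <- matrix(0, nrow(X), ncol(X))
  dh_next <- matrix(0, B, h)
  dc_next <- matrix(0, B, h)
  for (step in rev(seq_len(L))) {
    st <- cache$steps[[step]]
    dh <- dH[st$rows, , drop = FALSE] + dh_next
    do <- dh * st$tc
    dc <- dc_next + dh * st$o * (1 - st$tc^2)
    di <- dc * st$g
    df <- dc * st$c_prev
    dg <- dc * st$i
    dc_next <- dc * st$f
    dA <- cbind(
      di * st$i * (1 - st$i),
      df * st$f * (1 - st$f),
      dg * (1 - st$g^2),
      do * st$o * (1 - st$o)
    )
    dWx <- dWx + crossprod(X[st$rows, , drop = FALSE], dA)
    dWh <- dWh + crossprod(st$h_prev, dA)
    db <- db + colSums(dA)
    dh_next <- tcrossprod(dA, p$Wh)
    dX[st$rows, ] <- tcrossprod(dA, p$Wx)
  }
  list(dX = dX, grads = list(Wx = dWx, Wh = dWh, b = db))
}

# ---- Adam optimiser over nested parameter lists --------------------------

nn_adam_init <- function(params) {
  zero <- function(x) {
    if (is.list(x)) lapply(x, zero) else x * 0
  }
  list(m = zero(params), v = zero(params), t = 0L)
}

nn_adam_step <- function(params, grads, opt, lr,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p
      out_m <- m
      out_v <- v
      for (i in seq_along(p)) {
        if (i > length(g) || is.null(g[[i]])) {
          stop("missing gradient for parameter element ", i, call. = FALSE)
        }
        r <- rec(p[[i]], g[[i]], m[[i]], v[[i]])
        out_p[[i]] <- r[[1]]
        out_m[[i]] <- r[[2]]
        out_v[[i]] <- r[[3]]
      }
      list(out_p, out_m, out_v)
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
      list(p, m, v)
    }
  }
  r <- rec(params, grads, opt$m, opt$v)
  list(params = r[[1]], opt = list(m = r[[2]], v = r[[3]], t = opt$t))
}

nn_param_count <- function(params) {
  if (is.list(params)) {
    sum(vapply(params, nn_param_count, numeric(1)))
  } else {
    length(params)
  }
}
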