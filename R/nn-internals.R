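# Minimal neural-network machinery with analytic gradients.
#
# Images are numeric arrays [H, W, C]; batches are 4-D arrays [H, W, C, N].
# Flattened feature rows use R's native column-major vectorization of a
# single image, so `flatten` of [H, W, C, N] yields an N x (H*W*C) matrix
# whose row n is as.vector(X[,,,n]).
#
# Every layer is a list(type, name, params = list(...)) plus static shape
# info. `layer_forward` returns list(out, cache); `layer_backward` takes the
# cache and upstream gradient and returns list(dx, grads). Gradients are
# verified against finite differences in the test suite.

with_seed_ <- function(seed, code) {
  withr::with_seed(as.integer(seed), code,
                   .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion",
                   .rng_sample_kind = "Rejection")
}

# small uniform init in +/- 1/sqrt(fan_in); draws from the current RNG
init_uniform <- function(dim, fan_in) {
  lim <- 1 / sqrt(max(fan_in, 1))
  array(stats::runif(prod(dim), -lim, lim), dim = dim)
}

# ---- convolution (3x3 or 1x1, stride 1) ------------------------------------
# The hot path lives in src/conv.cpp (im2col + BLAS); weight rows are
# ordered (di, dj, channel) with di fastest.

conv_plan <- function(H, W, C, k, pad) {
  list(H = H, W = W, C = C, k = k, pad = pad,
       outH = H + 2L * pad - k + 1L, outW = W + 2L * pad - k + 1L)
}

conv_forward <- function(layer, X) {
  plan <- layer$plan
  fw <- conv_fwd_cpp(X, dim(X), layer$params$W, layer$params$b,
                     plan$k, plan$pad)
  list(out = fw$out, cache = list(cols = fw$cols, dimX = dim(X)))
}

conv_backward <- function(layer, cache, dout) {
  plan <- layer$plan
  bw <- conv_bwd_cpp(cache$cols, cache$dimX, layer$params$W, dout,
                     plan$k, plan$pad)
  list(dx = bw$dx, grads = list(W = bw$dW, b = as.numeric(bw$db)))
}

# ---- relu / maxpool / flatten ----------------------------------------------

relu_forward <- function(X) {
  list(out = relu_fwd_cpp(X), cache = list(X = X))
}

relu_backward <- function(cache, dout) {
  relu_bwd_cpp(cache$X, dout)
}

maxpool_forward <- function(X) {
  fw <- maxpool_fwd_cpp(X, dim(X))
  list(out = fw$out, cache = list(which = fw$which, dimX = dim(X)))
}

maxpool_backward <- function(cache, dout) {
  maxpool_bwd_cpp(cache$which, dout, cache$dimX)
}

flatten_forward <- function(X) {
  d <- dim(X)
  n <- prod(d[1:3])
  list(out = t(matrix(X, nrow = n, ncol = d[4])),
       cache = list(dimX = d))
}

flatten_backward <- function(cache, dout) {
  array(t(dout), dim = cache$dimX)
}

# ---- batched bilinear layer -------------------------------------------------
# params: b (m), W (m x n), F (k x n x m). Row x of the input matrix maps to
# y_j = b_j + W[j,] . x + || F[,,j] x ||^2.

bilinear_batch_forward <- function(layer, X) {
  p <- layer$params
  m <- length(p$b)
  k <- dim(p$F)[1]
  Y <- X %*% t(p$W)
  FX <- vector("list", m)
  for (j in seq_len(m)) {
    Fj <- matrix(p$F[, , j], nrow = k)
    fx <- X %*% t(Fj)
    FX[[j]] <- fx
    Y[, j] <- Y[, j] + rowSums(fx * fx)
  }
  Y <- sweep(Y, 2, p$b, "+")
  list(out = Y, cache = list(X = X, FX = FX))
}

bilinear_batch_backward <- function(layer, cache, dout) {
  p <- layer$params
  m <- length(p$b)
  X <- cache$X
  dX <- dout %*% p$W
  dW <- crossprod(dout, X)                     # m x n
  db <- colSums(dout)
  dF <- array(0, dim = dim(p$F))
  for (j in seq_len(m)) {
    g <- dout[, j]
    FXg <- cache$FX[[j]] * g                   # N x k
    dX <- dX + 2 * (FXg %*% matrix(p$F[, , j], nrow = dim(p$F)[1]))
    dF[, , j] <- 2 * crossprod(FXg, X)
  }
  list(dx = dX, grads = list(b = db, W = dW, F = dF))
}

# ---- batched attention gate -------------------------------------------------
# params: w (m). Row f: e = w * f; a = softmax(e); r = a * f.

attention_batch_forward <- function(layer, X) {
  w <- layer$params$w
  S <- sweep(X, 2, w, "*")
  S <- S - apply(S, 1, max)                    # row-wise stabilization
  E <- exp(S)
  A <- E / rowSums(E)
  list(out = A * X, cache = list(X = X, A = A))
}

attention_batch_backward <- function(layer, cache, dout) {
  w <- layer$params$w
  A <- cache$A
  X <- cache$X
  g <- dout * X * A                            # dL/ds_i before coupling
  dS <- g - A * rowSums(g)
  dX <- dout * A + sweep(dS, 2, w, "*")
  dw <- colSums(dS * X)
  list(dx = dX, grads = list(w = dw))
}

# ---- dense ------------------------------------------------------------------

dense_forward <- function(layer, X) {
  out <- sweep(X %*% layer$params$W, 2, layer$params$b, "+")
  list(out = out, cache = list(X = X))
}

dense_backward <- function(layer, cache, dout) {
  list(dx = dout %*% t(layer$params$W),
       grads = list(W = crossprod(cache$X, dout), b = colSums(dout)))
}

# ---- softmax + cross-entropy ------------------------------------------------

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# labels: 1-based integer vector
softmax_ce <- function(logits, labels) {
  P <- softmax_rows(logits)
  N <- nrow(P)
  picked <- P[cbind(seq_len(N), labels)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dZ <- P
  dZ[cbind(seq_len(N), labels)] <- dZ[cbind(seq_len(N), labels)] - 1
  list(loss = loss, probs = P, dlogits = dZ / N)
}

# ---- generic layer dispatch -------------------------------------------------

layer_forward <- function(layer, X) {
  switch(layer$type,
         conv = conv_forward(layer, X),
         relu = relu_forward(X),
         pool = maxpool_forward(X),
         flatten = flatten_forward(X),
         bilinear = bilinear_batch_forward(layer, X),
         attention = attention_batch_forward(layer, X),
         dense = dense_forward(layer, X),
         stop("unknown layer type: ", layer$type))
}

layer_backward <- function(layer, cache, dout) {
  switch(layer$type,
         conv = conv_backward(layer, cache, dout),
         relu = list(dx = relu_backward(cache, dout), grads = NULL),
         pool = list(dx = maxpool_backward(cache, dout), grads = NULL),
         flatten = list(dx = flatten_backward(cache, dout), grads = NULL),
         bilinear = bilinear_batch_backward(layer, cache, dout),
         attention = attention_batch_backward(layer, cache, dout),
         dense = dense_backward(layer, cache, dout),
         stop("unknown layer type: ", layer$type))
}

# forward through all layers; returns logits and per-layer caches/outputs
network_forward <- function(layers, X, keep = FALSE) {
  caches <- vector("list", length(layers))
  outs <- if (keep) vector("list", length(layers)) else NULL
  for (i in seq_along(layers)) {
    fw <- layer_forward(layers[[i]], X)
    X <- fw$out
    caches[[i]] <- fw$cache
    if (keep) outs[[i]] <- X
  }
  list(logits = X, caches = caches, outs = outs)
}

# backward from dlogits; if stop_at is given (layer index), returns the
# gradient w.r.t. that layer's OUTPUT and skips parameter grads below it
network_backward <- function(layers, caches, dlogits, stop_at = 0L) {
  grads <- vector("list", length(layers))
  dout <- dlogits
  for (i in rev(seq_along(layers))) {
    if (i == stop_at) {
      return(list(grads = grads, dact = dout))
    }
    bk <- layer_backward(layers[[i]], caches[[i]], dout)
    grads[i] <- list(bk$grads)
    dout <- bk$dx
  }
  list(grads = grads, dact = dout)
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(l) {
    if (is.null(l$params)) return(NULL)
    lapply(l$params, function(p) list(m = array(0, dim = dim(p) %||% length(p)),
                                      v = array(0, dim = dim(p) %||% length(p))))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(layers, grads, state, lr, beta1, beta2, eps, wd, t) {
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (nm in names(g)) {
      p <- layers[[i]]$params[[nm]]
      gr <- g[[nm]] + wd * p
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * gr
      st$v <- beta2 * st$v + (1 - beta2) * gr * gr
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      layers[[i]]$params[[nm]] <- p - lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[nm]] <- st
    }
  }
  list(layers = layers, state = state)
}
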