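# Finite-difference verification of the analytic gradients of every
# differentiable layer, on small instances.

test_that("bilinear layer gradients match finite differences", {
  set.seed(31)
  N <- 3; n <- 5; m <- 4; k <- 2
  layer <- list(type = "bilinear", name = "bl",
                params = list(b = runif(m, -0.5, 0.5),
                              W = matrix(runif(m * n, -1, 1), m, n),
                              F = array(runif(k * n * m, -1, 1), c(k, n, m))))
  X <- matrix(runif(N * n, -1, 1), N, n)
  D <- matrix(runif(N * m, -1, 1), N, m)   # arbitrary upstream gradient
  loss <- function(l, x) sum(D * tg_ns$bilinear_batch_forward(l, x)$out)
  fw <- tg_ns$bilinear_batch_forward(layer, X)
  bk <- tg_ns$bilinear_batch_backward(layer, fw$cache, D)
  for (nm in names(layer$params)) {
    f <- function(v) {
      l <- layer; l$params[[nm]][] <- v
      loss(l, X)
    }
    num <- numeric_gradient(f, as.vector(layer$params[[nm]]))
    expect_lt(max(rel_err(num, as.vector(bk$grads[[nm]]))), 1e-4)
  }
  fx <- function(v) loss(layer, matrix(v, N, n))
  num_x <- numeric_gradient(fx, as.vector(X))
  expect_lt(max(rel_err(num_x, as.vector(bk$dx))), 1e-4)
})

test_that("attention gate gradients match finite differences", {
  set.seed(37)
  N <- 3; m <- 6
  layer <- list(type = "attention", name = "att",
                params = list(w = runif(m, -1, 1)))
  X <- matrix(runif(N * m, -1, 1), N, m)
  D <- matrix(runif(N * m, -1, 1), N, m)
  loss <- function(l, x) sum(D * tg_ns$attention_batch_forward(l, x)$out)
  fw <- tg_ns$attention_batch_forward(layer, X)
  bk <- tg_ns$attention_batch_backward(layer, fw$cache, D)
  num_w <- numeric_gradient(function(v) {
    l <- layer; l$params$w[] <- v; loss(l, X)
  }, layer$params$w)
  expect_lt(max(rel_err(num_w, bk$grads$w)), 1e-4)
  num_x <- numeric_gradient(function(v) loss(layer, matrix(v, N, m)),
                            as.vector(X))
  expect_lt(max(rel_err(num_x, as.vector(bk$dx))), 1e-4)
})

test_that("batched attention forward agrees with the pure gate", {
  set.seed(41)
  m <- 7
  w <- runif(m, -1, 1)
  X <- matrix(runif(3 * m, -1, 1), 3, m)
  layer <- list(type = "attention", params = list(w = w))
  out <- tg_ns$attention_batch_forward(layer, X)$out
  for (i in 1:3) expect_equal(out[i, ], attention_gate(X[i, ], w), tolerance = 1e-12)
})

test_that("batched bilinear forward agrees with the per-node reference ops", {
  set.seed(43)
  n <- 6; m <- 3; k <- 2
  layer <- list(type = "bilinear",
                params = list(b = runif(m), W = matrix(runif(m * n), m, n),
                              F = array(runif(k * n * m), c(k, n, m))))
  X <- matrix(runif(2 * n, -1, 1), 2, n)
  out <- tg_ns$bilinear_batch_forward(layer, X)$out
  for (i in 1:2) {
    for (j in 1:m) {
      node <- bilinear_node(layer$params$b[j], layer$params$W[j, ],
                            matrix(layer$params$F[, , j], k, n))
      expect_equal(out[i, j], bilinear_response_bruteforce(X[i, ], node),
                   tolerance = 1e-9)
    }
  }
})

test_that("whole-network parameter gradients match finite differences", {
  set.seed(47)
  model <- tiny_model(n_classes = 3, size = 16, seed = 2)
  X <- array(runif(16 * 16 * 3 * 2), dim = c(16, 16, 3, 2))
  y <- c(1L, 3L)
  loss_of <- function(layers) {
    fw <- tg_ns$network_forward(layers, X)
    tg_ns$softmax_ce(fw$logits, y)$loss
  }
  fw <- tg_ns$network_forward(model$layers, X)
  ce <- tg_ns$softmax_ce(fw$logits, y)
  bk <- tg_ns$network_backward(model$layers, fw$caches, ce$dlogits)
  eps <- 1e-5
  errs <- c()
  for (li in seq_along(model$layers)) {
    g <- bk$grads[[li]]
    if (is.null(g)) next
    for (nm in names(g)) {
      p <- model$layers[[li]]$params[[nm]]
      idx <- sample(length(p), min(length(p), 5))
      for (ii in idx) {
        lp <- model$layers; lp[[li]]$params[[nm]][ii] <- p[ii] + eps
        lm <- model$layers; lm[[li]]$params[[nm]][ii] <- p[ii] - eps
        num <- (loss_of(lp) - loss_of(lm)) / (2 * eps)
        errs <- c(errs, rel_err(num, g[[nm]][ii]))
      }
    }
  }
  # ReLU kinks and max-pool argmax switches make a few finite differences
  # unreliable; the bulk of sampled entries must agree tightly
  expect_lt(median(errs), 1e-6)
  expect_lt(unname(quantile(errs, 0.9)), 1e-4)
})

test_that("softmax cross-entropy probabilities and gradient are consistent", {
  set.seed(53)
  Z <- matrix(rnorm(4 * 3, sd = 2), 4, 3)
  y <- c(1L, 2L, 3L, 1L)
  ce <- tg_ns$softmax_ce(Z, y)
  expect_equal(rowSums(ce$probs), rep(1, 4), tolerance = 1e-9)
  num <- numeric_gradient(function(v) tg_ns$softmax_ce(matrix(v, 4, 3), y)$loss,
                          as.vector(Z))
  expect_lt(max(abs(num - as.vector(ce$dlogits))), 1e-6)
})
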