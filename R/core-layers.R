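# ---- validation helpers -----------------------------------------------------

check_finite_vector <- function(x, arg) {
  if (!is.numeric(x) || length(x) < 1L) {
    stop(sprintf("`%s` must be a numeric vector of length >= 1", arg), call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  }
  invisible(x)
}

check_same_length <- function(a, b, arg_a, arg_b) {
  if (length(a) != length(b)) {
    stop(sprintf("dimension mismatch: length(%s) = %d but length(%s) = %d",
                 arg_a, length(a), arg_b, length(b)), call. = FALSE)
  }
  invisible(NULL)
}

# ---- bilinear node ----------------------------------------------------------

#' Parameters of a single bilinear output node
#'
#' A bilinear node extends the affine response `b + w'x` with a factorized
#' second-order interaction term `x' F'F x`, where `F` is a `k x n` factor
#' matrix. The interaction couples every pair of input features through the
#' inner products of the corresponding columns of `F`, at a parameter cost of
#' `k * n` instead of `n^2`.
#'
#' @param bias Scalar bias `b`.
#' @param linear_weight Numeric vector `w` of length `n` (first-order weights).
#' @param factor_matrix Numeric `k x n` matrix `F`; `k` is the number of
#'   interaction factors.
#' @return An object of class `bilinear_node` (a validated list).
#' @examples
#' p <- bilinear_node(bias = 1, linear_weight = c(1, 1),
#'                    factor_matrix = matrix(c(1, 1), nrow = 1))
#' bilinear_response(c(1, 2), p)
#' @export
bilinear_node <- function(bias, linear_weight, factor_matrix) {
  if (!is.numeric(bias) || length(bias) != 1L || !is.finite(bias)) {
    stop("`bias` must be a finite scalar", call. = FALSE)
  }
  check_finite_vector(linear_weight, "linear_weight")
  if (!is.matrix(factor_matrix) || !is.numeric(factor_matrix)) {
    stop("`factor_matrix` must be a numeric matrix", call. = FALSE)
  }
  if (!all(is.finite(factor_matrix))) {
    stop("`factor_matrix` contains non-finite values", call. = FALSE)
  }
  if (ncol(factor_matrix) != length(linear_weight)) {
    stop(sprintf(
      "dimension mismatch: factor_matrix has %d columns but linear_weight has length %d",
      ncol(factor_matrix), length(linear_weight)), call. = FALSE)
  }
  structure(
    list(bias = as.numeric(bias),
         linear_weight = as.numeric(linear_weight),
         factor_matrix = factor_matrix,
         n_factors = nrow(factor_matrix)),
    class = "bilinear_node")
}

#' Affine (first-order) response
#'
#' Computes `b + w'x`, the plain linear node that the bilinear node reduces to
#' when its factor matrix is zero.
#'
#' @param x Numeric input feature vector.
#' @param w Numeric weight vector, same length as `x`.
#' @param b Scalar bias.
#' @return A single numeric value.
#' @export
linear_response <- function(x, w, b) {
  check_finite_vector(x, "x")
  check_finite_vector(w, "w")
  check_same_length(x, w, "x", "w")
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b)) {
    stop("`b` must be a finite scalar", call. = FALSE)
  }
  as.numeric(b + sum(w * x))
}

#' Bilinear node response (efficient form)
#'
#' Computes `b + w'x + x'F'Fx`. The interaction term is evaluated as
#' `||Fx||^2`, which costs `O(nk)` instead of the `O(n^2 k)` double sum over
#' column inner products; the two forms are algebraically identical and
#' [bilinear_response_bruteforce()] provides the double-sum evaluation as an
#' independent check. The interaction term is a squared norm and therefore
#' never negative.
#'
#' @param x Numeric input feature vector of length `n`.
#' @param p A [bilinear_node()] with matching input dimension.
#' @return A single numeric value.
#' @seealso [bilinear_response_bruteforce()]
#' @export
bilinear_response <- function(x, p) {
  stopifnot(inherits(p, "bilinear_node"))
  check_finite_vector(x, "x")
  check_same_length(x, p$linear_weight, "x", "p$linear_weight")
  fx <- as.numeric(p$factor_matrix %*% x)
  as.numeric(p$bias + sum(p$linear_weight * x) + sum(fx * fx))
}

#' Bilinear node response (double-sum reference form)
#'
#' Evaluates the bilinear node as the explicit expansion
#' `b + sum_i w_i x_i + sum_i sum_j <f_i, f_j> x_i x_j`, where `f_i` is the
#' i-th column of the factor matrix. This is the `O(n^2 k)` textbook form,
#' retained as an independent oracle for [bilinear_response()]; it is not used
#' on any computational path.
#'
#' @inheritParams bilinear_response
#' @return A single numeric value.
#' @export
bilinear_response_bruteforce <- function(x, p) {
  stopifnot(inherits(p, "bilinear_node"))
  check_finite_vector(x, "x")
  check_same_length(x, p$linear_weight, "x", "p$linear_weight")
  n <- length(x)
  y <- p$bias
  for (i in seq_len(n)) y <- y + p$linear_weight[i] * x[i]
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      y <- y + sum(p$factor_matrix[, i] * p$factor_matrix[, j]) * x[i] * x[j]
    }
  }
  as.numeric(y)
}

#' A stack of bilinear nodes sharing one input
#'
#' Bundles `m` bilinear nodes with a common input dimension `n` into a layer
#' that maps a feature vector to an m-dimensional "bilinear vector".
#'
#' @param nodes A list of [bilinear_node()] objects with identical input
#'   dimension.
#' @return An object of class `bilinear_layer`.
#' @export
bilinear_layer <- function(nodes) {
  if (!is.list(nodes) || length(nodes) < 1L) {
    stop("`nodes` must be a non-empty list of bilinear_node objects", call. = FALSE)
  }
  if (!all(vapply(nodes, inherits, logical(1), "bilinear_node"))) {
    stop("every element of `nodes` must be a bilinear_node", call. = FALSE)
  }
  n <- length(nodes[[1]]$linear_weight)
  dims <- vapply(nodes, function(p) length(p$linear_weight), integer(1))
  if (!all(dims == n)) {
    stop("all nodes must share the same input dimension", call. = FALSE)
  }
  structure(list(nodes = nodes, n_in = n, n_out = length(nodes)),
            class = "bilinear_layer")
}

#' Forward pass through a bilinear layer
#'
#' @param x Numeric input feature vector.
#' @param layer A [bilinear_layer()].
#' @return Numeric vector of length `m` (one bilinear response per node).
#' @export
bilinear_layer_forward <- function(x, layer) {
  stopifnot(inherits(layer, "bilinear_layer"))
  check_finite_vector(x, "x")
  if (length(x) != layer$n_in) {
    stop(sprintf("dimension mismatch: layer expects n = %d, got %d",
                 layer$n_in, length(x)), call. = FALSE)
  }
  vapply(layer$nodes, function(p) bilinear_response(x, p), numeric(1))
}

# ---- soft attention ---------------------------------------------------------

#' Per-element attention scores
#'
#' Given a feature vector `f` and a learnable attention weight vector `w` of
#' the same length, returns the elementwise products `e_i = w_i * f_i`. Their
#' sum is the scalar score of the attention formulation; the per-element
#' values are what the softmax normalizes.
#'
#' @param f Numeric feature vector.
#' @param weight Numeric attention weight vector, same length as `f`.
#' @return Numeric vector of scores `e`.
#' @export
attention_scores <- function(f, weight) {
  check_finite_vector(f, "f")
  check_finite_vector(weight, "weight")
  check_same_length(f, weight, "f", "weight")
  as.numeric(weight * f)
}

#' Softmax-normalized attention weights
#'
#' `a_i = exp(e_i) / sum_j exp(e_j)`, computed with the usual max-subtraction
#' stabilization so that large scores do not overflow. The result is a proper
#' weighting: strictly positive, summing to one, and invariant to adding a
#' constant to all scores.
#'
#' @param e Numeric score vector (finite, length >= 1).
#' @return Numeric vector of attention weights summing to 1.
#' @export
attention_weights <- function(e) {
  check_finite_vector(e, "e")
  z <- exp(e - max(e))
  z / sum(z)
}

#' Attention-pooled scalar feature
#'
#' The scalar reduction `c = sum_i a_i f_i`: the attention-weighted sum of the
#' feature vector. Kept as the literal reference form of soft-attention
#' pooling; the classifier itself uses the dimension-preserving
#' [attention_gate()], whose elementwise products sum to exactly this value.
#'
#' @param a Attention weight vector (entries in (0,1), summing to 1).
#' @param f Feature vector, same length as `a`.
#' @return A single numeric value.
#' @export
attention_pool <- function(a, f) {
  check_finite_vector(a, "a")
  check_finite_vector(f, "f")
  check_same_length(a, f, "a", "f")
  if (abs(sum(a) - 1) > 1e-6 || any(a < 0)) {
    stop("`a` must be a valid attention vector (non-negative, summing to 1)",
         call. = FALSE)
  }
  as.numeric(sum(a * f))
}

#' Attention gate (dimension-preserving soft attention)
#'
#' Computes `r_i = a_i * f_i` with `a = softmax(w * f)`: the feature vector
#' multiplied elementwise by its own softmax attention weights. This is the
#' form used inside the classifier head, since it preserves dimensionality and
#' can feed a dense softmax layer; `sum(r)` equals the scalar
#' [attention_pool()] of the same features.
#'
#' @inheritParams attention_scores
#' @return Numeric vector `r`, same length as `f`.
#' @export
attention_gate <- function(f, weight) {
  e <- attention_scores(f, weight)
  a <- attention_weights(e)
  as.numeric(a * f)
}
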