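# Fully connected multi-layer perceptron: y_j = sigma(sum_i x_i W_ji + b_j)
# layer by layer, with a linear last layer (regression under normality).
# Forward/backward passes live here in plain matrix arithmetic; the heavy
# training loops run in the compiled trainer (src/mlp.cpp), and the two
# routes are cross-checked in the test suite.

#' Specify an MLP architecture
#'
#' @param input_dim number of input features.
#' @param hidden integer vector of hidden-layer widths.
#' @param output_dim output dimension (last layer is linear).
#' @param activation hidden activation, `"relu"` or `"tanh"`.
#' @return object of class `mlp_spec`.
#' @export
mlp_spec <- function(input_dim, hidden = c(32, 32), output_dim = 1,
                     activation = c("relu", "tanh")) {
  activation <- match.arg(activation)
  structure(list(input_dim = as.integer(input_dim),
                 hidden = as.integer(hidden),
                 output_dim = as.integer(output_dim),
                 activation = activation),
            class = "mlp_spec")
}

#' Initialise MLP weights
#'
#' He initialisation for ReLU, Glorot for tanh; biases start at zero.
#'
#' @param spec an [mlp_spec()].
#' @param seed RNG seed.
#' @return object of class `ecopinn_mlp`: the architecture plus weight matrices
#'   `W` (input-dim x output-dim per layer) and bias vectors `b`.
#' @export
mlp_init <- function(spec, seed = NULL) {
  dims <- c(spec$input_dim, spec$hidden, spec$output_dim)
  with_seed(seed, {
    W <- list(); b <- list()
    for (l in seq_len(length(dims) - 1)) {
      fan_in <- dims[l]
      sd0 <- if (spec$activation == "relu") sqrt(2 / fan_in)
             else sqrt(1 / fan_in)
      W[[l]] <- matrix(rnorm(dims[l] * dims[l + 1], 0, sd0), dims[l], dims[l + 1])
      b[[l]] <- rep(0, dims[l + 1])
    }
    structure(list(spec = spec, W = W, b = b), class = "ecopinn_mlp")
  })
}

act_fun <- function(z, activation) {
  if (activation == "relu") pmax(z, 0) else tanh(z)
}

act_grad <- function(z, activation) {
  if (activation == "relu") (z > 0) * 1 else 1 - tanh(z)^2
}

#' MLP forward pass
#'
#' @param net an [mlp_init()] network.
#' @param x input vector (one sample) or matrix (rows = samples).
#' @return output matrix (n x output_dim); a plain vector when
#'   `output_dim` is 1 and `x` was a vector.
#' @examples
#' net <- mlp_init(mlp_spec(2, hidden = 4), seed = 1)
#' mlp_forward(net, c(0.5, -1))
#' @export
mlp_forward <- function(net, x) {
  vec_in <- is.null(dim(x))
  X <- if (vec_in) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(X) != net$spec$input_dim)
    abort(sprintf("input has %d columns; spec expects %d",
                  ncol(X), net$spec$input_dim))
  out <- mlp_forward_full(net, X)$A[[length(net$W)]]
  if (vec_in && net$spec$output_dim == 1L) as.numeric(out) else out
}

# forward pass keeping pre-activations Z and activations A per layer
mlp_forward_full <- function(net, X) {
  L <- length(net$W)
  Z <- vector("list", L); A <- vector("list", L)
  input <- X
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(input %*% net$W[[l]], 2, net$b[[l]], "+")
    A[[l]] <- if (l < L) act_fun(Z[[l]], net$spec$activation) else Z[[l]]
    input <- A[[l]]
  }
  list(Z = Z, A = A)
}

# Backward pass: grad_out is dL/d(output) (n x output_dim). Returns weight
# and bias gradients plus dL/d(input) for composing networks.
mlp_backward <- function(net, X, cache, grad_out) {
  L <- length(net$W)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- as.matrix(grad_out)
  for (l in L:1) {
    input <- if (l == 1) X else cache$A[[l - 1]]
    gW[[l]] <- crossprod(input, delta)
    gb[[l]] <- colSums(delta)
    delta <- (delta %*% t(net$W[[l]])) *
      (if (l > 1) act_grad(cache$Z[[l - 1]], net$spec$activation) else 1)
  }
  list(gW = gW, gb = gb, gX = delta)
}

#' Train an MLP by (minibatch) Adam
#'
#' Minimises `mean((pred + offset - y)^2) + lambda * mean((pred - y2)^2)`,
#' which covers the plain MSE objective (`offset = 0`, `lambda = 0`), the
#' parallel-physics residual objective (`offset` = process-model
#' predictions) and the physics-regularised objective (`y2` = process-model
#' predictions weighted by `lambda`). Deterministic for a fixed `seed`.
#'
#' @param net an [mlp_init()] network (single output).
#' @param X feature matrix (standardise upstream).
#' @param y target vector.
#' @param epochs number of passes.
#' @param lr Adam learning rate.
#' @param offset additive offset inside the data term (default 0).
#' @param lambda consistency weight in `[0, 1]`.
#' @param y2 consistency target (required when `lambda > 0`).
#' @param batch_size minibatch size; `Inf` (default) trains full-batch.
#' @param seed seed for minibatch shuffling.
#' @return the trained network, with the per-epoch loss curve attached as
#'   attribute `loss_curve`.
#' @export
train_mlp <- function(net, X, y, epochs, lr, offset = NULL, lambda = 0,
                      y2 = NULL, batch_size = Inf, seed = 1L) {
  X <- as.matrix(X); n <- nrow(X)
  if (length(y) != n) abort("length(y) must match nrow(X)")
  if (lambda < 0 || lambda > 1) abort("`lambda` must be in [0, 1]")
  if (is.null(offset)) offset <- rep(0, n)
  if (is.null(y2)) {
    if (lambda > 0) abort("`y2` is required when lambda > 0")
    y2 <- rep(0, n)
  }
  bs <- if (!is.finite(batch_size)) 0L else as.integer(batch_size)
  res <- mlp_train_cpp(X, y, offset, y2, lambda, net$W, net$b,
                       net$spec$activation, as.integer(epochs), lr, bs,
                       as.integer(seed), 0.9, 0.999, 1e-8)
  net$W <- res$W
  net$b <- lapply(res$b, as.numeric)
  attr(net, "loss_curve") <- res$loss_curve
  net
}

# --- Adam in R (used by the embedding training loop) -----------------------

adam_new <- function(shapes) {
  list(m = lapply(shapes, function(s) array(0, dim = s)),
       v = lapply(shapes, function(s) array(0, dim = s)),
       t = 0L)
}

adam_update <- function(state, params, grads, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * grads[[i]]
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * grads[[i]]^2
    params[[i]] <- params[[i]] -
      lr * (state$m[[i]] / bc1) / (sqrt(state$v[[i]] / bc2) + eps)
  }
  list(state = state, params = params)
}
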