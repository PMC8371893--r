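# Shared single-hidden-layer network machinery for the wavelet network and
# the sigmoid (BP) baseline. Both use the same min-max normalization,
# initialization, per-sample gradient updates, and stopping rule; only the
# hidden activation (and whether the scale parameters are trained) differs.

# --- min-max normalization ------------------------------------------------

minmax_fit <- function(m) {
  m <- as.matrix(m)
  lo <- apply(m, 2, min)
  hi <- apply(m, 2, max)
  span <- hi - lo
  span[span == 0] <- 1  # constant column: map to 0
  list(lo = lo, span = span)
}

minmax_apply <- function(m, tr) {
  sweep(sweep(as.matrix(m), 2, tr$lo, "-"), 2, tr$span, "/")
}

minmax_invert <- function(m, tr) {
  sweep(sweep(as.matrix(m), 2, tr$span, "*"), 2, tr$lo, "+")
}

# --- activations ----------------------------------------------------------

#' Wavelet activation functions
#'
#' The mother wavelets available as hidden activations. The default Morlet
#' wavelet is psi(t) = cos(1.75 t) exp(-t^2 / 2); the Mexican-hat
#' alternative is (1 - t^2) exp(-t^2 / 2). Both are even functions with
#' psi(0) = 1.
#'
#' @param t numeric vector (unitless hidden pre-activation).
#' @param wavelet `"morlet"` (default) or `"mexican_hat"`.
#' @return psi(t).
#' @export
wavelet_activation <- function(t, wavelet = c("morlet", "mexican_hat")) {
  wavelet <- match.arg(wavelet)
  if (wavelet == "morlet") {
    cos(1.75 * t) * exp(-t^2 / 2)
  } else {
    (1 - t^2) * exp(-t^2 / 2)
  }
}

#' Derivative of the wavelet activation
#'
#' Analytic psi'(t) for the activations of [wavelet_activation()]; used by
#' the gradient-descent trainer.
#'
#' @inheritParams wavelet_activation
#' @return psi'(t).
#' @export
wavelet_activation_deriv <- function(t, wavelet = c("morlet", "mexican_hat")) {
  wavelet <- match.arg(wavelet)
  e <- exp(-t^2 / 2)
  if (wavelet == "morlet") {
    (-1.75 * sin(1.75 * t) - t * cos(1.75 * t)) * e
  } else {
    (t^3 - 3 * t) * e
  }
}

act_funs <- function(activation) {
  if (activation == "sigmoid") {
    list(f = stats::plogis,
         df = function(t) stats::plogis(t) * (1 - stats::plogis(t)),
         train_scale = FALSE)
  } else {
    list(f = function(t) wavelet_activation(t, activation),
         df = function(t) wavelet_activation_deriv(t, activation),
         train_scale = activation != "sigmoid")
  }
}

# --- forward pass ---------------------------------------------------------

net_forward_norm <- function(net, Xn) {
  Xn <- as.matrix(Xn)
  pre <- Xn %*% t(net$W)                       # n x nh
  tt <- sweep(sweep(pre, 2, net$b, "-"), 2, net$a, "/")
  H <- act_funs(net$activation)$f(tt)
  drop(H %*% net$v) + net$c
}

#' Forward pass of a trained network on normalized inputs
#'
#' Evaluates y-hat = c + sum_j v_j psi((w_j . x - b_j) / a_j) on inputs
#' already in the normalized [0, 1] space. Mostly useful for inspecting the
#' network; use [predict()] for predictions in g/L.
#'
#' @param model a trained `wnn_model` or `bp_model`.
#' @param x a normalized input vector (length `n_input`) or matrix.
#' @return normalized prediction(s).
#' @export
net_forward <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != ncol(model$net$W))
    stop("dimension mismatch: expected ", ncol(model$net$W), " inputs",
         call. = FALSE)
  net_forward_norm(model$net, x)
}

# Gradient of the half-sum-of-squares loss L = 0.5 * sum((yhat - y)^2) over
# a batch, with respect to every parameter group. The per-sample training
# update is this gradient on a single-row batch.
net_gradients <- function(net, Xn, yn) {
  Xn <- as.matrix(Xn)
  af <- act_funs(net$activation)
  n <- nrow(Xn)
  pre <- Xn %*% t(net$W)
  tt <- sweep(sweep(pre, 2, net$b, "-"), 2, net$a, "/")
  H <- af$f(tt)
  e <- drop(H %*% net$v) + net$c - yn          # length n
  dH <- af$df(tt)
  Gt <- dH * (e %o% net$v)                     # n x nh : dL/dt
  list(
    W = (t(Gt) / net$a) %*% Xn,
    b = -colSums(Gt) / net$a,
    a = -colSums(Gt * tt) / net$a,
    v = drop(crossprod(H, e)),
    c = sum(e),
    loss = 0.5 * sum(e^2)
  )
}

net_init <- function(n_input, n_hidden, Xn, activation, a0 = 0.3) {
  W <- matrix(stats::runif(n_hidden * n_input, -0.5, 0.5), n_hidden, n_input)
  v <- stats::runif(n_hidden, -0.5, 0.5)
  a <- rep(if (activation == "sigmoid") 1 else a0, n_hidden)
  pre <- as.matrix(Xn) %*% t(W)
  lo <- apply(pre, 2, min)
  hi <- apply(pre, 2, max)
  b <- lo + (seq_len(n_hidden) - 0.5) / n_hidden * (hi - lo)
  list(W = W, v = v, a = a, b = b, c = 0, activation = activation)
}

# Core trainer. Per-sample (online) gradient descent on the half-squared
# error, fixed sample order, scale parameters floored at 1e-6; stops when
# the epoch-level MSE on normalized targets reaches `error_goal`.
net_train <- function(X, Y, n_hidden, activation, learning_rate = 0.01,
                      max_iterations = 1000, error_goal = 0.001, seed = 1,
                      a0 = 0.3) {
  X <- as.matrix(X)
  if (nrow(X) < 5) stop("need at least 5 samples to train", call. = FALSE)
  if (any(!is.finite(X)) || any(!is.finite(Y)))
    stop("features and targets must be finite", call. = FALSE)
  x_tr <- minmax_fit(X)
  y_tr <- minmax_fit(matrix(Y, ncol = 1))
  Xn <- minmax_apply(X, x_tr)
  dimnames(Xn) <- NULL
  yn <- drop(minmax_apply(matrix(Y, ncol = 1), y_tr))
  set.seed(seed)
  net <- net_init(ncol(X), n_hidden, Xn, activation, a0)
  train_scale <- act_funs(activation)$train_scale
  n <- nrow(Xn)
  errs <- numeric(0)
  stop_reason <- "max_iterations"
  for (it in seq_len(max_iterations)) {
    for (i in seq_len(n)) {
      g <- net_gradients(net, Xn[i, , drop = FALSE], yn[i])
      net$W <- net$W - learning_rate * g$W
      net$b <- net$b - learning_rate * g$b
      if (train_scale)
        net$a <- pmax(net$a - learning_rate * g$a, 1e-6)
      net$v <- net$v - learning_rate * g$v
      net$c <- net$c - learning_rate * g$c
    }
    mse <- mean((net_forward_norm(net, Xn) - yn)^2)
    if (!is.finite(mse))
      stop("divergence error at iteration ", it, call. = FALSE)
    errs <- c(errs, mse)
    if (mse <= error_goal) {
      stop_reason <- "goal_reached"
      break
    }
  }
  list(net = net, x_transform = x_tr, y_transform = y_tr,
       history = list(errors = errs, stop_reason = stop_reason),
       feature_names = colnames(X))
}

net_predict <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != ncol(model$net$W))
    stop("feature count mismatch: expected ", ncol(model$net$W),
         call. = FALSE)
  Xn <- minmax_apply(X, model$x_transform)
  yn <- net_forward_norm(model$net, Xn)
  drop(minmax_invert(matrix(yn, ncol = 1), model$y_transform))
}
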