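#' Random-forest baseline
#'
#' Random-forest regressor with the comparison study's tree count (1070),
#' bootstrap sampling, seeded. Delegates to \pkg{randomForest}. A
#' single-valued target yields a constant predictor with a warning.
#'
#' @param X feature matrix.
#' @param Y targets (g/L).
#' @param n_trees number of trees (default 1070).
#' @param seed integer RNG seed.
#' @return object of class `rf_model`.
#' @export
train_rf <- function(X, Y, n_trees = 1070, seed = 1) {
  X <- as.matrix(X)
  if (nrow(X) < 10) stop("need at least 10 samples", call. = FALSE)
  if (stats::sd(Y) == 0) {
    warning("degenerate single-value target: returning a constant predictor")
    return(structure(list(constant = Y[1], n_input = ncol(X)),
                     class = c("rf_model", "petiole_model")))
  }
  set.seed(seed)
  fit <- randomForest::randomForest(x = X, y = Y, ntree = n_trees)
  structure(list(fit = fit, n_input = ncol(X)),
            class = c("rf_model", "petiole_model"))
}

#' @rdname predict.wnn_model
#' @export
predict.rf_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_input)
    stop("feature count mismatch", call. = FALSE)
  if (!is.null(object$constant))
    return(rep(object$constant, nrow(newdata)))
  unname(stats::predict(object$fit, newdata))
}

#' Radial-basis-function network baseline
#'
#' Classical exact-interpolation RBF network: one Gaussian unit
#' exp(-||x - c||^2 / (2 spread^2)) centred at every (min-max normalized)
#' training point, with linear output weights solved by ridge-regularized
#' least squares (ridge 1e-8). The comparison study's kernel variance
#' parameter 0.3 is the Gaussian spread.
#'
#' @param X feature matrix.
#' @param Y targets (g/L).
#' @param spread Gaussian kernel width on normalized inputs (default 0.3).
#' @param ridge ridge regularization (default 1e-8).
#' @return object of class `rbf_model`.
#' @export
train_rbf <- function(X, Y, spread = 0.3, ridge = 1e-8) {
  X <- as.matrix(X)
  x_tr <- minmax_fit(X)
  C <- minmax_apply(X, x_tr)
  K <- rbf_kernel(C, C, spread)
  w <- tryCatch(solve(K + diag(ridge, nrow(K)), Y),
                error = function(e)
                  stop("singular RBF system after ridge", call. = FALSE))
  structure(list(centers = C, weights = drop(w), spread = spread,
                 x_transform = x_tr, n_input = ncol(X)),
            class = c("rbf_model", "petiole_model"))
}

rbf_kernel <- function(A, B, spread) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  exp(-pmax(d2, 0) / (2 * spread^2))
}

#' @rdname predict.wnn_model
#' @export
predict.rbf_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_input)
    stop("feature count mismatch", call. = FALSE)
  Xn <- minmax_apply(newdata, object$x_transform)
  drop(rbf_kernel(Xn, object$centers, object$spread) %*% object$weights)
}

#' Back-propagation network baseline
#'
#' Three-layer perceptron with sigmoid hidden activation and linear output,
#' trained through the same normalization, per-sample gradient-descent and
#' stopping code path as the wavelet network -- only the activation (and the
#' absence of trainable scale parameters) differs.
#'
#' @param X feature matrix.
#' @param Y targets (g/L).
#' @param n_hidden hidden nodes (default 10).
#' @param cfg a [train_config()] (learning rate 0.01, 1000 iterations).
#' @return object of class `bp_model`.
#' @export
train_bp <- function(X, Y, n_hidden = 10, cfg = train_config()) {
  fit <- net_train(X, Y, n_hidden, "sigmoid",
                   learning_rate = cfg$learning_rate,
                   max_iterations = cfg$max_iterations,
                   error_goal = cfg$error_goal, seed = cfg$seed)
  structure(c(fit, list(n_hidden = n_hidden, cfg = cfg)),
            class = c("bp_model", "petiole_model"))
}

#' @rdname predict.wnn_model
#' @export
predict.bp_model <- function(object, newdata, ...) {
  net_predict(object, newdata)
}
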