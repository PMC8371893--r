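#' Training configuration
#'
#' Hyperparameters shared by the wavelet network and the BP baseline:
#' learning rate 0.01, at most 1000 iterations (epochs), and an error goal
#' of 0.001 interpreted as the mean squared error on min-max normalized
#' targets.
#'
#' @param learning_rate positive step size (default 0.01).
#' @param max_iterations maximum training epochs (default 1000).
#' @param error_goal stopping MSE on normalized targets (default 0.001).
#' @param seed integer RNG seed for the initialization.
#' @param hidden_candidates candidate hidden-node counts for
#'   [select_hidden_nodes()] (default 5, 8, 10, 12, 16, 20).
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 0.01, max_iterations = 1000,
                         error_goal = 0.001, seed = 1,
                         hidden_candidates = c(5, 8, 10, 12, 16, 20)) {
  stopifnot(learning_rate > 0, max_iterations >= 1,
            length(hidden_candidates) >= 1)
  structure(list(learning_rate = learning_rate,
                 max_iterations = max_iterations,
                 error_goal = error_goal, seed = as.integer(seed),
                 hidden_candidates = hidden_candidates),
            class = "train_config")
}

#' Train a wavelet neural network
#'
#' Fits the core estimator: a single-hidden-layer network whose hidden
#' activations are a mother wavelet (default Morlet) with trainable scale
#' (dilation) and translation parameters in place of the usual sigmoid
#' weights and thresholds. Inputs and targets are min-max normalized to
#' [0, 1] per column; input weights and output weights start at
#' Uniform(-0.5, 0.5), scales at 0.3, and translations are spread evenly
#' over each node's pre-activation range. Training is seeded, per-sample
#' gradient descent in a fixed sample order, stopping at the error goal or
#' the iteration cap. Predictions are returned in g/L via the stored
#' inverse transform.
#'
#' @param X feature matrix (rows = samples).
#' @param Y targets in g/L.
#' @param n_hidden hidden node count (default 10).
#' @param cfg a [train_config()].
#' @param wavelet `"morlet"` (default) or `"mexican_hat"`.
#' @return object of class `wnn_model` with elements `net`, `history`
#'   (per-epoch normalized MSE and stop reason), and the normalization
#'   transforms.
#' @export
train_wnn <- function(X, Y, n_hidden = 10, cfg = train_config(),
                      wavelet = c("morlet", "mexican_hat")) {
  wavelet <- match.arg(wavelet)
  fit <- net_train(X, Y, n_hidden, wavelet,
                   learning_rate = cfg$learning_rate,
                   max_iterations = cfg$max_iterations,
                   error_goal = cfg$error_goal, seed = cfg$seed)
  structure(c(fit, list(n_hidden = n_hidden, cfg = cfg)),
            class = c("wnn_model", "petiole_model"))
}

#' @export
print.wnn_model <- function(x, ...) {
  h <- x$history
  cat(sprintf(
    "<wavelet network: %d inputs, %d hidden (%s), %d epoch(s), final MSE %.2e (%s)>\n",
    ncol(x$net$W), x$n_hidden, x$net$activation, length(h$errors),
    h$errors[length(h$errors)], h$stop_reason))
  invisible(x)
}

#' Predict petiole nitrate from a trained model
#'
#' All four model families (`wnn_model`, `bp_model`, `rbf_model`,
#' `rf_model`) share this contract: a matrix of features in, predictions in
#' g/L out.
#'
#' @param object a trained model.
#' @param newdata feature matrix with the training feature count.
#' @param ... unused.
#' @return numeric vector of predictions (g/L).
#' @export
predict.wnn_model <- function(object, newdata, ...) {
  net_predict(object, newdata)
}

#' Select the hidden-node count by prediction error
#'
#' Trains one wavelet network per candidate hidden-node count (each with a
#' fresh seeded initialization), scores each on a seeded 50/50 held-out
#' split of the data by MRE -- the root mean squared relative prediction
#' error, in percent -- and returns the count minimizing it. Ties go to the
#' smaller network.
#'
#' @param X,Y as in [train_wnn()].
#' @param candidates integer vector of hidden-node counts.
#' @param cfg a [train_config()].
#' @param split_frac fraction of samples used for training (default 0.5).
#' @return list with `best_n` and `mre_table` (data frame: `n_hidden`,
#'   `mre`; a failed candidate records `NA`).
#' @export
select_hidden_nodes <- function(X, Y, candidates = NULL,
                                cfg = train_config(), split_frac = 0.5) {
  if (is.null(candidates)) candidates <- cfg$hidden_candidates
  if (!length(candidates)) stop("empty candidate set", call. = FALSE)
  X <- as.matrix(X)
  set.seed(cfg$seed)
  n <- nrow(X)
  idx_train <- sort(sample.int(n, max(2, round(n * split_frac))))
  idx_test <- setdiff(seq_len(n), idx_train)
  mre <- vapply(candidates, function(nh) {
    tryCatch({
      m <- train_wnn(X[idx_train, , drop = FALSE], Y[idx_train],
                     n_hidden = nh, cfg = cfg)
      p <- predict(m, X[idx_test, , drop = FALSE])
      eval_metrics(p, Y[idx_test])$mre
    }, error = function(e) NA_real_)
  }, numeric(1))
  tab <- data.frame(n_hidden = candidates, mre = mre)
  ok <- which(is.finite(mre))
  if (!length(ok)) stop("every candidate failed to train", call. = FALSE)
  best <- ok[order(mre[ok], candidates[ok])][1]
  list(best_n = candidates[best], mre_table = tab)
}

#' Save / load a wavelet network
#'
#' Serializes a trained `wnn_model` (dimensions, parameter arrays,
#' normalization bounds, configuration, seed) to a flat JSON document from
#' which it reloads exactly.
#'
#' @param model a `wnn_model`.
#' @param path JSON file path.
#' @return `path` (save) or the reloaded `wnn_model` (load).
#' @export
save_wnn <- function(model, path) {
  doc <- list(
    activation = model$net$activation,
    n_hidden = model$n_hidden, n_input = ncol(model$net$W),
    W = as.vector(model$net$W), v = model$net$v, a = model$net$a,
    b = model$net$b,
    c = model$net$c,
    x_lo = model$x_transform$lo, x_span = model$x_transform$span,
    y_lo = model$y_transform$lo, y_span = model$y_transform$span,
    feature_names = model$feature_names,
    cfg = unclass(model$cfg),
    history = model$history
  )
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_wnn
#' @export
load_wnn <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  net <- list(W = matrix(doc$W, nrow = doc$n_hidden, ncol = doc$n_input),
              v = doc$v, a = doc$a, b = doc$b, c = doc$c,
              activation = doc$activation)
  cfg <- do.call(train_config, doc$cfg[c("learning_rate", "max_iterations",
                                         "error_goal", "seed",
                                         "hidden_candidates")])
  structure(list(net = net,
                 x_transform = list(lo = doc$x_lo, span = doc$x_span),
                 y_transform = list(lo = doc$y_lo, span = doc$y_span),
                 history = doc$history, feature_names = doc$feature_names,
                 n_hidden = doc$n_hidden, cfg = cfg),
            class = c("wnn_model", "petiole_model"))
}
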