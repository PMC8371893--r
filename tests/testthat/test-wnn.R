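test_that("wavelet activations match their closed forms", {
  expect_equal(wavelet_activation(0), 1)
  expect_equal(wavelet_activation(0, "mexican_hat"), 1)
  t <- seq(-4, 4, by = 0.37)
  expect_equal(wavelet_activation(t), wavelet_activation(-t))  # even
  expect_equal(wavelet_activation(t),
               cos(1.75 * t) * exp(-t^2 / 2), tolerance = 1e-15)

  # analytic derivative vs central differences at random points
  set.seed(17)
  tp <- runif(20, -3, 3)
  h <- 1e-6
  for (wv in c("morlet", "mexican_hat")) {
    num <- (wavelet_activation(tp + h, wv) -
              wavelet_activation(tp - h, wv)) / (2 * h)
    expect_equal(wavelet_activation_deriv(tp, wv), num, tolerance = 1e-6)
  }
})

test_that("forward pass matches a hand-unrolled evaluation", {
  # 1 hidden node, identity-ish parameters: yhat = psi(0) = 1 at x = 0
  net <- list(W = matrix(1, 1, 1), v = 1, a = 1, b = 0, c = 0,
              activation = "morlet")
  model <- structure(list(net = net), class = "wnn_model")
  expect_equal(net_forward(model, 0), 1)

  # all output weights zero: yhat = c everywhere
  net0 <- list(W = matrix(1, 3, 2), v = rep(0, 3), a = rep(1, 3),
               b = rep(0, 3), c = 0.7, activation = "morlet")
  m0 <- structure(list(net = net0), class = "wnn_model")
  expect_equal(net_forward(m0, c(0.3, 0.9)), 0.7)

  # random 2-input 3-node model vs explicit sums
  set.seed(23)
  net2 <- list(W = matrix(rnorm(6), 3, 2), v = rnorm(3),
               a = runif(3, 0.5, 2), b = rnorm(3), c = rnorm(1),
               activation = "morlet")
  m2 <- structure(list(net = net2), class = "wnn_model")
  x <- c(0.2, 0.6)
  by_hand <- net2$c
  for (j in 1:3) {
    t_j <- (sum(net2$W[j, ] * x) - net2$b[j]) / net2$a[j]
    by_hand <- by_hand + net2$v[j] * wavelet_activation(t_j)
  }
  expect_equal(net_forward(m2, x), by_hand, tolerance = 1e-12)
  expect_error(net_forward(m2, c(1, 2, 3)), "dimension mismatch")
})

test_that("analytic gradients match central finite differences", {
  set.seed(29)
  X <- matrix(runif(12), 6, 2)
  y <- runif(6)
  for (act in c("morlet", "sigmoid")) {
    net <- nitraspec:::net_init(2, 3, X, act)
    g <- nitraspec:::net_gradients(net, X, y)
    loss_at <- function(net) nitraspec:::net_gradients(net, X, y)$loss
    h <- 1e-6
    check <- function(group, analytic) {
      arr <- net[[group]]
      num <- arr
      for (i in seq_along(arr)) {
        np <- net; np[[group]][i] <- arr[i] + h
        nm <- net; nm[[group]][i] <- arr[i] - h
        num[i] <- (loss_at(np) - loss_at(nm)) / (2 * h)
      }
      expect_equal(as.vector(analytic), as.vector(num), tolerance = 1e-5)
    }
    check("W", g$W)
    check("b", g$b)
    check("a", g$a)
    check("v", g$v)
    check("c", g$c)
  }
})

test_that("training fits a constant target and the identity map", {
  set.seed(31)
  X <- matrix(runif(40), 20, 2)
  m <- train_wnn(X, rep(4.2, 20), cfg = train_config(seed = 1))
  expect_identical(m$history$stop_reason, "goal_reached")
  expect_lte(sqrt(mean((predict(m, X) - 4.2)^2)), sqrt(0.001) + 1e-9)

  X1 <- matrix(seq(0, 1, length.out = 50), ncol = 1)
  m1 <- train_wnn(X1, drop(X1), cfg = train_config(seed = 1))
  expect_lte(m1$history$errors[length(m1$history$errors)], 0.001)
  expect_identical(m1$history$stop_reason, "goal_reached")
})

test_that("training is deterministic under a fixed seed", {
  d <- tiny_xy(seed = 37, n = 30)
  X <- matrix(d$x, ncol = 1)
  m1 <- train_wnn(X, d$y, cfg = train_config(seed = 5))
  m2 <- train_wnn(X, d$y, cfg = train_config(seed = 5))
  expect_identical(m1$history, m2$history)
  expect_identical(m1$net, m2$net)
  p <- predict(m1, X)
  expect_identical(p, predict(m1, X))  # predict is pure
})

test_that("wavelet capacity: sine map learned within budget for most seeds", {
  X <- matrix(seq(0, 1, length.out = 50), ncol = 1)
  y <- sin(2 * pi * drop(X))
  hits <- 0
  for (s in 1:10) {
    m <- train_wnn(X, y, n_hidden = 10, cfg = train_config(seed = s))
    if (m$history$errors[length(m$history$errors)] < 1e-3) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("hidden-node selection minimizes MRE with smaller-count tie-break", {
  # printed training-error table: argmin of the MRE column is 10 nodes
  mre <- c(`5` = 7.14, `8` = 5.86, `10` = 5.82, `12` = 6.92,
           `16` = 6.35, `20` = 5.92)
  expect_equal(as.integer(names(which.min(mre))), 10)

  d <- tiny_xy(seed = 41, n = 24)
  X <- matrix(d$x, ncol = 1)
  sel <- select_hidden_nodes(X, d$y, candidates = c(5, 8, 10, 12, 16, 20),
                             cfg = train_config(seed = 2))
  expect_equal(sel$mre_table$n_hidden, c(5, 8, 10, 12, 16, 20))
  expect_equal(sel$best_n,
               sel$mre_table$n_hidden[which.min(sel$mre_table$mre)])

  single <- select_hidden_nodes(X, d$y, candidates = 7,
                                cfg = train_config(seed = 2))
  expect_equal(single$best_n, 7)

  # tie goes to the smaller network (order in candidates is irrelevant)
  tab <- data.frame(n_hidden = c(12, 8), mre = c(5, 5))
  ok <- which(is.finite(tab$mre))
  best <- ok[order(tab$mre[ok], tab$n_hidden[ok])][1]
  expect_equal(tab$n_hidden[best], 8)
})

test_that("model serialization reloads exactly", {
  d <- tiny_xy(seed = 43, n = 25)
  X <- cbind(d$x, d$x^2)
  colnames(X) <- c("f1", "f2")
  m <- train_wnn(X, d$y, n_hidden = 4, cfg = train_config(seed = 3))
  f <- withr::local_tempfile(fileext = ".json")
  save_wnn(m, f)
  m2 <- load_wnn(f)
  expect_equal(m2$net, m$net, tolerance = 1e-15)
  expect_equal(predict(m2, X), predict(m, X), tolerance = 1e-15)

  # de-normalization inverts normalization on the training target bounds
  tr <- m$y_transform
  expect_equal(drop(nitraspec:::minmax_invert(
    nitraspec:::minmax_apply(matrix(range(d$y)), tr), tr)),
    range(d$y), tolerance = 1e-12)
})
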