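test_that("layer-length recurrence matches the printed chain", {
  expect_equal(conv_output_length(2000, 3, 1, 0), 1998)
  expect_equal(conv_output_length(1998, 7, 7, 0), 285)
  expect_equal(conv_output_length(285, 3, 1, 0), 283)
  expect_equal(conv_output_length(283, 7, 7, 0), 40)
  # 4-s input through the same chain
  expect_equal(Reduce(function(n, mk) conv_output_length(n, mk[1], mk[2]),
                      list(c(3, 1), c(7, 7), c(3, 1), c(7, 7)), accumulate = TRUE,
                      init = 1000),
               c(1000, 998, 142, 140, 20))
  expect_error(conv_output_length(4, 7, 1, 0), "output length")
})

test_that("convolution + ReLU matches a nested-loop oracle", {
  set.seed(1)
  # bias through ReLU
  W0 <- array(0, dim = c(3, 1, 2))
  expect_true(all(conv1d_relu(rnorm(10), W0, c(2, 2)) == 2))
  expect_true(all(conv1d_relu(rnorm(10), W0, c(-2, -2)) == 0))
  # random multi-channel instances vs brute force
  for (rep in 1:5) {
    C <- sample(1:3, 1); J <- sample(1:3, 1); M <- sample(2:4, 1)
    x <- matrix(rnorm(30 * C), 30, C)
    W <- array(rnorm(M * C * J), dim = c(M, C, J))
    b <- rnorm(J)
    expect_equal(conv1d_relu(x, W, b), oracle_conv1d_relu(x, W, b),
                 tolerance = 1e-10)
  }
  expect_error(conv1d_relu(rnorm(2), array(0, c(3, 1, 1)), 0), "shorter")
})

test_that("max-pooling takes block maxima and drops the partial tail", {
  expect_equal(drop(maxpool(c(1, 9, 2, 3, 1, 0), 3)), c(9, 3))
  expect_equal(drop(maxpool(rep(4, 10), 3)), rep(4, 3))
  x <- matrix(rnorm(40), 20, 2)
  expect_identical(maxpool(x, 1), x)
  for (K in 2:5)
    expect_equal(maxpool(x, K), oracle_maxpool(x, K), tolerance = 1e-12)
})

test_that("LSTM forward pass matches step-by-step oracles and stays bounded", {
  zero <- function(J, Q) list(Wf = matrix(0, J, Q), Wi = matrix(0, J, Q),
                              Wo = matrix(0, J, Q), Wc = matrix(0, J, Q),
                              Rf = matrix(0, Q, Q), Ri = matrix(0, Q, Q),
                              Ro = matrix(0, Q, Q), Rc = matrix(0, Q, Q),
                              bf = numeric(Q), bi = numeric(Q),
                              bo = numeric(Q), bc = numeric(Q))
  expect_equal(lstm_forward(matrix(rnorm(10), 10, 1), zero(1, 3)), rep(0, 3))
  # scalar hand-stepped case: all W = 1, R = 0, b = 0, input [1]
  pr <- zero(1, 1)
  pr$Wf[] <- 1; pr$Wi[] <- 1; pr$Wo[] <- 1; pr$Wc[] <- 1
  sig <- function(z) 1 / (1 + exp(-z))
  cc <- sig(1) * tanh(1)
  expect_equal(lstm_forward(matrix(1, 1, 1), pr), sig(1) * tanh(cc),
               tolerance = 1e-12)
  # random instances vs oracle; outputs bounded in (-1, 1)
  for (rep in 1:5) {
    J <- sample(1:3, 1); Q <- sample(1:4, 1)
    pr <- random_lstm_params(J, Q, seed = rep)
    P <- matrix(rnorm(7 * J), 7, J)
    h <- lstm_forward(P, pr)
    expect_equal(h, oracle_lstm(P, pr), tolerance = 1e-12)
    expect_true(all(abs(h) < 1))
  }
})

test_that("built networks expose the correct LSTM sequence length and deterministic init", {
  m8 <- build_network(net_spec(), 8, 250, seed = 4)
  expect_equal(m8$seq_len, 40)
  expect_equal(m8$chain, c(2000, 1998, 285, 283, 40))
  m2 <- build_network(net_spec(), 2, 250, seed = 4)
  expect_equal(m2$chain, c(500, 498, 71, 69, 9))
  expect_identical(build_network(net_spec(), 4, 250, seed = 9)$params,
                   build_network(net_spec(), 4, 250, seed = 9)$params)
  expect_error(build_network(net_spec(), 0.1, 250, 1), "layer")
})

test_that("weighted cross-entropy follows the closed form and is linear in weights", {
  expect_lt(weighted_bce_loss(c(1, 0), c(1, 0)), 1e-5)
  expect_equal(weighted_bce_loss(1, 0.5, 1), log(2), tolerance = 1e-12)
  y <- rbinom(20, 1, 0.5); p <- runif(20); eta <- runif(20)
  expect_equal(weighted_bce_loss(y, p, 2 * eta),
               2 * weighted_bce_loss(y, p, eta), tolerance = 1e-12)
  expect_error(weighted_bce_loss(c(1, 0), 0.5), "equal length")
})

test_that("class weights equalize the class totals", {
  eta <- class_weights(c(rep(0, 8), rep(1, 2)))
  expect_equal(unique(eta[1:8]), 0.625)
  expect_equal(unique(eta[9:10]), 2.5)
  expect_equal(sum(eta[1:8]), sum(eta[9:10]))
  expect_equal(class_weights(c(0, 1, 0, 1)), rep(1, 4))
  for (rep in 1:10) {
    y <- c(0, 1, rbinom(30, 1, runif(1, 0.2, 0.8)))
    eta <- class_weights(y)
    expect_equal(sum(eta[y == 1]), sum(eta[y == 0]), tolerance = 1e-9)
  }
  expect_error(class_weights(rep(1, 5)), "both classes")
})

test_that("threshold selection attains the exhaustive-grid balanced accuracy", {
  expect_equal(select_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 0.5)
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(10:40, 1)
    p <- round(runif(n), 3)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    th <- select_threshold(p, y)
    pred <- as.integer(p >= th)
    expect_equal(bac_of(y, pred), oracle_best_bac(p, y), tolerance = 1e-9)
  }
  # degenerate: all probabilities equal -> smallest candidate threshold
  expect_equal(select_threshold(rep(0.5, 6), c(0, 1, 0, 1, 0, 1)), 0)
  expect_error(select_threshold(runif(5), rep(1, 5)), "both classes")
})

test_that("the full forward pass equals the composed layer oracles", {
  m <- build_network(net_spec(conv_filters = 2, conv_kernels = 3,
                              pool_sizes = 2, lstm_units = 3),
                     L = 0.2, fs = 250, seed = 21)   # N = 50
  x <- rnorm(50)
  W1 <- array(m$params$conv[[1]]$W, dim = c(3, 1, 2))
  a1 <- oracle_conv1d_relu(x, W1, m$params$conv[[1]]$b)
  a2 <- oracle_maxpool(a1, 2)
  h <- oracle_lstm(a2, m$params$lstm)
  p_or <- 1 / (1 + exp(-(sum(h * m$params$dense[[1]]$W) +
                           m$params$dense[[1]]$b)))
  expect_equal(predict(m, x), p_or, tolerance = 1e-10)
  # probabilities always in [0, 1]; identical input -> identical output
  expect_identical(predict(m, x), predict(m, x))
  expect_true(all(predict(m, matrix(rnorm(500), 10, 50)) >= 0))
  expect_true(all(predict(m, matrix(rnorm(500), 10, 50)) <= 1))
  expect_error(predict(m, rnorm(49)), "does not match")
})

layer_length_chain_ok <- function(spec, n) {
  m <- build_network(spec, n / 250, 250, 1)
  m$chain >= 1
}

test_that("CNN-only variants match their published layouts and fit 4-s inputs", {
  k <- build_variant("kiranyaz")
  expect_equal(k$conv_filters, c(32, 16))
  expect_equal(k$conv_kernels, c(15, 15))
  expect_equal(k$pool_sizes, c(6, 6))
  expect_equal(k$lstm_units, 0)
  z <- build_variant("zubair")
  expect_equal(z$conv_filters, c(32, 16, 8))
  a <- build_variant("acharya")
  expect_equal(length(a$conv_filters), 4)
  expect_equal(a$conv_kernels, c(5, 5, 5, 4))
  expect_length(a$dense, 1)   # one hidden + implicit sigmoid output = 2 dense
  for (nm in c("kiranyaz", "zubair", "acharya"))
    expect_true(all(layer_length_chain_ok(build_variant(nm), 1000)))
  expect_error(build_variant("lenet"), "arg")
})

shock_net_dummy_cnn <- function() {
  build_network(build_variant("zubair"), 2, 250, 1)
}

test_that("training separates the synthetic cohort and the loss descends", {
  net <- get_tiny_trained_net()
  segs <- get_tiny_train_segments()
  p <- predict(net, segs)
  y <- as.integer(segs$meta$label == "Sh")
  pred <- as.integer(p >= net$theta)
  expect_gte(bac_of(y, pred), 0.99)
  expect_lt(net$history$loss[nrow(net$history)], net$history$loss[1])
  # learned features are bounded and Q = 20 for the default spec
  H <- extract_lstm_features(net, segs)
  expect_equal(ncol(H), 20)
  expect_true(all(abs(H) < 1))
  expect_equal(H, {
    A <- segs$samples
    extract_lstm_features(net, A)
  })
  expect_error(extract_lstm_features(shock_net_dummy_cnn(), segs),
               "no LSTM")
})

test_that("training is deterministic given data and seed", {
  segs <- make_separable_segments(15, L = 2, seed = 77)
  ctrl <- train_control(epochs = 4L, batch_size = 16L, seed = 5L)
  f1 <- shock_net(segs, net_spec(), ctrl)
  f2 <- shock_net(segs, net_spec(), ctrl)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$theta, f2$theta)
})

test_that("checkpoints round-trip through the JSON archive", {
  net <- get_tiny_trained_net()
  path <- withr::local_tempfile(fileext = ".json")
  write_shock_net(net, path)
  back <- read_shock_net(path)
  x <- make_separable_test_segments(3)$samples
  expect_equal(predict(back, x), predict(net, x), tolerance = 1e-12)
  expect_equal(back$theta, net$theta)
})
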