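make_blobs <- function(n_per = 20, sep = 6, seed = 3) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(2 * n_per), ncol = 2),
             matrix(rnorm(2 * n_per, mean = sep), ncol = 2))
  y <- rep(c(-1, 1), each = n_per)
  list(X = X, y = y)
}

test_that("the RBF kernel has unit diagonal, the closed form, and symmetry", {
  x <- rnorm(5)
  expect_equal(rbf_kernel(x, x, 2), 1)
  expect_equal(rbf_kernel(c(0, 0), c(1, 0), 1), exp(-1), tolerance = 1e-12)
  for (rep in 1:10) {
    a <- rnorm(4); b <- rnorm(4); g <- runif(1, 0.1, 3)
    expect_equal(rbf_kernel(a, b, g), rbf_kernel(b, a, g))
    expect_true(rbf_kernel(a, b, g) > 0 && rbf_kernel(a, b, g) <= 1)
  }
  expect_error(rbf_kernel(1:3, 1:4, 1), "equal dimension")
  expect_error(rbf_kernel(1:3, 1:3, -1), "positive")
})

test_that("the fitted SVM separates blobs and satisfies the dual constraints", {
  d <- make_blobs(20)
  m <- fit_svm(d$X, d$y, C = 10, gamma = 0.5)
  expect_true(all(svm_decide(m, d$X) == d$y))
  # box constraints 0 <= alpha_i <= C * class weight
  wmax <- max(m$class_weights)
  expect_true(all(m$alpha >= 0))
  expect_true(all(m$alpha <= 10 * wmax + 1e-8))
  # sum alpha_i y_i = 0 within solver tolerance
  expect_lt(abs(sum(m$coefs)), 1e-6)
})

test_that("the decision function equals a direct support-vector summation", {
  d <- make_blobs(15, sep = 3)
  m <- fit_svm(d$X, d$y, C = 2, gamma = 0.7)
  set.seed(8)
  Xq <- matrix(rnorm(200), ncol = 2) * 2
  direct <- apply(Xq, 1, function(x) {
    xs <- (x - m$center) / m$scale
    sum(sapply(seq_len(nrow(m$sv)), function(i)
      m$coefs[i] * exp(-m$gamma * sum((xs - m$sv[i, ])^2)))) + m$b
  })
  expect_equal(svm_decision_values(m, Xq), direct, tolerance = 1e-8)
  expect_equal(svm_decide(m, Xq), ifelse(direct >= 0, 1, -1))
})

test_that("hand-built expansions give the expected decisions", {
  base <- list(sv = matrix(c(0, 0), 1, 2), alpha = 1, ysv = 1, coefs = 1,
               b = 0, gamma = 1, C = 1, center = c(0, 0), scale = c(1, 1),
               feature_names = NULL, n_features = 2)
  m1 <- structure(base, class = "shock_svm")
  expect_equal(svm_decide(m1, c(0, 0)), 1)    # dominant positive term at SV
  base$coefs <- 1e-6; base$b <- -10
  m2 <- structure(base, class = "shock_svm")
  expect_equal(svm_decide(m2, c(50, 50)), -1) # bias-dominated far away
  expect_error(svm_decide(m1, c(1, 2, 3)), "dimension")
})

test_that("standardization constants come from training data only", {
  d <- make_blobs(15)
  m1 <- fit_svm(d$X, d$y)
  m2 <- fit_svm(d$X, d$y)
  expect_identical(m1$center, m2$center)
  expect_identical(m1$scale, m2$scale)
  expect_equal(m1$center, colMeans(d$X))
})

test_that("outlier trimming honors the floor(frac*n) budget and spares clean data", {
  d <- make_blobs(50)                      # n = 100 -> floor(0.5) = 0 removed
  out <- trim_outliers(d$X, d$y, frac = 0.005)
  expect_length(out$removed, 0)
  # clean separable data: nothing removed even with a positive budget
  out2 <- trim_outliers(d$X, d$y, frac = 0.04, C = 100, gamma = 0.1)
  expect_length(out2$removed, 0)
  # contaminated data: flipped labels are trimmed first, within budget
  d2 <- make_blobs(50)
  d2$y[1:3] <- 1                           # three mislabeled points
  out3 <- trim_outliers(d2$X, d2$y, frac = 0.04, C = 1, gamma = 0.1)
  expect_lte(length(out3$removed), 4)
  expect_true(all(1:3 %in% out3$removed))
  expect_error(trim_outliers(d$X, d$y, frac = 0.2), "0.05")
})

test_that("Bayesian hyperparameter search stays in the box and is deterministic", {
  d <- make_blobs(12, sep = 4)
  hp1 <- tune_hyperparams(d$X, d$y, seed = 5, n_init = 5, n_iter = 8,
                          folds = 3)
  hp2 <- tune_hyperparams(d$X, d$y, seed = 5, n_init = 5, n_iter = 8,
                          folds = 3)
  expect_identical(hp1, hp2)
  expect_true(hp1["C"] >= 1e-3 && hp1["C"] <= 2e2)
  expect_true(hp1["gamma"] >= 1e-3 && hp1["gamma"] <= 2e2)
})

test_that("classical features behave on analytic signals and separate VF from sinus", {
  fs <- 250
  t <- seq(0, by = 1 / fs, length.out = 4 * fs)
  f <- compute_classical_features(sin(2 * pi * 5 * t), fs)
  expect_lt(abs(f["dominant_freq"] - 5), 0.2)
  expect_equal(unname(f["p2p_amplitude"]), 2, tolerance = 0.01)
  fc <- compute_classical_features(rep(1, 4 * fs), fs)
  expect_equal(unname(fc["mean_abs_slope"]), 0)
  expect_equal(unname(fc["crossing_rate"]), 0)
  expect_true(all(is.finite(compute_classical_features(rnorm(1000), fs))))
  expect_error(compute_classical_features(rnorm(1000), fs, "fractal_dim"),
               "unknown feature")
  # generator ground truth: VF dominant frequency exceeds sinus
  vf_dom <- sapply(1:15, function(i) compute_classical_features(
    gen_vf(5, 0.8, fs = fs, dur = 4, seed = i), fs)["dominant_freq"])
  si_dom <- sapply(1:15, function(i) compute_classical_features(
    gen_sinus(80, 1, fs, 4, seed = i), fs)["dominant_freq"])
  expect_gt(median(vf_dom), median(si_dom))
})

test_that("SVM on LSTM features selects subsets and classifies the held-out cohort", {
  net <- get_tiny_trained_net()
  train <- get_tiny_train_segments()
  test <- make_separable_test_segments(25)
  res_full <- svm_on_lstm_features(net, train, test, k = 20)
  expect_length(res_full$selected, 20)
  expect_true(all(res_full$selected %in% paste0("lstm_", 1:20)))
  res_small <- svm_on_lstm_features(net, train, test, k = 1)
  expect_length(res_small$selected, 1)
  expect_gte(res_full$metrics$BAC / 100, res_small$metrics$BAC / 100 - 0.05)
  expect_error(svm_on_lstm_features(net, train, test, k = 0), "1..")
})
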