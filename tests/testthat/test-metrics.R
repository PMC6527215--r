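test_that("confusion metrics match direct count arithmetic", {
  perfect <- confusion_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(perfect$Se, 100)
  expect_equal(perfect$Sp, 100)
  expect_equal(perfect$BAC, 100)
  expect_equal(perfect$Acc, 100)
  # TP=9 FN=1 TN=18 FP=2
  y <- c(rep(1, 10), rep(0, 20))
  yh <- c(rep(1, 9), 0, rep(0, 18), 1, 1)
  m <- confusion_metrics(y, yh)
  expect_equal(m$Se, 90)
  expect_equal(m$Sp, 90)
  expect_equal(m$PPV, 100 * 9 / 11, tolerance = 1e-9)
  expect_equal(m$Acc, 90)
  expect_equal(m$BAC, (m$Se + m$Sp) / 2)
  expect_warning(confusion_metrics(c(1, 0), c(0, 0)), "PPV undefined")
  expect_error(confusion_metrics(integer(0), integer(0)), "empty")
})

test_that("balanced accuracy, not total accuracy, is imbalance-invariant", {
  set.seed(2)
  y <- rep(c(1, 0), c(100, 400))
  yh <- y
  yh[sample(which(y == 1), 10)] <- 0   # Se = 90
  yh[sample(which(y == 0), 80)] <- 1   # Sp = 80
  full <- confusion_metrics(y, yh)
  # subsample negatives keeping the per-class error rates fixed
  keep <- c(which(y == 1), which(y == 0)[1:100])
  sub <- confusion_metrics(y[keep], yh[keep])
  expect_equal(sub$Se, full$Se, tolerance = 5)
  expect_lt(abs(sub$BAC - full$BAC), 5)
  expect_gt(abs((sub$Acc - full$Acc)) + 1e-9,
            abs(sub$BAC - full$BAC) - 5)   # Acc shifts with prevalence
})

test_that("McNemar p-values equal exact binomial tails and flip with the roles", {
  y <- rep(1, 40)
  # construct decisions with given discordant counts
  mk <- function(b, cc) {
    a_ok <- c(rep(TRUE, b), rep(FALSE, cc), rep(TRUE, 40 - b - cc))
    b_ok <- c(rep(FALSE, b), rep(TRUE, cc), rep(TRUE, 40 - b - cc))
    list(a = ifelse(a_ok, 1, 0), b = ifelse(b_ok, 1, 0))
  }
  d <- mk(10, 10)
  r <- mcnemar_test(y, d$a, d$b)
  expect_equal(r$b, 10); expect_equal(r$c, 10)
  expect_equal(r$p_value, sum(dbinom(10:20, 20, 0.5)), tolerance = 1e-12)
  expect_gt(r$p_value, 0.05)
  d2 <- mk(15, 0)
  r2 <- mcnemar_test(y, d2$a, d2$b)
  expect_equal(r2$p_value, 2^-15, tolerance = 1e-12)
  expect_lt(r2$p_value, 0.001)
  # swapping A and B moves to the opposite binomial tail
  r2s <- mcnemar_test(y, d2$b, d2$a)
  expect_equal(r2s$p_value, sum(dbinom(0:15, 15, 0.5)), tolerance = 1e-12)
  expect_warning(r3 <- mcnemar_test(y, d$a, d$a), "no discordant")
  expect_equal(r3$p_value, 1)
})

test_that("rank-based AUC matches the O(n^2) pairwise oracle", {
  expect_equal(auc_score(c(1, 2, 3, 4), c(0, 0, 1, 1)), 100)
  expect_equal(auc_score(rep(0.3, 10), rep(c(0, 1), 5)), 50)
  set.seed(4)
  for (rep in 1:10) {
    n <- sample(10:60, 1)
    s <- sample(round(runif(n), 2))   # ties likely
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(auc_score(s, y), oracle_auc(s, y), tolerance = 1e-10)
  }
  expect_error(auc_score(runif(4), rep(1, 4)), "both classes")
})

test_that("LSTM feature ranking yields a sorted 20-row AUC table", {
  net <- get_tiny_trained_net()
  test <- make_separable_test_segments(25)
  tab <- rank_lstm_features(net, test)
  expect_equal(nrow(tab), 20)
  expect_true(all(tab$auc_complete >= 0 & tab$auc_complete <= 100))
  expect_true(all(diff(tab$auc_complete) <= 0))
  expect_gte(max(tab$auc_complete), 90)   # separable cohort
})

test_that("Davies-Bouldin matches the definitional oracle and is scale invariant", {
  two <- rbind(matrix(rnorm(20, sd = 0.01), ncol = 2),
               matrix(rnorm(20, sd = 0.01, mean = 100), ncol = 2))
  lab <- rep(1:2, each = 10)
  expect_lt(davies_bouldin(two, lab), 0.01)
  set.seed(6)
  for (rep in 1:5) {
    pts <- matrix(rnorm(60), ncol = 2)
    lab3 <- sample(1:3, 30, replace = TRUE)
    if (length(unique(lab3)) < 2) next
    db <- davies_bouldin(pts, lab3)
    expect_equal(db, oracle_davies_bouldin(pts, lab3), tolerance = 1e-10)
    expect_equal(davies_bouldin(pts * 17.3, lab3), db, tolerance = 1e-9)
  }
  same <- rbind(matrix(0, 5, 2), matrix(0, 5, 2))
  expect_warning(ix <- davies_bouldin(same + rnorm(20, sd = 1e-9) * 0,
                                      rep(1:2, each = 5)), "coincident")
  expect_true(is.infinite(ix))
})

test_that("t-SNE separates well-separated classes into tight clusters", {
  set.seed(9)
  X <- rbind(matrix(rnorm(40 * 5), ncol = 5),
             matrix(rnorm(40 * 5, mean = 8), ncol = 5))
  Y <- tsne_embed(X, perplexity = 10, max_iter = 250, seed = 2)
  expect_equal(dim(Y), c(80, 2))
  expect_identical(Y, tsne_embed(X, perplexity = 10, max_iter = 250, seed = 2))
  expect_lt(davies_bouldin(Y, rep(1:2, each = 40)), 0.5)
})

test_that("the separability experiment contrasts informative and noise features", {
  set.seed(10)
  n <- 60
  lab <- rep(c(0, 1), each = n / 2)
  informative <- cbind(matrix(rnorm(n * 3), ncol = 3) + 6 * lab, lab * 4)
  noise <- matrix(rnorm(n * 5), ncol = 5)
  res <- separability_experiment(noise, informative, lab, B = 100, seed = 3,
                                 perplexity = 10, max_iter = 250)
  expect_lt(res$db_lstm["mean"], res$db_classical["mean"])
  expect_lt(res$p_value, 0.05)
  expect_gte(res$db_lstm["sd"], 0)
  # identical feature sets: equal means within bootstrap noise, p near 1
  res0 <- separability_experiment(informative, informative, lab, B = 100,
                                  seed = 4, perplexity = 10, max_iter = 250)
  expect_gt(res0$p_value, 0.5)
  expect_error(separability_experiment(noise, informative, lab, B = 1),
               "B")
})

test_that("AHA compliance uses inclusive 90/95 bounds", {
  expect_true(aha_check(99.2, 96.7))
  expect_true(aha_check(90, 95))
  expect_false(aha_check(89.9, 99))
  expect_false(aha_check(99, 94.9))
  expect_error(aha_check(-1, 50))
})

test_that("error reduction follows the printed-accuracy arithmetic", {
  expect_equal(error_reduction(96.1, 97.5), 100 * 1.4 / 3.9, tolerance = 1e-9)
  expect_gt(error_reduction(96.1, 97.5), 35)
  expect_equal(error_reduction(88, 88), 0)
  expect_equal(error_reduction(90, 100), 100)
  expect_error(error_reduction(100, 100), "undefined")
})
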