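# Independent brute-force oracles used to cross-check the implementation.

# naive valid cross-correlation + ReLU, nested loops
oracle_conv1d_relu <- function(x, W, b) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  M <- dim(W)[1]; C <- dim(W)[2]; J <- dim(W)[3]
  n_out <- nrow(x) - M + 1
  out <- matrix(0, n_out, J)
  for (j in seq_len(J)) for (i in seq_len(n_out)) {
    acc <- b[j]
    for (c in seq_len(C)) for (m in seq_len(M))
      acc <- acc + W[m, c, j] * x[i + m - 1, c]
    out[i, j] <- max(0, acc)
  }
  out
}

oracle_maxpool <- function(x, K) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  n_out <- nrow(x) %/% K
  out <- matrix(0, n_out, ncol(x))
  for (c in seq_len(ncol(x))) for (i in seq_len(n_out))
    out[i, c] <- max(x[((i - 1) * K + 1):(i * K), c])
  out
}

# scalar / vector step-by-step LSTM
oracle_lstm <- function(P, pr) {
  if (is.vector(P)) P <- matrix(P, ncol = 1)
  Q <- ncol(pr$Wf)
  sig <- function(z) 1 / (1 + exp(-z))
  h <- rep(0, Q); cc <- rep(0, Q)
  for (t in seq_len(nrow(P))) {
    p <- P[t, ]
    f <- sig(drop(p %*% pr$Wf) + drop(h %*% pr$Rf) + pr$bf)
    i <- sig(drop(p %*% pr$Wi) + drop(h %*% pr$Ri) + pr$bi)
    o <- sig(drop(p %*% pr$Wo) + drop(h %*% pr$Ro) + pr$bo)
    g <- tanh(drop(p %*% pr$Wc) + drop(h %*% pr$Rc) + pr$bc)
    cc <- f * cc + i * g
    h <- o * tanh(cc)
  }
  h
}

# O(n^2) pairwise AUC
oracle_auc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  100 * tot / (length(pos) * length(neg))
}

oracle_davies_bouldin <- function(pts, labels) {
  labs <- unique(labels)
  k <- length(labs)
  cent <- lapply(labs, function(l) colMeans(pts[labels == l, , drop = FALSE]))
  s <- sapply(seq_len(k), function(i) {
    P <- pts[labels == labs[i], , drop = FALSE]
    mean(apply(P, 1, function(r) sqrt(sum((r - cent[[i]])^2))))
  })
  rs <- sapply(seq_len(k), function(i) {
    max(sapply(setdiff(seq_len(k), i), function(j) {
      (s[i] + s[j]) / sqrt(sum((cent[[i]] - cent[[j]])^2))
    }))
  })
  mean(rs)
}

# exhaustive-grid threshold search
oracle_best_bac <- function(p, y, step = 1e-4) {
  grid <- seq(0, 1, by = step)
  best <- 0
  for (th in grid) {
    pred <- as.integer(p >= th)
    bac <- (mean(pred[y == 1] == 1) + mean(pred[y == 0] == 0)) / 2
    if (bac > best) best <- bac
  }
  best
}

bac_of <- function(y, pred) {
  (mean(pred[y == 1] == 1) + mean(pred[y == 0] == 0)) / 2
}
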