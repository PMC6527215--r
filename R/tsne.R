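# Exact-gradient t-SNE (2-D). At the cohort sizes this package works with
# (hundreds of instances) the exact O(n^2) gradient is affordable and more
# accurate than tree-based approximations, so no approximation is used.

#' t-SNE embedding to two dimensions
#'
#' t-distributed stochastic neighbor embedding with the standard recipe:
#' per-point Gaussian bandwidths found by bisection to match the target
#' perplexity, symmetrized input affinities, early exaggeration (factor 4
#' for the first 100 iterations), gradient descent with momentum (0.5, then
#' 0.8 after iteration 250) and adaptive per-coordinate gains.
#'
#' @param X Numeric feature matrix (instances x features).
#' @param perplexity Target perplexity (effective neighborhood size).
#' @param max_iter Gradient-descent iterations.
#' @param eta Learning rate.
#' @param seed Integer seed for the random initialization.
#' @return Numeric matrix (instances x 2) of embedding coordinates.
#' @export
tsne_embed <- function(X, perplexity = 30, max_iter = 1000L, eta = 200,
                       seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4L) stop("need at least 4 instances")
  perplexity <- min(perplexity, (n - 1) / 3)
  D2 <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta <- 1; lo <- -Inf; hi <- Inf
    for (it in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { beta <- beta / 2; next }
      H <- log(sw) + beta * sum(di * w) / sw
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  rng <- local_rng(seed)
  on.exit(restore_rng(rng))
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  dY <- matrix(0, n, 2); gains <- matrix(1, n, 2)
  for (it in seq_len(max_iter)) {
    Pe <- if (it <= 100L) P * 4 else P
    mom <- if (it < 250L) 0.5 else 0.8
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Qm <- pmax(num / sum(num), 1e-12)
    W <- (Pe - Qm) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- mom * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2L, colMeans(Y))
  }
  Y
}
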