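# Network layer primitives. Public single-example operations mirror the
# forward equations of the architecture; batched internals (bt_*) carry both
# the forward pass and backpropagation used in training.

relu <- function(z) pmax(z, 0)
sigmoid <- function(z) 1 / (1 + exp(-z))

#' Output length of a valid convolution / pooling stage
#'
#' `floor((n_in + 2p - m) / s) + 1`, the temporal length after a 1-D
#' convolution or max-pooling stage with kernel `m`, stride `s` and padding
#' `p`. For an 8-s segment at 250 Hz the chain conv(3,1) - pool(7,7) -
#' conv(3,1) - pool(7,7) gives 2000 -> 1998 -> 285 -> 283 -> 40.
#'
#' @param n_in Input length in samples.
#' @param m Kernel (or pool) size.
#' @param s Stride (1 for convolution, the pool size for pooling).
#' @param p Zero padding (0 throughout this architecture).
#' @return Integer output length.
#' @export
conv_output_length <- function(n_in, m, s = 1L, p = 0L) {
  stopifnot(s >= 1)
  out <- floor((n_in + 2 * p - m) / s) + 1
  if (out < 1) stop("layer output length < 1 (input too short for kernel ", m, ")")
  as.integer(out)
}

#' 1-D convolution with ReLU activation
#'
#' Valid (no padding, stride 1) cross-correlation of a multichannel sequence
#' with a filter bank, plus bias, through `max(0, .)`.
#'
#' @param x Numeric matrix (length x channels) or vector (single channel).
#' @param weights Array of dimension `(M, C_in, J)`: kernel x input channels
#'   x filters.
#' @param bias Numeric vector of length `J`.
#' @return Matrix of dimension `(length - M + 1, J)`.
#' @export
conv1d_relu <- function(x, weights, bias) {
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  dw <- dim(weights)
  if (length(dw) != 3L || dw[2] != ncol(x) || length(bias) != dw[3])
    stop("weight/bias shapes inconsistent with input channels")
  if (nrow(x) < dw[1]) stop("sequence shorter than kernel")
  A <- array(x, dim = c(1L, nrow(x), ncol(x)))
  W <- matrix(as.vector(weights), dw[1] * dw[2], dw[3])
  out <- bt_conv_fwd(A, W, bias, dw[1])
  matrix(out$Y, dim(out$Y)[2], dim(out$Y)[3])
}

#' Non-overlapping max-pooling
#'
#' Per channel, the maximum over consecutive non-overlapping blocks of `K`
#' samples; a trailing partial block is dropped.
#'
#' @param x Numeric matrix (length x channels) or vector.
#' @param K Pool size (>= 1).
#' @return Matrix of dimension `(floor(length / K), channels)`.
#' @export
maxpool <- function(x, K) {
  if (K < 1) stop("`K` must be >= 1")
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  if (nrow(x) < K) stop("sequence shorter than pool size")
  A <- array(x, dim = c(1L, nrow(x), ncol(x)))
  out <- bt_pool_fwd(A, as.integer(K))
  matrix(out$Y, dim(out$Y)[2], dim(out$Y)[3])
}

#' LSTM forward pass over a feature-map sequence
#'
#' Iterates the gated recurrence (forget, input, output gates; cell state)
#' with zero initial state and returns the hidden state after the last step.
#' Input weight matrices have dimension `(J, Q)` (acting on row vectors),
#' recurrence matrices `(Q, Q)`, biases length `Q`.
#'
#' @param P Numeric matrix (time x J input features) or vector.
#' @param params List with `Wf, Wi, Wo, Wc`, `Rf, Ri, Ro, Rc`,
#'   `bf, bi, bo, bc`.
#' @return Numeric vector of length `Q`, the final hidden state; every
#'   component lies in (-1, 1).
#' @export
lstm_forward <- function(P, params) {
  if (is.vector(P)) P <- matrix(P, ncol = 1L)
  if (nrow(P) < 1L) stop("sequence must have length >= 1")
  if (ncol(P) != nrow(params$Wf)) stop("input width does not match Wf")
  A <- array(P, dim = c(1L, nrow(P), ncol(P)))
  drop(bt_lstm_fwd(A, params)$h)
}

# ---- batched internals -------------------------------------------------

# A: (n, Nin, C) -> (n*Nout, M*C), columns ordered kernel-position fastest
# within channel, matching matrix(as.vector(W), M*C, J).
bt_im2col <- function(A, M) {
  d <- dim(A); n <- d[1]; C <- d[3]
  Nout <- d[2] - M + 1L
  out <- matrix(0, n * Nout, M * C)
  for (c in seq_len(C)) for (m in seq_len(M))
    out[, (c - 1L) * M + m] <- as.vector(A[, m:(m + Nout - 1L), c])
  out
}

bt_conv_fwd <- function(A, W, b, M) {
  d <- dim(A)
  Nout <- d[2] - M + 1L
  Acol <- bt_im2col(A, M)
  Z <- sweep(Acol %*% W, 2L, b, "+")
  list(Y = array(relu(Z), dim = c(d[1], Nout, ncol(W))),
       Acol = Acol, mask = Z > 0, dims_in = d, M = M)
}

bt_conv_bwd <- function(cache, W, dY) {
  d <- cache$dims_in; n <- d[1]; C <- d[3]; M <- cache$M
  Nout <- d[2] - M + 1L
  dZ <- matrix(dY, n * Nout, ncol(W)) * cache$mask
  dW <- crossprod(cache$Acol, dZ)
  db <- colSums(dZ)
  dAcol <- tcrossprod(dZ, W)
  dA <- array(0, dim = d)
  for (c in seq_len(C)) for (m in seq_len(M))
    dA[, m:(m + Nout - 1L), c] <- dA[, m:(m + Nout - 1L), c] +
      matrix(dAcol[, (c - 1L) * M + m], n, Nout)
  list(dA = dA, dW = dW, db = db)
}

bt_pool_fwd <- function(A, K) {
  d <- dim(A)
  Nout <- d[2] %/% K
  Y <- A[, seq(1L, by = K, length.out = Nout), , drop = FALSE]
  arg <- array(1L, dim = c(d[1], Nout, d[3]))
  if (K > 1L) for (k in 2:K) {
    cand <- A[, seq(k, by = K, length.out = Nout), , drop = FALSE]
    sel <- cand > Y
    Y[sel] <- cand[sel]
    arg[sel] <- k
  }
  list(Y = Y, arg = arg, dims_in = d, K = K)
}

bt_pool_bwd <- function(cache, dY) {
  d <- cache$dims_in; n <- d[1]; K <- cache$K
  Nout <- d[2] %/% K
  dA <- array(0, dim = d)
  pos <- rep(seq_len(Nout), each = n)
  ni <- rep(seq_len(n), Nout)
  for (c in seq_len(d[3])) {
    src <- (pos - 1L) * K + as.vector(cache$arg[, , c])
    lin <- ni + n * (src - 1L) + n * d[2] * (c - 1L)
    dA[lin] <- dA[lin] + as.vector(dY[, , c])
  }
  dA
}

bt_lstm_fwd <- function(P, pr) {
  d <- dim(P); n <- d[1]; Tn <- d[2]
  Q <- ncol(pr$Wf)
  h <- matrix(0, n, Q); cc <- matrix(0, n, Q)
  S <- list(f = array(0, c(n, Tn, Q)), i = array(0, c(n, Tn, Q)),
            o = array(0, c(n, Tn, Q)), g = array(0, c(n, Tn, Q)),
            c = array(0, c(n, Tn, Q)), h = array(0, c(n, Tn, Q)))
  for (t in seq_len(Tn)) {
    Pt <- matrix(P[, t, ], n)
    f <- sigmoid(sweep(Pt %*% pr$Wf + h %*% pr$Rf, 2L, pr$bf, "+"))
    i <- sigmoid(sweep(Pt %*% pr$Wi + h %*% pr$Ri, 2L, pr$bi, "+"))
    o <- sigmoid(sweep(Pt %*% pr$Wo + h %*% pr$Ro, 2L, pr$bo, "+"))
    g <- tanh(sweep(Pt %*% pr$Wc + h %*% pr$Rc, 2L, pr$bc, "+"))
    cc <- f * cc + i * g
    h <- o * tanh(cc)
    S$f[, t, ] <- f; S$i[, t, ] <- i; S$o[, t, ] <- o
    S$g[, t, ] <- g; S$c[, t, ] <- cc; S$h[, t, ] <- h
  }
  list(h = h, S = S, P = P)
}

bt_lstm_bwd <- function(cache, pr, dh_T) {
  P <- cache$P; S <- cache$S
  d <- dim(P); n <- d[1]; Tn <- d[2]; J <- d[3]
  Q <- ncol(pr$Wf)
  gr <- list(Wf = matrix(0, J, Q), Wi = matrix(0, J, Q),
             Wo = matrix(0, J, Q), Wc = matrix(0, J, Q),
             Rf = matrix(0, Q, Q), Ri = matrix(0, Q, Q),
             Ro = matrix(0, Q, Q), Rc = matrix(0, Q, Q),
             bf = numeric(Q), bi = numeric(Q), bo = numeric(Q), bc = numeric(Q))
  dP <- array(0, dim = d)
  dh <- dh_T; dc <- matrix(0, n, Q)
  for (t in Tn:1) {
    f <- matrix(S$f[, t, ], n); i <- matrix(S$i[, t, ], n)
    o <- matrix(S$o[, t, ], n); g <- matrix(S$g[, t, ], n)
    cc <- matrix(S$c[, t, ], n)
    cprev <- if (t > 1L) matrix(S$c[, t - 1L, ], n) else matrix(0, n, Q)
    hprev <- if (t > 1L) matrix(S$h[, t - 1L, ], n) else matrix(0, n, Q)
    tc <- tanh(cc)
    do_ <- dh * tc
    dc <- dc + dh * o * (1 - tc^2)
    df <- dc * cprev; di <- dc * g; dg <- dc * i
    dzf <- df * f * (1 - f); dzi <- di * i * (1 - i)
    dzo <- do_ * o * (1 - o); dzg <- dg * (1 - g^2)
    Pt <- matrix(P[, t, ], n)
    gr$Wf <- gr$Wf + crossprod(Pt, dzf); gr$Wi <- gr$Wi + crossprod(Pt, dzi)
    gr$Wo <- gr$Wo + crossprod(Pt, dzo); gr$Wc <- gr$Wc + crossprod(Pt, dzg)
    gr$Rf <- gr$Rf + crossprod(hprev, dzf); gr$Ri <- gr$Ri + crossprod(hprev, dzi)
    gr$Ro <- gr$Ro + crossprod(hprev, dzo); gr$Rc <- gr$Rc + crossprod(hprev, dzg)
    gr$bf <- gr$bf + colSums(dzf); gr$bi <- gr$bi + colSums(dzi)
    gr$bo <- gr$bo + colSums(dzo); gr$bc <- gr$bc + colSums(dzg)
    dP[, t, ] <- tcrossprod(dzf, pr$Wf) + tcrossprod(dzi, pr$Wi) +
      tcrossprod(dzo, pr$Wo) + tcrossprod(dzg, pr$Wc)
    dh <- tcrossprod(dzf, pr$Rf) + tcrossprod(dzi, pr$Ri) +
      tcrossprod(dzo, pr$Ro) + tcrossprod(dzg, pr$Rc)
    dc <- dc * f
  }
  list(gr = gr, dP = dP)
}
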