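# The CNN+LSTM shock-decision classifier and CNN-only comparison networks:
# architecture specification, initialization, class-weighted training with
# Nesterov SGD, balanced-accuracy threshold selection, and prediction.

#' Network architecture specification
#'
#' The default is the mixed architecture: two convolutional sub-blocks of
#' J = 32 filters of size M = 3 with ReLU activation, each followed by
#' max-pooling of size K = 7; an LSTM with Q = 20 output features; and a
#' single sigmoid output unit.
#'
#' @param conv_filters Integer vector, filters per convolutional layer (J).
#' @param conv_kernels Integer vector, kernel size per layer (M).
#' @param pool_sizes Integer vector, max-pool size after each layer (K).
#' @param lstm_units LSTM output features Q; 0 for a CNN-only network (the
#'   final feature map is then flattened into the dense head).
#' @param dense Integer vector of hidden dense widths (ReLU); the final
#'   1-unit sigmoid output layer is implicit.
#' @return A list of class `net_spec`.
#' @export
net_spec <- function(conv_filters = c(32L, 32L), conv_kernels = c(3L, 3L),
                     pool_sizes = c(7L, 7L), lstm_units = 20L,
                     dense = integer(0)) {
  nb <- length(conv_filters)
  if (length(conv_kernels) != nb || length(pool_sizes) != nb)
    stop("conv_filters, conv_kernels and pool_sizes must have equal length")
  if (any(c(conv_filters, conv_kernels, pool_sizes) < 1) || lstm_units < 0)
    stop("all architecture sizes must be positive")
  structure(list(conv_filters = as.integer(conv_filters),
                 conv_kernels = as.integer(conv_kernels),
                 pool_sizes = as.integer(pool_sizes),
                 lstm_units = as.integer(lstm_units),
                 dense = as.integer(dense)),
            class = "net_spec")
}

#' CNN-only comparison architectures
#'
#' Published 1D-CNN architectures reimplemented for comparison. All use ReLU
#' activations, stride 1, no padding; where the original lists two dense
#' layers the hidden width is 32.
#'
#' @param name One of `"kiranyaz"` (2 conv layers: 32, 16 filters, kernels
#'   15, pool 6, 1 dense), `"zubair"` (3 layers: 32, 16, 8 filters, kernels
#'   5, pool 2, 1 dense), `"acharya"` (4 layers: 3, 5, 10, 10 filters,
#'   kernels 5, 5, 5, 4, pool 2, 2 dense).
#' @return A [net_spec()] with `lstm_units = 0`.
#' @export
build_variant <- function(name = c("kiranyaz", "zubair", "acharya")) {
  name <- match.arg(name)
  switch(name,
    kiranyaz = net_spec(c(32L, 16L), c(15L, 15L), c(6L, 6L), 0L),
    zubair   = net_spec(c(32L, 16L, 8L), c(5L, 5L, 5L), c(2L, 2L, 2L), 0L),
    acharya  = net_spec(c(3L, 5L, 10L, 10L), c(5L, 5L, 5L, 4L),
                        c(2L, 2L, 2L, 2L), 0L, dense = 32L))
}

# Temporal lengths through the conv/pool chain; includes the input length
# as the first element.
layer_length_chain <- function(spec, n_in) {
  lens <- n_in
  n <- n_in
  for (l in seq_along(spec$conv_filters)) {
    n <- tryCatch(conv_output_length(n, spec$conv_kernels[l], 1L, 0L),
                  error = function(e)
                    stop("conv layer ", l, ": ", conditionMessage(e), call. = FALSE))
    lens <- c(lens, n)
    n <- tryCatch(conv_output_length(n, spec$pool_sizes[l], spec$pool_sizes[l], 0L),
                  error = function(e)
                    stop("pool layer ", l, ": ", conditionMessage(e), call. = FALSE))
    lens <- c(lens, n)
  }
  lens
}

#' Training configuration
#'
#' Defaults follow the standard large-scale recipe: stochastic gradient
#' descent with Nesterov acceleration, learning rate 1e-3 with per-update
#' decay `lr / (1 + decay * t)`, momentum 0.9, 600 epochs in batches of 256.
#' Desk-scale experiments use fewer epochs and smaller batches (see
#' [experiment_config()]).
#'
#' @param lr Learning rate.
#' @param lr_decay Per-update multiplicative decay rate.
#' @param momentum Momentum coefficient (Nesterov).
#' @param epochs Number of passes over the training data.
#' @param batch_size Mini-batch size.
#' @param seed Integer seed controlling initialization and batch shuffling.
#' @return A list of class `train_control`.
#' @export
train_control <- function(lr = 1e-3, lr_decay = 1e-6, momentum = 0.9,
                          epochs = 600L, batch_size = 256L, seed = 1L) {
  stopifnot(lr > 0, epochs >= 1, batch_size >= 1)
  structure(list(lr = lr, lr_decay = lr_decay, momentum = momentum,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "train_control")
}

#' Instance weights balancing the two classes
#'
#' Each instance of class `k` receives weight `n_total / (2 * n_k)`, so the
#' total weight of the shockable and nonshockable classes is equal.
#'
#' @param labels Binary labels: 0/1, logical, or `"Sh"`/`"NSh"`.
#' @return Numeric weight vector, one value per instance.
#' @export
class_weights <- function(labels) {
  y <- as_binary_y(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  n <- length(y)
  ifelse(y == 1, n / (2 * n1), n / (2 * n0))
}

as_binary_y <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    bad <- setdiff(labels, c("Sh", "NSh"))
    if (length(bad)) stop("labels must be 'Sh'/'NSh' or 0/1")
    as.integer(labels == "Sh")
  } else as.integer(labels != 0)
}

#' Class-weighted binary cross-entropy
#'
#' `-sum(eta * (y * log(p) + (1 - y) * log(1 - p)))` with probabilities
#' clipped to `[1e-7, 1 - 1e-7]`.
#'
#' @param y Binary labels (0/1).
#' @param p Predicted probabilities.
#' @param eta Non-negative instance weights.
#' @return Scalar loss.
#' @export
weighted_bce_loss <- function(y, p, eta = rep(1, length(y))) {
  if (length(y) != length(p) || length(eta) != length(y))
    stop("y, p and eta must have equal length")
  y <- as_binary_y(y)
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -sum(eta * (y * log(p) + (1 - y) * log(1 - p)))
}

#' Decision threshold maximizing balanced accuracy
#'
#' Scans candidate thresholds (0, 1, and midpoints between consecutive
#' sorted unique probabilities) and returns the one maximizing the balanced
#' accuracy of the decision `p >= theta`; ties resolve to the smallest
#' threshold.
#'
#' @param p Predicted probabilities.
#' @param y Binary labels (both classes must be present).
#' @return The selected threshold in `[0, 1]`.
#' @export
select_threshold <- function(p, y) {
  y <- as_binary_y(y)
  if (all(y == 1) || all(y == 0)) stop("both classes must be present")
  u <- sort(unique(p))
  cand <- sort(unique(c(0, 1, if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2)))
  bac <- vapply(cand, function(th) {
    pred <- as.integer(p >= th)
    (mean(pred[y == 1] == 1) + mean(pred[y == 0] == 0)) / 2
  }, numeric(1))
  cand[which.max(bac)]   # which.max returns the first (smallest) maximizer
}

# fan-in scaled uniform init
init_uniform <- function(nr, nc, fan_in) {
  lim <- sqrt(6 / fan_in)
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

init_orthogonal <- function(q) {
  qr.Q(qr(matrix(stats::rnorm(q * q), q, q)))
}

#' Build an untrained network
#'
#' Allocates and initializes all parameters for a given architecture and
#' segment length: fan-in-scaled uniform weights for convolutional and dense
#' layers, orthogonal LSTM recurrence matrices, zero biases except the LSTM
#' forget-gate bias (1). Initialization is deterministic given the seed.
#'
#' @param spec A [net_spec()].
#' @param L Segment length in seconds.
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed for the initialization.
#' @return An object of class `shock_net` with `fitted = FALSE`.
#' @export
build_network <- function(spec, L, fs = 250, seed = 1L) {
  N <- round(L * fs)
  chain <- layer_length_chain(spec, N)
  rng <- local_rng(seed)
  on.exit(restore_rng(rng))
  conv <- list()
  C <- 1L
  for (l in seq_along(spec$conv_filters)) {
    M <- spec$conv_kernels[l]; J <- spec$conv_filters[l]
    conv[[l]] <- list(W = init_uniform(M * C, J, M * C), b = numeric(J))
    C <- J
  }
  seq_len_final <- chain[length(chain)]
  lstm <- NULL
  feat_dim <- seq_len_final * C
  if (spec$lstm_units > 0L) {
    Q <- spec$lstm_units; J <- C
    lstm <- list(Wf = init_uniform(J, Q, J), Wi = init_uniform(J, Q, J),
                 Wo = init_uniform(J, Q, J), Wc = init_uniform(J, Q, J),
                 Rf = init_orthogonal(Q), Ri = init_orthogonal(Q),
                 Ro = init_orthogonal(Q), Rc = init_orthogonal(Q),
                 bf = rep(1, Q), bi = numeric(Q), bo = numeric(Q),
                 bc = numeric(Q))
    feat_dim <- Q
  }
  dense <- list()
  d_in <- feat_dim
  for (w in spec$dense) {
    dense[[length(dense) + 1L]] <- list(W = init_uniform(d_in, w, d_in),
                                        b = numeric(w))
    d_in <- w
  }
  dense[[length(dense) + 1L]] <- list(W = init_uniform(d_in, 1L, d_in), b = 0)
  structure(list(spec = spec, L = L, fs = fs, N = as.integer(N),
                 chain = as.integer(chain),
                 seq_len = as.integer(seq_len_final),
                 params = list(conv = conv, lstm = lstm, dense = dense),
                 theta = NA_real_, history = NULL, control = NULL,
                 seed = as.integer(seed), fitted = FALSE),
            class = "shock_net")
}

# full batched forward pass; X: (n, N) matrix
net_forward <- function(model, X, keep_cache = FALSE) {
  sp <- model$spec; pr <- model$params
  A <- array(X, dim = c(nrow(X), ncol(X), 1L))
  cc <- list(); pc <- list()
  for (l in seq_along(sp$conv_filters)) {
    cf <- bt_conv_fwd(A, pr$conv[[l]]$W, pr$conv[[l]]$b, sp$conv_kernels[l])
    pf <- bt_pool_fwd(cf$Y, sp$pool_sizes[l])
    A <- pf$Y
    if (keep_cache) { cc[[l]] <- cf; pc[[l]] <- pf }
    else { cf$Acol <- NULL; cf$mask <- NULL }
  }
  lf <- NULL
  if (sp$lstm_units > 0L) {
    lf <- bt_lstm_fwd(A, pr$lstm)
    H <- lf$h
  } else {
    H <- matrix(A, nrow(X))
  }
  dcache <- list()
  for (k in seq_along(pr$dense)) {
    Z <- sweep(H %*% pr$dense[[k]]$W, 2L, pr$dense[[k]]$b, "+")
    last <- k == length(pr$dense)
    out <- if (last) sigmoid(Z) else relu(Z)
    if (keep_cache) dcache[[k]] <- list(H_in = H, Z = Z)
    H <- out
  }
  list(p = as.numeric(H), conv = cc, pool = pc, lstm = lf,
       feat_dims = if (sp$lstm_units > 0L) NULL else dim(A),
       dense = dcache)
}

net_backward <- function(model, fw, dz) {
  sp <- model$spec; pr <- model$params
  g <- list(conv = vector("list", length(pr$conv)), lstm = NULL,
            dense = vector("list", length(pr$dense)))
  dH <- matrix(dz, ncol = 1L)
  for (k in rev(seq_along(pr$dense))) {
    cache <- fw$dense[[k]]
    dZ <- if (k == length(pr$dense)) dH else dH * (cache$Z > 0)
    g$dense[[k]] <- list(W = crossprod(cache$H_in, dZ), b = colSums(dZ))
    dH <- tcrossprod(dZ, pr$dense[[k]]$W)
  }
  if (sp$lstm_units > 0L) {
    lb <- bt_lstm_bwd(fw$lstm, pr$lstm, dH)
    g$lstm <- lb$gr
    dA <- lb$dP
  } else {
    dA <- array(dH, dim = fw$feat_dims)
  }
  for (l in rev(seq_along(pr$conv))) {
    dA <- bt_pool_bwd(fw$pool[[l]], dA)
    cb <- bt_conv_bwd(fw$conv[[l]], pr$conv[[l]]$W, dA)
    g$conv[[l]] <- list(W = cb$dW, b = cb$db)
    dA <- cb$dA
  }
  g
}

# Nesterov momentum update applied leaf-wise over the parameter tree
sgd_step <- function(params, vel, grads, lr, mom) {
  walk <- function(p, v, g) {
    if (is.list(p) && is.null(names(p))) {
      for (i in seq_along(p)) {
        if (is.null(g[[i]])) next
        r <- walk(p[[i]], v[[i]], g[[i]])
        p[[i]] <- r$p; v[[i]] <- r$v
      }
      return(list(p = p, v = v))
    }
    if (is.list(p)) {
      for (nm in names(p)) {
        if (is.null(g[[nm]])) next
        r <- walk(p[[nm]], v[[nm]], g[[nm]])
        p[[nm]] <- r$p; v[[nm]] <- r$v
      }
      return(list(p = p, v = v))
    }
    v2 <- mom * v - lr * g
    list(p = p + mom * v2 - lr * g, v = v2)
  }
  walk(params, vel, grads)
}

zero_like <- function(p) {
  if (is.list(p)) return(lapply(p, zero_like))
  p * 0
}

#' Train a network on a segment set
#'
#' Minimizes the class-weighted binary cross-entropy by mini-batch
#' stochastic gradient descent with Nesterov acceleration and per-update
#' learning-rate decay. After training, the decision threshold is chosen to
#' maximize the balanced accuracy on the *training* predictions, so no test
#' information enters the fitted classifier.
#'
#' @param model An untrained [build_network()] result.
#' @param segments A `segment_set` containing both classes.
#' @param control A [train_control()].
#' @return The fitted `shock_net` (threshold set, training log in
#'   `$history`).
#' @export
train_network <- function(model, segments, control = train_control()) {
  stopifnot(inherits(model, "shock_net"), inherits(segments, "segment_set"))
  X <- segments$samples
  if (ncol(X) != model$N)
    stop("segment length ", ncol(X), " does not match model input ", model$N)
  y <- as_binary_y(segments$meta$label)
  if (all(y == 1) || all(y == 0)) stop("both classes must be present")
  eta <- class_weights(y)
  rng <- local_rng(control$seed + 1L)
  on.exit(restore_rng(rng))
  vel <- zero_like(model$params)
  iter <- 0L
  hist <- numeric(control$epochs)
  for (ep in seq_len(control$epochs)) {
    ord <- sample.int(length(y))
    batches <- split(ord, ceiling(seq_along(ord) / control$batch_size))
    ep_loss <- 0
    for (bi in batches) {
      iter <- iter + 1L
      fw <- net_forward(model, X[bi, , drop = FALSE], keep_cache = TRUE)
      nb <- length(bi)
      ep_loss <- ep_loss + weighted_bce_loss(y[bi], fw$p, eta[bi])
      dz <- eta[bi] * (fw$p - y[bi]) / nb
      g <- net_backward(model, fw, dz)
      lr_t <- control$lr / (1 + control$lr_decay * iter)
      r <- sgd_step(model$params, vel, g, lr_t, control$momentum)
      model$params <- r$p; vel <- r$v
    }
    hist[ep] <- ep_loss / length(y)
    if (!is.finite(hist[ep]))
      stop("training diverged (non-finite loss) at epoch ", ep)
  }
  p_train <- net_forward(model, X)$p
  model$theta <- select_threshold(p_train, y)
  model$history <- data.frame(epoch = seq_len(control$epochs), loss = hist)
  model$control <- control
  model$fitted <- TRUE
  model
}

#' Fit the shock-decision network
#'
#' Builds and trains a classifier on a labeled segment set in one call; the
#' default architecture is the mixed CNN+LSTM network.
#'
#' @param segments A `segment_set` (see [extract_segments()]).
#' @param spec A [net_spec()]; defaults to the CNN+LSTM architecture.
#' @param control A [train_control()].
#' @param seed Seed for parameter initialization; batch shuffling is driven
#'   by `control$seed`.
#' @return A fitted object of class `shock_net`.
#' @export
shock_net <- function(segments, spec = net_spec(), control = train_control(),
                      seed = control$seed) {
  model <- build_network(spec, segments$L, segments$fs, seed)
  train_network(model, segments, control)
}

#' Predict shock probabilities or decisions
#'
#' @param object A fitted `shock_net`.
#' @param newdata A `segment_set`, a samples matrix (one segment per row),
#'   or a single segment vector.
#' @param type `"prob"` for the shock likelihood `p_Sh`, `"decision"` for
#'   the thresholded shock/no_shock call (`shock` iff `p_Sh >= theta`).
#' @param ... Unused.
#' @return Numeric vector of probabilities, or a factor with levels
#'   `no_shock`, `shock`.
#' @export
predict.shock_net <- function(object, newdata, type = c("prob", "decision"),
                              ...) {
  type <- match.arg(type)
  X <- segment_matrix(newdata)
  if (ncol(X) != object$N)
    stop("segment length ", ncol(X), " does not match model input ", object$N)
  p <- net_forward(object, X)$p
  if (type == "prob") return(p)
  if (!object$fitted || is.na(object$theta))
    stop("model has no decision threshold; train it first")
  factor(ifelse(p >= object$theta, "shock", "no_shock"),
         levels = c("no_shock", "shock"))
}

segment_matrix <- function(newdata) {
  if (inherits(newdata, "segment_set")) newdata$samples
  else if (is.matrix(newdata)) newdata
  else matrix(newdata, nrow = 1L)
}

#' Extract the learned LSTM features
#'
#' Returns the hidden state of the LSTM at the final time step (the Q
#' features feeding the dense head), one row per segment.
#'
#' @param model A `shock_net` with an LSTM block.
#' @param newdata A `segment_set` or samples matrix.
#' @return Numeric matrix (segments x Q), columns named `lstm_1..lstm_Q`;
#'   every value lies in (-1, 1).
#' @export
extract_lstm_features <- function(model, newdata) {
  if (model$spec$lstm_units == 0L)
    stop("model has no LSTM block; features are undefined for CNN-only networks")
  X <- segment_matrix(newdata)
  if (ncol(X) != model$N)
    stop("segment length ", ncol(X), " does not match model input ", model$N)
  sp <- model$spec; pr <- model$params
  A <- array(X, dim = c(nrow(X), ncol(X), 1L))
  for (l in seq_along(sp$conv_filters)) {
    cf <- bt_conv_fwd(A, pr$conv[[l]]$W, pr$conv[[l]]$b, sp$conv_kernels[l])
    A <- bt_pool_fwd(cf$Y, sp$pool_sizes[l])$Y
  }
  H <- bt_lstm_fwd(A, pr$lstm)$h
  colnames(H) <- paste0("lstm_", seq_len(ncol(H)))
  H
}

#' @export
print.shock_net <- function(x, ...) {
  sp <- x$spec
  kind <- if (sp$lstm_units > 0L) "CNN+LSTM" else "CNN-only"
  cat(sprintf("<shock_net> %s, input %g s x %g Hz (N = %d)\n", kind, x$L,
              x$fs, x$N))
  cat("  conv blocks:", paste(sprintf("%dxM%d/K%d", sp$conv_filters,
                                      sp$conv_kernels, sp$pool_sizes),
                              collapse = " -> "), "\n")
  cat("  length chain:", paste(x$chain, collapse = " -> "), "\n")
  if (sp$lstm_units > 0L) cat("  LSTM units Q =", sp$lstm_units, "\n")
  if (x$fitted)
    cat(sprintf("  fitted: %d epochs, final loss %.4f, threshold %.4f\n",
                nrow(x$history), x$history$loss[nrow(x$history)], x$theta))
  else cat("  (untrained)\n")
  invisible(x)
}

#' @export
summary.shock_net <- function(object, ...) {
  n_par <- sum(rapply(object$params, length, how = "unlist"))
  out <- list(spec = object$spec, n_parameters = n_par, L = object$L,
              fs = object$fs, theta = object$theta, fitted = object$fitted,
              final_loss = if (object$fitted)
                object$history$loss[nrow(object$history)] else NA_real_)
  class(out) <- "summary.shock_net"
  out
}

#' @export
print.summary.shock_net <- function(x, ...) {
  cat(sprintf("shock_net with %d trainable parameters (L = %g s, fs = %g Hz)\n",
              x$n_parameters, x$L, x$fs))
  if (x$fitted)
    cat(sprintf("final training loss %.4f; decision threshold %.4f\n",
                x$final_loss, x$theta))
  invisible(x)
}

#' @export
plot.shock_net <- function(x, ...) {
  if (!x$fitted) stop("nothing to plot: model is untrained")
  graphics::plot(x$history$epoch, x$history$loss, type = "l",
                 xlab = "epoch", ylab = "weighted BCE loss",
                 main = "Training loss", ...)
  invisible(x)
}

#' @export
coef.shock_net <- function(object, ...) object$params

#' Save / load a network checkpoint
#'
#' The checkpoint is a self-describing JSON file holding the architecture,
#' all parameter arrays, the decision threshold and the training
#' configuration.
#'
#' @param model A `shock_net`.
#' @param path Output file path.
#' @return Invisibly `path`; `read_shock_net()` returns the `shock_net`.
#' @export
write_shock_net <- function(model, path) {
  enc <- function(m) if (is.matrix(m)) list(dim = dim(m), data = as.vector(m))
    else m
  obj <- list(spec = unclass(model$spec), L = model$L, fs = model$fs,
              theta = model$theta, seed = model$seed, fitted = model$fitted,
              control = if (!is.null(model$control)) unclass(model$control),
              history = model$history,
              params = rapply(model$params, enc, how = "replace",
                              classes = c("matrix", "numeric", "integer")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "columns")
  invisible(path)
}

#' @rdname write_shock_net
#' @export
read_shock_net <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  dec <- function(x) {
    if (is.list(x) && !is.null(x$dim))
      matrix(as.numeric(x$data), x$dim[1], x$dim[2])
    else if (is.list(x)) lapply(x, dec)
    else x
  }
  spec_fields <- lapply(obj$spec, function(v)
    if (is.list(v) && !length(v)) integer(0) else unlist(v))
  sp <- do.call(net_spec, spec_fields)
  model <- build_network(sp, obj$L, obj$fs, obj$seed %||% 1L)
  model$params <- dec(obj$params)
  model$theta <- obj$theta %||% NA_real_
  model$fitted <- isTRUE(obj$fitted)
  if (!is.null(obj$history)) model$history <- as.data.frame(obj$history)
  if (!is.null(obj$control)) model$control <- do.call(train_control, obj$control)
  model
}
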