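# Gaussian-kernel SVM baselines: classical VF-detection features, Bayesian
# hyperparameter search, outlier trimming, and SVMs on learned LSTM features.
# The soft-margin dual is solved by libsvm (via e1071); the package stores an
# explicit support-vector expansion so the decision function can be
# re-evaluated independently.

#' Gaussian (RBF) kernel
#'
#' `exp(-gamma * ||x - x'||^2)`.
#'
#' @param x,xp Numeric vectors of equal length.
#' @param gamma Positive kernel width parameter.
#' @return Kernel value in (0, 1].
#' @export
rbf_kernel <- function(x, xp, gamma) {
  if (length(x) != length(xp)) stop("vectors must have equal dimension")
  if (gamma <= 0) stop("`gamma` must be positive")
  exp(-gamma * sum((x - xp)^2))
}

#' Fit a Gaussian-kernel SVM
#'
#' Solves the weighted soft-margin dual (libsvm) on standardized features
#' and stores the support-vector expansion: support vectors, multipliers
#' `alpha_i`, labels `y_i`, bias `b`, and the training-set standardization
#' constants. Per-class instance weighting scales the box constraint, so
#' `0 <= alpha_i <= C * weight_class(i)`.
#'
#' @param X Numeric feature matrix (instances x features).
#' @param y Labels in -1/+1 (or 0/1, or `"Sh"`/`"NSh"`; +1 = shockable).
#' @param C Soft-margin parameter.
#' @param gamma Kernel width; defaults to `1 / ncol(X)`.
#' @param weights Named per-class weights (`"1"`, `"-1"`); `NULL` balances
#'   the classes via [class_weights()] logic.
#' @return An object of class `shock_svm`.
#' @export
fit_svm <- function(X, y, C = 1, gamma = 1 / ncol(X), weights = NULL) {
  X <- as.matrix(X)
  y <- as_pm1(y)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, ctr, scl)
  if (is.null(weights)) {
    n <- length(y)
    weights <- c("1" = n / (2 * sum(y == 1)), "-1" = n / (2 * sum(y == -1)))
  }
  fit <- e1071::svm(Xs, factor(y, levels = c(1, -1), labels = c("1", "-1")),
                    scale = FALSE, kernel = "radial", cost = C, gamma = gamma,
                    class.weights = weights)
  coefs <- as.numeric(fit$coefs)      # alpha_i * y_i, libsvm orientation
  b <- -fit$rho
  sv <- as.matrix(fit$SV)
  # align the stored expansion with our +1 = shockable convention
  dv <- as.numeric(attr(stats::predict(fit, Xs[1:min(5, nrow(Xs)), , drop = FALSE],
                                       decision.values = TRUE),
                        "decision.values"))
  lab <- stats::predict(fit, Xs[1:min(5, nrow(Xs)), , drop = FALSE])
  flip <- any(dv > 0 & lab == "-1") || any(dv < 0 & lab == "1")
  if (flip) { coefs <- -coefs; b <- -b }
  structure(list(sv = sv, alpha = abs(coefs), ysv = sign(coefs),
                 coefs = coefs, b = b, gamma = gamma, C = C,
                 class_weights = weights, center = ctr, scale = scl,
                 feature_names = colnames(X), n_features = ncol(X)),
            class = "shock_svm")
}

as_pm1 <- function(y) {
  if (is.character(y) || is.factor(y)) return(ifelse(as.character(y) == "Sh", 1, -1))
  y <- as.numeric(y)
  if (all(y %in% c(0, 1))) return(ifelse(y == 1, 1, -1))
  if (all(y %in% c(-1, 1))) return(y)
  stop("labels must be -1/+1, 0/1 or 'Sh'/'NSh'")
}

#' SVM decision values and class decisions
#'
#' Evaluates the support-vector expansion
#' `sum_i alpha_i y_i exp(-gamma ||x - x_i||^2) + b` on new instances
#' (standardized with the training constants); `svm_decide()` returns its
#' sign, with 0 mapping to +1.
#'
#' @param model A `shock_svm`.
#' @param X Numeric matrix (instances x features) or a single vector.
#' @return `svm_decision_values()`: numeric vector; `svm_decide()`: vector
#'   of -1/+1.
#' @export
svm_decision_values <- function(model, X) {
  if (is.vector(X)) X <- matrix(X, nrow = 1L)
  if (ncol(X) != model$n_features)
    stop("feature dimension ", ncol(X), " does not match model (",
         model$n_features, ")")
  Xs <- scale(X, model$center, model$scale)
  d2 <- outer(rowSums(Xs^2), rowSums(model$sv^2), "+") -
    2 * tcrossprod(Xs, model$sv)
  drop(exp(-model$gamma * pmax(d2, 0)) %*% model$coefs) + model$b
}

#' @rdname svm_decision_values
#' @export
svm_decide <- function(model, X) {
  f <- svm_decision_values(model, X)
  ifelse(f >= 0, 1, -1)
}

#' @export
predict.shock_svm <- function(object, newdata, type = c("class", "decision"),
                              ...) {
  type <- match.arg(type)
  if (type == "decision") svm_decision_values(object, newdata)
  else svm_decide(object, newdata)
}

#' @export
print.shock_svm <- function(x, ...) {
  cat(sprintf("<shock_svm> RBF SVM: %d support vectors, C = %.4g, gamma = %.4g, b = %.4g\n",
              nrow(x$sv), x$C, x$gamma, x$b))
  invisible(x)
}

#' Discard the worst margin violators
#'
#' Fits once with the supplied hyperparameters, computes the margin
#' violations `xi_i = max(0, 1 - y_i f(x_i))` on the training set, and
#' removes up to `floor(frac * n)` instances with the largest strictly
#' positive violations. On cleanly separable data nothing is removed.
#'
#' @param X Feature matrix.
#' @param y Labels (-1/+1 convention as in [fit_svm()]).
#' @param frac Maximum fraction of instances to discard (default 0.5%).
#' @param C,gamma Hyperparameters of the screening fit.
#' @return List with the reduced `X`, `y` and the integer indices `removed`.
#' @export
trim_outliers <- function(X, y, frac = 0.005, C = 1, gamma = 1 / ncol(X)) {
  if (frac < 0 || frac >= 0.05) stop("`frac` must lie in [0, 0.05)")
  X <- as.matrix(X)
  y <- as_pm1(y)
  n <- nrow(X)
  k <- floor(frac * n)
  removed <- integer(0)
  if (k > 0L) {
    fit <- fit_svm(X, y, C = C, gamma = gamma)
    xi <- pmax(0, 1 - y * svm_decision_values(fit, X))
    viol <- which(xi > 1e-6)
    if (length(viol)) {
      ord <- viol[order(xi[viol], decreasing = TRUE)]
      removed <- sort(ord[seq_len(min(k, length(ord)))])
    }
  }
  keep <- setdiff(seq_len(n), removed)
  list(X = X[keep, , drop = FALSE], y = y[keep], removed = removed)
}

svm_box <- function() c(lo = 1e-3, hi = 2e2)

cv_bac_objective <- function(X, y, groups, folds, seed) {
  rng <- local_rng(seed)
  if (is.null(groups)) groups <- seq_along(y)
  gset <- unique(groups)
  fold_of_group <- stats::setNames(
    rep_len(seq_len(folds), length(gset))[sample.int(length(gset))], gset)
  fold <- fold_of_group[as.character(groups)]
  restore_rng(rng)
  function(C, gamma) {
    pred <- numeric(length(y))
    for (f in seq_len(folds)) {
      tr <- fold != f; te <- !tr
      if (!any(te) || length(unique(y[tr])) < 2L) next
      m <- fit_svm(X[tr, , drop = FALSE], y[tr], C = C, gamma = gamma)
      pred[te] <- svm_decide(m, X[te, , drop = FALSE])
    }
    se <- mean(pred[y == 1] == 1); sp <- mean(pred[y == -1] == -1)
    (se + sp) / 2
  }
}

# GP posterior (squared-exponential kernel, unit-box inputs) for EI search
gp_ei <- function(Z, f, Zc, ls = 0.25, nug = 1e-6) {
  k <- function(A, B) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    exp(-pmax(d2, 0) / (2 * ls^2))
  }
  sf2 <- max(stats::var(f), 1e-12)
  K <- sf2 * k(Z, Z) + diag(nug + 1e-10, nrow(Z))
  Ks <- sf2 * k(Zc, Z)
  Kc <- chol(K)
  al <- backsolve(Kc, forwardsolve(t(Kc), f - mean(f)))
  mu <- mean(f) + Ks %*% al
  V <- backsolve(Kc, forwardsolve(t(Kc), t(Ks)))   # K^{-1} Ks^T
  s2 <- pmax(sf2 - colSums(t(Ks) * V), 1e-12)
  s <- sqrt(s2)
  best <- max(f)
  z <- (mu - best) / s
  ei <- (mu - best) * stats::pnorm(z) + s * stats::dnorm(z)
  list(mu = drop(mu), s = s, ei = drop(ei))
}

#' Bayesian hyperparameter search for the SVM
#'
#' Gaussian-process Bayesian optimization (expected-improvement
#' acquisition) of the soft-margin parameter `C` and kernel width `gamma`
#' over the box `[1e-3, 2e2]^2`, searched log-uniformly. The objective is
#' patient-grouped k-fold cross-validated balanced accuracy. Deterministic
#' given the seed.
#'
#' @param X Feature matrix.
#' @param y Labels.
#' @param seed Integer seed.
#' @param groups Optional grouping vector (e.g. patient ids) for grouped CV.
#' @param n_init Latin-hypercube initial design size.
#' @param n_iter Total number of objective evaluations (>= `n_init`).
#' @param folds Number of CV folds.
#' @return Named vector `c(C, gamma)` inside the search box.
#' @export
tune_hyperparams <- function(X, y, seed, groups = NULL, n_init = 10L,
                             n_iter = 60L, folds = 5L) {
  X <- as.matrix(X)
  y <- as_pm1(y)
  box <- log10(svm_box())
  obj <- cv_bac_objective(X, y, groups, folds, seed)
  rng <- local_rng(seed + 1L)
  on.exit(restore_rng(rng))
  Z <- lhs::maximinLHS(n_init, 2L)       # unit box; maps to log10 scale
  to_par <- function(z) 10^(box["lo"] + z * (box["hi"] - box["lo"]))
  f <- apply(Z, 1L, function(z) { p <- to_par(z); obj(p[1], p[2]) })
  while (nrow(Z) < n_iter) {
    if (max(f) - min(f) < 1e-12) break
    cand <- matrix(stats::runif(2 * 256L), ncol = 2L)
    post <- gp_ei(Z, f, cand)
    znew <- cand[which.max(post$ei), , drop = FALSE]
    pnew <- to_par(drop(znew))
    Z <- rbind(Z, znew)
    f <- c(f, obj(pnew[1], pnew[2]))
  }
  if (max(f) - min(f) < 1e-12) {
    warning("objective is constant over the search box; returning its center")
    ctr <- to_par(c(0.5, 0.5))
    return(c(C = unname(ctr[1]), gamma = unname(ctr[2])))
  }
  best <- to_par(Z[which.max(f), ])
  c(C = unname(best[1]), gamma = unname(best[2]))
}

#' Registry of classical VF-detection features
#'
#' A documented, representative registry of waveform features spanning the
#' classical analysis domains: amplitude, slope, rate, spectral shape and
#' complexity.
#'
#' @return Character vector of feature names.
#' @export
classical_feature_registry <- function() {
  c("mean_abs_slope", "dominant_freq", "spectral_flatness",
    "band_power_ratio", "crossing_rate", "p2p_amplitude", "kurtosis",
    "sample_entropy", "mean_abs_value")
}

#' Compute classical VF-detection features for one segment
#'
#' Features: mean absolute slope (mV/s); dominant spectral frequency in
#' 0.5-30 Hz (Hz); spectral flatness of the band power; band-power ratio
#' (0.5-9 Hz over 9-30 Hz); threshold-crossing rate (crossings/s of the
#' level 0.2 max|x|); peak-to-peak amplitude (mV); excess kurtosis; sample
#' entropy (m = 2, r = 0.2 sd, on the segment decimated to at most 500
#' samples); mean absolute value (mV).
#'
#' @param x Numeric vector, a preprocessed segment in millivolts.
#' @param fs Sampling rate in Hz.
#' @param registry Character vector of requested features (subset of
#'   [classical_feature_registry()]).
#' @return Named numeric vector of finite feature values.
#' @export
compute_classical_features <- function(x, fs,
                                       registry = classical_feature_registry()) {
  bad <- setdiff(registry, classical_feature_registry())
  if (length(bad)) stop("unknown feature name(s): ", paste(bad, collapse = ", "))
  n <- length(x)
  xd <- x - mean(x)
  P <- Mod(stats::fft(xd))^2 / n
  fr <- (seq_len(n) - 1) * fs / n
  band <- fr >= 0.5 & fr <= 30
  Pb <- P[band]; frb <- fr[band]
  feats <- c(
    mean_abs_slope = mean(abs(diff(x))) * fs,
    dominant_freq = if (sum(Pb) > 0) frb[which.max(Pb)] else 0,
    spectral_flatness = if (sum(Pb) > 0)
      exp(mean(log(Pb + 1e-12))) / (mean(Pb) + 1e-12) else 0,
    band_power_ratio = {
      lo <- sum(P[fr >= 0.5 & fr < 9]); hi <- sum(P[fr >= 9 & fr <= 30])
      lo / (hi + 1e-12)
    },
    crossing_rate = {
      thr <- 0.2 * max(abs(x))
      if (thr == 0) 0 else sum(diff(x >= thr) != 0) / (n / fs)
    },
    p2p_amplitude = max(x) - min(x),
    kurtosis = {
      s <- stats::sd(x)
      if (s == 0) 0 else mean((x - mean(x))^4) / s^4 - 3
    },
    sample_entropy = sample_entropy(x, fs),
    mean_abs_value = mean(abs(x))
  )
  feats[registry]
}

# Sample entropy, m = 2, r = 0.2 sd (Chebyshev), on a decimated copy.
sample_entropy <- function(x, fs, m = 2L, r_frac = 0.2) {
  if (stats::sd(x) == 0) return(0)
  dec <- max(1L, ceiling(length(x) / 500L))
  x <- x[seq(1L, length(x), by = dec)]
  n <- length(x)
  r <- r_frac * stats::sd(x)
  if (n < m + 2L) return(0)
  D <- abs(outer(x, x, "-")) <= r
  count_m <- function(mm) {
    nn <- n - mm
    M <- D[1:nn, 1:nn]
    for (k in seq_len(mm - 1L)) M <- M & D[(1 + k):(nn + k), (1 + k):(nn + k)]
    (sum(M) - nn) / 2
  }
  B <- count_m(m)
  A <- count_m(m + 1L)
  if (A == 0 || B == 0) return(log(2 * (n - m - 1)))   # capped
  -log(A / B)
}

#' Classical feature matrix for a segment set
#'
#' @param segments A `segment_set`.
#' @param registry Requested feature names.
#' @return Numeric matrix, one row per segment, named columns.
#' @export
classical_feature_matrix <- function(segments,
                                     registry = classical_feature_registry()) {
  t(apply(segments$samples, 1L, compute_classical_features,
          fs = segments$fs, registry = registry))
}

# greedy forward selection with an LDA training-BAC criterion
select_features_lda <- function(X, y, k) {
  y <- as_pm1(y)
  chosen <- integer(0)
  avail <- seq_len(ncol(X))
  for (step in seq_len(k)) {
    sc <- vapply(avail, function(j) {
      Xi <- X[, c(chosen, j), drop = FALSE]
      fit <- tryCatch(MASS::lda(Xi, grouping = factor(y)),
                      error = function(e) NULL)
      if (is.null(fit)) return(-Inf)
      pred <- stats::predict(fit, Xi)$class
      pr <- as.numeric(as.character(pred))
      (mean(pr[y == 1] == 1) + mean(pr[y == -1] == -1)) / 2
    }, numeric(1))
    best <- avail[which.max(sc)]
    chosen <- c(chosen, best)
    avail <- setdiff(avail, best)
  }
  chosen
}

#' SVM on learned LSTM features
#'
#' Extracts the LSTM features of a trained CNN+LSTM network on the training
#' and test sets, selects the best `k`-feature subset on the training data
#' with a linear-discriminant criterion (greedy forward selection), fits a
#' Gaussian-kernel SVM on the selected features, and evaluates on the test
#' set.
#'
#' @param net A fitted CNN+LSTM `shock_net`.
#' @param train_segments,test_segments `segment_set` objects.
#' @param k Number of LSTM features to use (1..Q).
#' @param seed Integer seed (used when `tune = TRUE`).
#' @param tune Run [tune_hyperparams()] on the selected features; otherwise
#'   use `C`, `gamma` as given.
#' @param C,gamma Hyperparameters when `tune = FALSE`; `gamma` defaults to
#'   `1/k`.
#' @param n_iter Evaluations for the Bayesian search when tuning.
#' @return A list with the `metrics` ([confusion_metrics()] report on the
#'   test set), the fitted `model`, and the `selected` feature names.
#' @export
svm_on_lstm_features <- function(net, train_segments, test_segments, k,
                                 seed = 1L, tune = FALSE, C = 1,
                                 gamma = NULL, n_iter = 20L) {
  Q <- net$spec$lstm_units
  if (k < 1L || k > Q) stop("`k` must lie in 1..", Q)
  Htr <- extract_lstm_features(net, train_segments)
  Hte <- extract_lstm_features(net, test_segments)
  ytr <- as_pm1(train_segments$meta$label)
  yte <- as_pm1(test_segments$meta$label)
  sel <- select_features_lda(Htr, ytr, k)
  Xtr <- Htr[, sel, drop = FALSE]; Xte <- Hte[, sel, drop = FALSE]
  if (tune) {
    hp <- tune_hyperparams(Xtr, ytr, seed,
                           groups = train_segments$meta$patient_id,
                           n_iter = n_iter)
    C <- hp["C"]; gamma <- hp["gamma"]
  } else if (is.null(gamma)) gamma <- 1 / k
  model <- fit_svm(Xtr, ytr, C = C, gamma = gamma)
  pred <- svm_decide(model, Xte)
  list(metrics = confusion_metrics(yte == 1, pred == 1),
       model = model, selected = colnames(Htr)[sel])
}
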