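# Evaluation statistics: confusion metrics and balanced accuracy, McNemar
# paired comparison, rank-based AUC, LSTM-feature ranking, Davies-Bouldin
# separability with t-SNE and bootstrap, AHA compliance, error-reduction
# arithmetic.

#' Confusion-matrix metrics for a binary shock decision
#'
#' Sensitivity, specificity, positive/negative predictive values, total
#' accuracy and balanced accuracy `BAC = (Se + Sp) / 2`, all as percentages,
#' plus the raw confusion counts. Positive class = shockable.
#'
#' @param y True labels (logical, 0/1, or `"Sh"`/`"NSh"`).
#' @param y_hat Predicted labels, same conventions (or a factor
#'   `shock`/`no_shock`).
#' @param dataset Optional dataset tag stored in the report.
#' @param L Optional segment length tag (seconds).
#' @return An object of class `metrics_report`.
#' @export
confusion_metrics <- function(y, y_hat, dataset = NA_character_, L = NA_real_) {
  if (length(y) == 0L) stop("empty input")
  if (length(y) != length(y_hat)) stop("y and y_hat must have equal length")
  yb <- as_decision(y); pb <- as_decision(y_hat)
  if (all(yb) || !any(yb)) stop("both classes must be present in y")
  tp <- sum(yb & pb); fn <- sum(yb & !pb)
  tn <- sum(!yb & !pb); fp <- sum(!yb & pb)
  se <- 100 * tp / (tp + fn)
  sp <- 100 * tn / (tn + fp)
  ppv <- if (tp + fp == 0) { warning("PPV undefined (no positive predictions)"); NA_real_ }
    else 100 * tp / (tp + fp)
  npv <- if (tn + fn == 0) { warning("NPV undefined (no negative predictions)"); NA_real_ }
    else 100 * tn / (tn + fn)
  structure(list(Se = se, Sp = sp, PPV = ppv, NPV = npv,
                 Acc = 100 * (tp + tn) / length(yb), BAC = (se + sp) / 2,
                 TP = tp, FP = fp, TN = tn, FN = fn,
                 dataset = dataset, L = L),
            class = "metrics_report")
}

as_decision <- function(v) {
  if (is.logical(v)) return(v)
  if (is.factor(v)) v <- as.character(v)
  if (is.character(v)) {
    if (all(v %in% c("Sh", "NSh"))) return(v == "Sh")
    if (all(v %in% c("shock", "no_shock"))) return(v == "shock")
    stop("unrecognized label coding")
  }
  if (all(v %in% c(-1, 1))) return(v == 1)
  v != 0
}

#' @export
print.metrics_report <- function(x, digits = 1, ...) {
  hdr <- if (!is.na(x$dataset)) paste0(" [", x$dataset,
                                       if (!is.na(x$L)) paste0(", L = ", x$L, " s"), "]")
    else ""
  cat(sprintf("<metrics_report>%s n = %d\n", hdr, x$TP + x$FP + x$TN + x$FN))
  cat(sprintf("  Se %.*f  Sp %.*f  BAC %.*f  Acc %.*f  PPV %s  NPV %s\n",
              digits, x$Se, digits, x$Sp, digits, x$BAC, digits, x$Acc,
              if (is.na(x$PPV)) "NA" else sprintf("%.*f", digits, x$PPV),
              if (is.na(x$NPV)) "NA" else sprintf("%.*f", digits, x$NPV)))
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(dataset = x$dataset, L = x$L, Se = x$Se, Sp = x$Sp, PPV = x$PPV,
             NPV = x$NPV, Acc = x$Acc, BAC = x$BAC, TP = x$TP, FP = x$FP,
             TN = x$TN, FN = x$FN, stringsAsFactors = FALSE)
}

#' McNemar paired comparison of two classifiers
#'
#' Counts the discordant pairs (`b`: A correct, B wrong; `c`: A wrong, B
#' correct) and tests whether A's accuracy exceeds B's. For `b + c < 25` an
#' exact one-sided binomial tail `P(X >= b | n = b + c, 1/2)` is used,
#' otherwise the continuity-corrected chi-square, halved for one-sidedness.
#'
#' @param y True labels.
#' @param y_a,y_b Predictions of classifiers A and B.
#' @return List with `p_value`, `b`, `c`.
#' @export
mcnemar_test <- function(y, y_a, y_b) {
  if (length(y) != length(y_a) || length(y) != length(y_b))
    stop("inputs must have equal length")
  yt <- as_decision(y); pa <- as_decision(y_a); pb <- as_decision(y_b)
  ca <- pa == yt; cb <- pb == yt
  b <- sum(ca & !cb); cc <- sum(!ca & cb)
  n <- b + cc
  if (n == 0L) {
    warning("no discordant pairs; p = 1")
    return(list(p_value = 1, b = b, c = cc))
  }
  p <- if (n < 25L) {
    stats::pbinom(b - 1L, n, 0.5, lower.tail = FALSE)
  } else {
    x2 <- (abs(b - cc) - 1)^2 / n
    half <- stats::pchisq(x2, df = 1, lower.tail = FALSE) / 2
    if (b > cc) half else 1 - half
  }
  list(p_value = min(max(p, 0), 1), b = b, c = cc)
}

#' Rank-based (Mann-Whitney) AUC
#'
#' Area under the ROC curve computed from ranks with ties averaged,
#' expressed as a percentage.
#'
#' @param scores Numeric scores (larger = more shockable).
#' @param y Binary labels; both classes required.
#' @return AUC in `[0, 100]`.
#' @export
auc_score <- function(scores, y) {
  yb <- as_decision(y)
  n1 <- sum(yb); n0 <- sum(!yb)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  100 * (sum(r[yb]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Rank the learned LSTM features by test-set AUC
#'
#' Computes the Q LSTM features of a trained network on the test set (no
#' retraining) and one AUC per feature, on the complete test set and within
#' each source database, sorted by descending complete-set AUC.
#'
#' @param model A fitted CNN+LSTM `shock_net`.
#' @param test_segments Test `segment_set`.
#' @return Data frame with `feature`, `auc_complete`, and one `auc_<db>`
#'   column per source database present.
#' @export
rank_lstm_features <- function(model, test_segments) {
  if (nrow(test_segments$samples) == 0L) stop("empty test set")
  H <- extract_lstm_features(model, test_segments)
  y <- test_segments$meta$label
  out <- data.frame(feature = colnames(H),
                    auc_complete = apply(H, 2L, auc_score, y = y),
                    stringsAsFactors = FALSE)
  for (db in unique(test_segments$meta$source_db)) {
    i <- test_segments$meta$source_db == db
    out[[paste0("auc_", db)]] <- if (length(unique(y[i])) == 2L)
      apply(H[i, , drop = FALSE], 2L, auc_score, y = y[i]) else NA_real_
  }
  out <- out[order(-out$auc_complete), ]
  rownames(out) <- NULL
  out
}

#' Davies-Bouldin cluster-separability index
#'
#' Mean over clusters of `max_{j != i} (s_i + s_j) / d_ij`, where `s_i` is
#' the mean distance of cluster members to their centroid and `d_ij` the
#' distance between centroids. Lower is better separated.
#'
#' @param points Numeric matrix of coordinates (rows = instances).
#' @param labels Cluster labels (>= 2 non-empty clusters).
#' @return The index; `Inf` (with a warning) for coincident centroids.
#' @export
davies_bouldin <- function(points, labels) {
  points <- as.matrix(points)
  labs <- unique(labels)
  if (length(labs) < 2L) stop("need at least 2 clusters")
  cent <- t(vapply(labs, function(l)
    colMeans(points[labels == l, , drop = FALSE]), numeric(ncol(points))))
  s <- vapply(seq_along(labs), function(i) {
    P <- points[labels == labs[i], , drop = FALSE]
    mean(sqrt(rowSums((P - matrix(cent[i, ], nrow(P), ncol(P),
                                  byrow = TRUE))^2)))
  }, numeric(1))
  k <- length(labs)
  r <- numeric(k)
  for (i in seq_len(k)) {
    d <- sqrt(rowSums((cent - matrix(cent[i, ], k, ncol(cent),
                                     byrow = TRUE))^2))
    ratio <- (s[i] + s[-i]) / d[-i]
    if (any(!is.finite(ratio))) {
      warning("coincident centroids; index is infinite")
      return(Inf)
    }
    r[i] <- max(ratio)
  }
  mean(r)
}

#' Separability of learned vs classical features
#'
#' Embeds each feature set to 2-D with t-SNE, computes the Davies-Bouldin
#' index of the two classes on `B` paired bootstrap resamples of the
#' embedded points, and reports the mean, standard deviation, and the
#' paired bootstrap p-value `P(db_lstm >= db_classical)`.
#'
#' @param classical_features,lstm_features Numeric matrices over the same
#'   instances.
#' @param labels Binary class labels for the instances.
#' @param B Number of bootstrap replicas (>= 2).
#' @param seed Integer seed (t-SNE initialization and resampling).
#' @param perplexity,max_iter t-SNE settings (see [tsne_embed()]).
#' @return List with `db_classical`, `db_lstm` (each `c(mean, sd)`),
#'   `p_value`, and the two embeddings.
#' @export
separability_experiment <- function(classical_features, lstm_features, labels,
                                    B = 1000L, seed = 1L, perplexity = 30,
                                    max_iter = 1000L) {
  if (B < 2L) stop("`B` must be >= 2")
  if (nrow(classical_features) != nrow(lstm_features))
    stop("feature sets must cover the same instances")
  yc <- tsne_embed(classical_features, perplexity = perplexity,
                   max_iter = max_iter, seed = seed)
  yl <- tsne_embed(lstm_features, perplexity = perplexity,
                   max_iter = max_iter, seed = seed + 1L)
  n <- nrow(yc)
  rng <- local_rng(seed + 2L)
  on.exit(restore_rng(rng))
  dbc <- numeric(B); dbl <- numeric(B)
  for (r in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[idx])) == 2L) break
    }
    dbc[r] <- davies_bouldin(yc[idx, , drop = FALSE], labels[idx])
    dbl[r] <- davies_bouldin(yl[idx, , drop = FALSE], labels[idx])
  }
  list(db_classical = c(mean = mean(dbc), sd = stats::sd(dbc)),
       db_lstm = c(mean = mean(dbl), sd = stats::sd(dbl)),
       p_value = mean(dbl >= dbc),
       embedding_classical = yc, embedding_lstm = yl)
}

#' AHA compliance of a shock-decision algorithm
#'
#' The minimum performance goals are 90% sensitivity for shockable rhythms
#' and 95% specificity for nonshockable rhythms (inclusive bounds).
#'
#' @param se,sp Sensitivity and specificity in percent.
#' @return `TRUE` iff `se >= 90` and `sp >= 95`.
#' @export
aha_check <- function(se, sp) {
  stopifnot(se >= 0, se <= 100, sp >= 0, sp <= 100)
  se >= 90 & sp >= 95
}

#' Fraction of classification errors corrected
#'
#' `100 * (acc_new - acc_old) / (100 - acc_old)`: the share of the old
#' model's errors removed by the new one.
#'
#' @param acc_old,acc_new Accuracies in percent; `acc_old < 100`.
#' @return Percentage of errors corrected.
#' @export
error_reduction <- function(acc_old, acc_new) {
  if (any(acc_old >= 100)) stop("undefined for acc_old = 100 (no errors to correct)")
  100 * (acc_new - acc_old) / (100 - acc_old)
}
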