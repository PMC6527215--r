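# Experiment orchestration: end-to-end training/evaluation with patient-wise
# splitting, model comparison via McNemar, and the segment-length sweep.

#' Preprocess an annotated record
#'
#' Applies the AED conditioning chain to the record's samples, keeping the
#' annotations.
#'
#' @param rec An [ecg_record()].
#' @param cfg A [preprocess_config()].
#' @return The conditioned [ecg_record()].
#' @export
preprocess_record <- function(rec, cfg = preprocess_config()) {
  rec$samples <- preprocess_ecg(rec$samples, rec$fs, cfg)
  rec
}

#' Experiment configuration
#'
#' Bundles the data source, model roster and all stage configurations of an
#' end-to-end experiment. The default is the desk-scale profile: a 20-patient
#' synthetic cohort and 50 training epochs in batches of 32; pass
#' `train = train_control()` for the full-scale recipe (600 epochs, batches
#' of 256).
#'
#' @param cohort A [cohort_config()] describing the synthetic data source,
#'   or `NULL` when `records` are supplied directly to [run_experiment()].
#' @param length Segment length in seconds for a single experiment.
#' @param lengths Lengths for [sweep_segment_lengths()].
#' @param models Character roster; any of `"proposed"`, `"kiranyaz"`,
#'   `"zubair"`, `"acharya"`, `"svm_classical"`, `"svm_lstm"`.
#' @param train A [train_control()].
#' @param preprocess A [preprocess_config()].
#' @param split_seed Seed of the patient-wise split.
#' @param split_frac Training fraction of patients per database.
#' @param svm_tune Run Bayesian hyperparameter search for the SVM models.
#' @param svm_tune_iter Objective evaluations for that search.
#' @param svm_trim Apply outlier trimming before the final SVM fit.
#' @param svm_lstm_k Number of LSTM features for the `svm_lstm` model.
#' @param out_dir Output directory for reports/checkpoints (`NULL` = none).
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_config(), length = 4,
                              lengths = c(2, 3, 4, 8),
                              models = c("proposed", "kiranyaz"),
                              train = train_control(epochs = 50L,
                                                    batch_size = 32L),
                              preprocess = preprocess_config(),
                              split_seed = 1L, split_frac = 0.8,
                              svm_tune = FALSE, svm_tune_iter = 15L,
                              svm_trim = TRUE, svm_lstm_k = 20L,
                              out_dir = NULL) {
  known <- c("proposed", "kiranyaz", "zubair", "acharya", "svm_classical",
             "svm_lstm")
  bad <- setdiff(models, known)
  if (length(bad)) stop("unknown model(s): ", paste(bad, collapse = ", "))
  if (!length(models)) stop("need at least one model")
  stopifnot(all(lengths > 0), length > 0)
  structure(list(cohort = cohort, length = length, lengths = lengths,
                 models = models, train = train, preprocess = preprocess,
                 split_seed = as.integer(split_seed), split_frac = split_frac,
                 svm_tune = isTRUE(svm_tune),
                 svm_tune_iter = as.integer(svm_tune_iter),
                 svm_trim = isTRUE(svm_trim),
                 svm_lstm_k = as.integer(svm_lstm_k), out_dir = out_dir),
            class = "experiment_config")
}

# preprocess + split + segment at one length
prepare_data <- function(records, cfg, L) {
  records <- lapply(records, preprocess_record, cfg = cfg$preprocess)
  split <- split_patients(records, cfg$split_frac, cfg$split_seed)
  sets <- lapply(records, extract_segments, L = L)
  nonempty <- vapply(sets, function(s) nrow(s$samples) > 0L, logical(1))
  sets <- sets[nonempty]
  ids <- vapply(sets, function(s) s$meta$patient_id[1], character(1))
  train <- bind_segment_sets(sets[ids %in% split$train_ids])
  test <- bind_segment_sets(sets[ids %in% split$test_ids])
  list(train = train, test = test, split = split)
}

fit_one_model <- function(name, train, cfg, proposed = NULL, test = NULL) {
  if (name == "proposed")
    return(shock_net(train, net_spec(), cfg$train))
  if (name %in% c("kiranyaz", "zubair", "acharya"))
    return(shock_net(train, build_variant(name), cfg$train))
  if (name == "svm_classical") {
    X <- classical_feature_matrix(train)
    y <- as_pm1(train$meta$label)
    if (cfg$svm_tune) {
      hp <- tune_hyperparams(X, y, cfg$train$seed,
                             groups = train$meta$patient_id,
                             n_iter = cfg$svm_tune_iter)
      C <- hp["C"]; gamma <- hp["gamma"]
    } else { C <- 1; gamma <- 1 / ncol(X) }
    if (cfg$svm_trim) {
      tr <- trim_outliers(X, y, C = C, gamma = gamma)
      X <- tr$X; y <- tr$y
    }
    return(fit_svm(X, y, C = C, gamma = gamma))
  }
  if (name == "svm_lstm") {
    if (is.null(proposed))
      stop("svm_lstm requires the proposed CNN+LSTM model in the roster")
    return(svm_on_lstm_features(proposed, train, test,
                                k = min(cfg$svm_lstm_k,
                                        proposed$spec$lstm_units),
                                seed = cfg$train$seed, tune = cfg$svm_tune,
                                n_iter = cfg$svm_tune_iter))
  }
  stop("unknown model: ", name)
}

predict_decisions <- function(name, model, segments) {
  if (inherits(model, "shock_net"))
    predict(model, segments, type = "decision") == "shock"
  else if (inherits(model, "shock_svm"))
    svm_decide(model, classical_feature_matrix(segments)) == 1
  else stop("cannot predict with model ", name)
}

#' Run an end-to-end experiment
#'
#' Patient-wise split, preprocessing, segment extraction, training of every
#' model in the roster on the merged training data, and evaluation on the
#' test set (complete and per source database), with a pairwise McNemar
#' comparison table. Fully deterministic given the configuration seeds.
#'
#' @param cfg An [experiment_config()].
#' @param records Optional list of [ecg_record()] objects; by default the
#'   synthetic cohort described by `cfg$cohort` is generated.
#' @return A list of class `shock_experiment`: `metrics` (data frame),
#'   `mcnemar` (data frame), `models`, `split`, `train`, `test`.
#' @export
run_experiment <- function(cfg = experiment_config(), records = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (is.null(records)) {
    if (is.null(cfg$cohort)) stop("no data source: supply records or a cohort config")
    records <- gen_cohort(cfg$cohort)
  }
  dat <- prepare_data(records, cfg, cfg$length)
  for (side in c("train", "test"))
    if (length(unique(dat[[side]]$meta$label)) < 2L)
      stop("the ", side, " set contains a single class; use a larger cohort ",
           "or a different split seed")
  models <- list(); decisions <- list()
  roster <- cfg$models
  # the proposed net must be fitted before svm_lstm can reuse its features
  if ("svm_lstm" %in% roster && !"proposed" %in% roster)
    roster <- c("proposed", roster)
  roster <- unique(roster[order(roster != "proposed")])
  for (name in roster) {
    fit <- fit_one_model(name, dat$train, cfg, proposed = models$proposed,
                         test = dat$test)
    if (name == "svm_lstm") {
      models[[name]] <- fit$model
      Hte <- extract_lstm_features(models$proposed, dat$test)
      sel <- match(fit$selected, colnames(Hte))
      decisions[[name]] <- svm_decide(fit$model,
                                      Hte[, sel, drop = FALSE]) == 1
    } else {
      models[[name]] <- fit
      decisions[[name]] <- predict_decisions(name, fit, dat$test)
    }
  }
  y <- dat$test$meta$label
  metrics <- list()
  subsets <- c(list(complete = rep(TRUE, length(y))),
               lapply(stats::setNames(nm = unique(dat$test$meta$source_db)),
                      function(db) dat$test$meta$source_db == db))
  for (name in names(decisions)) for (sub in names(subsets)) {
    i <- subsets[[sub]]
    if (length(unique(y[i])) < 2L) next
    rep_ <- confusion_metrics(y[i], decisions[[name]][i], dataset = sub,
                              L = cfg$length)
    metrics[[length(metrics) + 1L]] <- cbind(model = name,
                                             as.data.frame(rep_))
  }
  metrics <- do.call(rbind, metrics)
  pairs <- if (length(decisions) >= 2L)
    utils::combn(names(decisions), 2L, simplify = FALSE) else list()
  mcn <- do.call(rbind, lapply(pairs, function(pr) {
    mt <- mcnemar_test(y, decisions[[pr[1]]], decisions[[pr[2]]])
    data.frame(model_a = pr[1], model_b = pr[2], b = mt$b, c = mt$c,
               p_value = mt$p_value, stringsAsFactors = FALSE)
  }))
  if (is.null(mcn))
    mcn <- data.frame(model_a = character(), model_b = character(),
                      b = integer(), c = integer(), p_value = numeric())
  out <- structure(list(metrics = metrics, mcnemar = mcn, models = models,
                        decisions = decisions, split = dat$split,
                        train = dat$train, test = dat$test, config = cfg),
                   class = "shock_experiment")
  if (!is.null(cfg$out_dir)) write_experiment(out, cfg$out_dir)
  out
}

#' @export
print.shock_experiment <- function(x, ...) {
  cat("<shock_experiment>", length(x$models), "model(s), L =",
      x$config$length, "s\n")
  print(x$metrics[x$metrics$dataset == "complete",
                  c("model", "Se", "Sp", "BAC", "Acc")], row.names = FALSE)
  invisible(x)
}

write_experiment <- function(exp, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.csv(exp$metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(exp$mcnemar, file.path(out_dir, "mcnemar.csv"),
                   row.names = FALSE)
  manifest <- list(models = names(exp$models),
                   length = exp$config$length,
                   split_seed = exp$config$split_seed,
                   train_seed = exp$config$train$seed,
                   n_train = nrow(exp$train$samples),
                   n_test = nrow(exp$test$samples),
                   train_ids = exp$split$train_ids,
                   test_ids = exp$split$test_ids)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (name in names(exp$models))
    if (inherits(exp$models[[name]], "shock_net"))
      write_shock_net(exp$models[[name]],
                      file.path(out_dir, paste0(name, "_checkpoint.json")))
  invisible(out_dir)
}

#' Segment-length sweep
#'
#' Retrains and evaluates the configured models at each segment length,
#' reporting Se/Sp/BAC per (model, length) together with the AHA compliance
#' flag and, for LSTM models, the temporal length of the feature map
#' entering the recurrent block.
#'
#' @param cfg An [experiment_config()].
#' @param lengths Segment lengths in seconds; defaults to `cfg$lengths`.
#' @param records Optional explicit record list (one cohort reused across
#'   lengths).
#' @return Data frame with one row per (model, dataset, length).
#' @export
sweep_segment_lengths <- function(cfg = experiment_config(),
                                  lengths = cfg$lengths, records = NULL) {
  if (is.null(records)) records <- gen_cohort(cfg$cohort)
  out <- list()
  for (L in lengths) {
    cfg_l <- cfg; cfg_l$length <- L; cfg_l$out_dir <- NULL
    exp <- run_experiment(cfg_l, records = records)
    m <- exp$metrics
    m$aha_compliant <- aha_check(m$Se, m$Sp)
    m$lstm_seq_len <- vapply(m$model, function(nm) {
      md <- exp$models[[nm]]
      if (inherits(md, "shock_net") && md$spec$lstm_units > 0L)
        md$seq_len else NA_integer_
    }, integer(1))
    out[[length(out) + 1L]] <- m
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (!is.null(cfg$out_dir)) {
    if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
    utils::write.csv(res, file.path(cfg$out_dir, "length_sweep.csv"),
                     row.names = FALSE)
  }
  res
}
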