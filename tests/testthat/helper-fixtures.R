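# Shared fixtures: small synthetic cohorts, WFDB writers, and a cached
# small trained network so several test files can reuse one training run.

.fixture_cache <- new.env(parent = emptyenv())

# separable two-class segment set: organized (sinus) vs VF morphologies
make_separable_segments <- function(n_per_class = 100, L = 2, fs = 250,
                                    seed = 42) {
  n <- round(L * fs)
  rows <- matrix(0, 2 * n_per_class, n)
  for (i in seq_len(n_per_class)) {
    rows[i, ] <- gen_sinus(80, 1, fs, L, jitter = 0.05, seed = seed + i)
    rows[n_per_class + i, ] <- gen_vf(5, 0.8, fs = fs, dur = L,
                                      seed = seed + 1000 + i)
  }
  meta <- data.frame(
    patient_id = rep(sprintf("p%02d", rep(1:10, length.out = n_per_class)), 2),
    source_db = "synthetic",
    rhythm = rep(c("NSR", "VF"), each = n_per_class),
    label = rep(c("NSh", "Sh"), each = n_per_class),
    t_start = 0, stringsAsFactors = FALSE)
  segment_set(rows, meta, L, fs)
}

# one small CNN+LSTM trained on the separable cohort, cached across tests
get_tiny_trained_net <- function() {
  if (!is.null(.fixture_cache$net)) return(.fixture_cache$net)
  segs <- make_separable_segments(60, L = 2)
  ctrl <- train_control(epochs = 30L, batch_size = 32L, seed = 11L)
  net <- shock_net(segs, net_spec(), ctrl)
  .fixture_cache$net <- net
  .fixture_cache$net_train <- segs
  net
}

get_tiny_train_segments <- function() {
  get_tiny_trained_net()
  .fixture_cache$net_train
}

# held-out segments from the same distribution
make_separable_test_segments <- function(n_per_class = 40, L = 2) {
  make_separable_segments(n_per_class, L = L, seed = 9000)
}

# ---- WFDB binary writers (test-only; real files are produced elsewhere) ----

write_wfdb_212 <- function(dir, name, channels, fs = 250, gain = 200,
                           baseline = 0) {
  n_sig <- ncol(channels)
  n <- nrow(channels)
  hea <- c(sprintf("%s %d %g %d", name, n_sig, fs, n),
           vapply(seq_len(n_sig), function(i)
             sprintf("%s.dat 212 %g(%g)/mV 12 0 0 0 0 sig%d", name, gain,
                     baseline, i), character(1)))
  writeLines(hea, file.path(dir, paste0(name, ".hea")))
  vals <- as.integer(t(channels))           # frame-interleaved
  if (length(vals) %% 2L == 1L) vals <- c(vals, 0L)
  v <- ifelse(vals < 0, vals + 4096L, vals)
  s1 <- v[seq(1, length(v), by = 2)]
  s2 <- v[seq(2, length(v), by = 2)]
  bytes <- as.raw(rbind(bitwAnd(s1, 0xFF),
                        bitwOr(bitwShiftR(s1, 8), bitwShiftL(bitwAnd(bitwShiftR(s2, 8), 0x0F), 4)),
                        bitwAnd(s2, 0xFF)))
  writeBin(bytes, file.path(dir, paste0(name, ".dat")))
  invisible(file.path(dir, name))
}

# .atr writer: rhythm-change annotations (code 28 '+') with aux strings
write_wfdb_atr <- function(dir, name, times, aux_strings) {
  con <- file(file.path(dir, paste0(name, ".atr")), "wb")
  on.exit(close(con))
  t_prev <- 0
  for (k in seq_along(times)) {
    dt <- times[k] - t_prev
    t_prev <- times[k]
    if (dt > 1023) {
      writeBin(as.integer(c(bitwShiftL(59L, 10))), con, size = 2,
               endian = "little")
      writeBin(as.integer(c(bitwShiftR(dt, 16), bitwAnd(dt, 65535L))), con,
               size = 2, endian = "little")
      dt <- 0L
    }
    writeBin(as.integer(bitwOr(bitwShiftL(28L, 10), dt)), con, size = 2,
             endian = "little")
    aux <- aux_strings[k]
    len <- nchar(aux)
    writeBin(as.integer(bitwOr(bitwShiftL(63L, 10), len)), con, size = 2,
             endian = "little")
    writeBin(charToRaw(aux), con)
    if (len %% 2L == 1L) writeBin(as.raw(0), con)
  }
  writeBin(as.integer(0L), con, size = 2, endian = "little")
  invisible(file.path(dir, paste0(name, ".atr")))
}

# tiny random LSTM parameter set
random_lstm_params <- function(J, Q, seed = 1) {
  set.seed(seed)
  m <- function(r, c) matrix(rnorm(r * c, sd = 0.5), r, c)
  list(Wf = m(J, Q), Wi = m(J, Q), Wo = m(J, Q), Wc = m(J, Q),
       Rf = m(Q, Q), Ri = m(Q, Q), Ro = m(Q, Q), Rc = m(Q, Q),
       bf = rnorm(Q), bi = rnorm(Q), bo = rnorm(Q), bc = rnorm(Q))
}
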