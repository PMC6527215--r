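test_that("sinus generator hits the requested rate and amplitude and is seeded", {
  fs <- 250
  s <- gen_sinus(80, 1, fs, 10, jitter = 0, seed = 4)
  m <- measure_segment(s, fs)
  expect_lt(abs(m["rate"] - 80), 5)
  expect_true(m["p2p_amp"] >= 1500 && m["p2p_amp"] <= 2500)
  expect_identical(s, gen_sinus(80, 1, fs, 10, jitter = 0, seed = 4))
  expect_false(identical(s, gen_sinus(80, 1, fs, 10, jitter = 0, seed = 5)))
  expect_error(gen_sinus(10, 1, fs, 10), "rate")
})

test_that("VF generator concentrates power at its center frequency and scales linearly", {
  fs <- 250
  v <- gen_vf(5, 0.8, fs = fs, dur = 10, seed = 6)
  P <- Mod(fft(v - mean(v)))^2
  fr <- (seq_along(v) - 1) * fs / length(v)
  half <- fr <= fs / 2
  expect_lt(abs(fr[half][which.max(P[half])] - 5), 1)
  v2 <- gen_vf(5, 1.6, fs = fs, dur = 10, seed = 6)
  p2p <- function(x) max(x) - min(x)
  expect_equal(p2p(v2) / p2p(v), 2, tolerance = 0.05)
  # irregularity contrast: VF decorrelates faster than a sinus train at lag = one period
  lag <- round(fs / 5)
  ac <- function(x, k) cor(x[1:(length(x) - k)], x[(k + 1):length(x)])
  s <- gen_sinus(60, 1, fs, 10, jitter = 0, seed = 6)
  expect_lt(ac(v, lag), ac(s, round(fs * 1)))
})

test_that("edge-case signals trip the intended exclusion rules", {
  fs <- 250
  for (seed in 1:5) {
    a <- gen_edge_case("asystole", fs, 10, seed)
    m <- measure_segment(a$signal, fs)
    expect_lt(m["p2p_amp"], 100)
    expect_equal(check_special_rhythm(m["rate"], m["peak_amp"], m["p2p_amp"],
                                      "NSR"), "AS")
    f <- gen_edge_case("fine_vf", fs, 10, seed)
    mf <- measure_segment(f$signal, fs)
    expect_equal(check_special_rhythm(mf["rate"], mf["peak_amp"],
                                      mf["p2p_amp"], "VF"), "fine_VF")
    sv <- gen_edge_case("slow_vt", fs, 10, seed)
    ms <- measure_segment(sv$signal, fs)
    expect_equal(check_special_rhythm(ms["rate"], ms["peak_amp"],
                                      ms["p2p_amp"], "VT"), "slow_VT")
    expect_equal(to_binary_label("slow_VT"), "excluded")
  }
})

test_that("cohorts carry valid labels, the target imbalance, and per-patient variety", {
  expect_error(cohort_config(n_patients = 1), "2 patients")
  expect_error(cohort_config(imbalance_ratio = 0), "positive")
  expect_error(cohort_config(imbalance_ratio = Inf), "finite")
  cfg <- cohort_config(n_patients = 20, seed = 7)
  recs <- gen_cohort(cfg)
  expect_length(recs, 20)
  labs <- unlist(lapply(recs, function(r) r$rhythm_intervals$label))
  expect_true(all(labs %in% rhythm_vocabulary()))
  expect_false(identical(recs[[1]]$samples, recs[[2]]$samples))
  segs <- bind_segment_sets(lapply(lapply(recs, preprocess_record),
                                   extract_segments, L = 4))
  tab <- table(segs$meta$label)
  ratio <- tab[["NSh"]] / tab[["Sh"]]
  expect_gte(ratio, 3); expect_lte(ratio, 5)
  .fixture_cache$cohort20 <- recs
  .fixture_cache$cohort20_segs <- segs
})

test_that("shockable and nonshockable segments differ in frequency and amplitude", {
  segs <- .fixture_cache$cohort20_segs
  if (is.null(segs)) {
    recs <- gen_cohort(cohort_config(n_patients = 20, seed = 7))
    segs <- bind_segment_sets(lapply(lapply(recs, preprocess_record),
                                     extract_segments, L = 4))
  }
  n <- min(200, nrow(segs$samples))
  idx <- seq_len(n)
  dom <- apply(segs$samples[idx, ], 1, function(x)
    compute_classical_features(x, segs$fs, "dominant_freq"))
  slope <- apply(segs$samples[idx, ], 1, function(x)
    compute_classical_features(x, segs$fs, "mean_abs_slope"))
  y <- segs$meta$label[idx]
  expect_lt(wilcox.test(dom[y == "Sh"], dom[y == "NSh"])$p.value, 0.01)
  expect_lt(wilcox.test(slope[y == "Sh"], slope[y == "NSh"])$p.value, 0.01)
})

test_that("quantization and the OHCA-like regime change the waveform as configured", {
  cfgq <- cohort_config(n_patients = 2, record_seconds = 20,
                        quantization_uV = 1.031, seed = 3)
  rq <- gen_cohort(cfgq)[[1]]
  steps <- diff(sort(unique(round(rq$samples / (1.031e-3), 6))))
  expect_true(all(abs(steps - round(steps)) < 1e-6))
  cfgo <- cohort_config(n_patients = 4, record_seconds = 60, ohca_like = TRUE,
                        seed = 5)
  reco <- gen_cohort(cfgo)
  vf_amp <- function(recs) {
    a <- unlist(lapply(recs, function(r) {
      ri <- r$rhythm_intervals
      vf <- ri[ri$label == "VF", , drop = FALSE]
      if (!nrow(vf)) return(NULL)
      apply(vf, 1, function(iv)
        diff(range(r$samples[(as.numeric(iv["start"]) + 1):as.numeric(iv["end"])])))
    }))
    a
  }
  base <- gen_cohort(cohort_config(n_patients = 4, record_seconds = 60,
                                   seed = 5))
  ao <- vf_amp(reco); ab <- vf_amp(base)
  if (length(ao) && length(ab)) expect_lt(median(ao), median(ab))
})

test_that("the intended exclusions are recovered from the waveforms themselves", {
  # run the measurement + reclassification chain on generated intervals and
  # check it reproduces the generator's intent on at least 95% of them
  cfg <- cohort_config(n_patients = 10, seed = 21)
  recs <- gen_cohort(cfg)
  total <- 0; agree <- 0
  for (r in recs) {
    ri <- r$rhythm_intervals
    for (k in seq_len(nrow(ri))) {
      if (ri$end[k] - ri$start[k] < r$fs) next
      x <- r$samples[(ri$start[k] + 1):ri$end[k]]
      m <- measure_segment(x, r$fs)
      base <- ri$label[k]
      mapped_base <- if (base %in% c("fine_VF")) "VF"
        else if (base %in% c("slow_VT")) "VT"
        else if (base == "AS") "NSR" else base
      out <- check_special_rhythm(m["rate"], m["peak_amp"], m["p2p_amp"],
                                  mapped_base)
      intended_excluded <- to_binary_label(base) == "excluded"
      detected_excluded <- to_binary_label(out) == "excluded"
      total <- total + 1
      agree <- agree + (intended_excluded == detected_excluded)
    }
  }
  expect_gt(total, 30)
  expect_gte(agree / total, 0.95)
})
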