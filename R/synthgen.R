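# Synthetic patient-structured ECG cohorts. Morphologies are deliberately
# simple surrogates -- Gaussian-bump PQRST trains for organized rhythms and
# modulated band-limited oscillations for VF -- tuned to reproduce the
# statistical contrasts the pipeline relies on (rate, amplitude, dominant
# frequency, irregularity), not clinical fidelity.

gauss_bump <- function(t, mu, sigma) exp(-((t - mu)^2) / (2 * sigma^2))

#' Synthetic organized (sinus-like) rhythm
#'
#' A periodic PQRST-like pulse train built from Gaussian bumps with
#' beat-to-beat rate jitter plus a small additive noise floor. Peak-to-peak
#' amplitude is about 1.6 `amp` (the R and S waves dominate).
#'
#' @param rate Heart rate in bpm (20-220).
#' @param amp R-wave amplitude in millivolts.
#' @param fs Sampling rate in Hz.
#' @param dur Duration in seconds.
#' @param jitter Relative standard deviation of the RR interval.
#' @param seed Integer seed; output is deterministic per seed.
#' @param wide Widen the QRS (aberrant-conduction morphology) and drop the
#'   P/T waves, as seen in pulseless organized OHCA rhythms.
#' @return Numeric vector of `round(dur * fs)` samples (millivolts).
#' @export
gen_sinus <- function(rate, amp = 1, fs = 250, dur = 10, jitter = 0.03,
                      seed = 1L, wide = FALSE) {
  stopifnot(rate >= 20, rate <= 220)
  rng <- local_rng(seed)
  on.exit(restore_rng(rng))
  n <- round(dur * fs)
  t <- seq(0, by = 1 / fs, length.out = n)
  x <- numeric(n)
  rr <- 60 / rate
  tb <- stats::runif(1, 0, rr)
  sig_r <- if (wide) 0.050 else 0.009
  while (tb < dur + rr) {
    x <- x + amp * gauss_bump(t, tb, sig_r) -
      0.6 * amp * gauss_bump(t, tb + (if (wide) 0.09 else 0.035), sig_r * 1.3)
    if (!wide)
      x <- x + 0.15 * amp * gauss_bump(t, tb - 0.18, 0.03) +
        0.30 * amp * gauss_bump(t, tb + 0.25, 0.05)
    tb <- tb + rr * (1 + jitter * stats::rnorm(1))
  }
  x + stats::rnorm(n, 0, 0.01 * max(amp, 0.1))
}

#' Synthetic ventricular fibrillation
#'
#' An amplitude- and frequency-modulated oscillation: the instantaneous
#' frequency performs a bounded random walk around `center_freq` and the
#' envelope is a slow band-limited modulation, so the waveform is irregular
#' and has no isolated QRS-like spikes.
#'
#' @param center_freq Dominant frequency in Hz (3-8).
#' @param amp Nominal amplitude in millivolts (peak-to-peak is about
#'   2.6 `amp`).
#' @param drift Standard deviation of the frequency random walk, Hz per
#'   sample step.
#' @param fs Sampling rate in Hz.
#' @param dur Duration in seconds.
#' @param seed Integer seed.
#' @return Numeric vector of `round(dur * fs)` samples (millivolts).
#' @export
gen_vf <- function(center_freq = 5, amp = 0.8, drift = 0.02, fs = 250,
                   dur = 10, seed = 1L) {
  stopifnot(center_freq >= 3, center_freq <= 8)
  rng <- local_rng(seed)
  on.exit(restore_rng(rng))
  n <- round(dur * fs)
  fwalk <- center_freq + cumsum(stats::rnorm(n, 0, drift))
  fwalk <- center_freq + (fwalk - center_freq) -
    (seq_len(n) / n) * (fwalk[n] - center_freq)   # pin the endpoint
  fwalk <- pmin(pmax(fwalk, 0.6 * center_freq), 1.4 * center_freq)
  ph <- cumsum(2 * pi * fwalk / fs) + stats::runif(1, 0, 2 * pi)
  env <- 1 + 0.3 * sin(2 * pi * 0.5 * seq_len(n) / fs + stats::runif(1, 0, 2 * pi))
  amp * env * sin(ph) + stats::rnorm(n, 0, 0.01 * max(amp, 0.05))
}

#' Synthetic borderline-rhythm edge cases
#'
#' Signals constructed to sit on the clinical exclusion rules: asystole
#' (peak-to-peak < 100 uV), fine VF (VF morphology, peak amplitude
#' < 200 uV), slow VT (wide monomorphic train under 150 bpm), and a
#' broadband noise burst.
#'
#' @param kind One of `"asystole"`, `"fine_vf"`, `"slow_vt"`,
#'   `"noise_burst"`.
#' @param fs Sampling rate in Hz.
#' @param dur Duration in seconds.
#' @param seed Integer seed.
#' @return List with `signal` (millivolts) and the `label` the segmenter is
#'   expected to assign (`AS`, `fine_VF`, `slow_VT`, `noise`).
#' @export
gen_edge_case <- function(kind = c("asystole", "fine_vf", "slow_vt",
                                   "noise_burst"),
                          fs = 250, dur = 10, seed = 1L) {
  kind <- match.arg(kind)
  rng <- local_rng(seed)
  on.exit(restore_rng(rng))
  n <- round(dur * fs)
  t <- seq(0, by = 1 / fs, length.out = n)
  out <- switch(kind,
    asystole = list(
      signal = 0.012 * sin(2 * pi * 0.25 * t + stats::runif(1, 0, 2 * pi)) +
        stats::rnorm(n, 0, 0.004),
      label = "AS"),
    fine_vf = list(
      signal = gen_vf(4, amp = 0.07, fs = fs, dur = dur,
                      seed = stats::runif(1, 1, 1e6)),
      label = "fine_VF"),
    slow_vt = list(
      signal = gen_sinus(135, amp = 1, fs = fs, dur = dur, jitter = 0.01,
                         seed = stats::runif(1, 1, 1e6), wide = TRUE),
      label = "slow_VT"),
    noise_burst = list(
      signal = stats::rnorm(n, 0, 0.5),
      label = "noise"))
  out
}

#' Cohort configuration for the synthetic generator
#'
#' Defaults describe the study conditions the pipeline assumes: 250 Hz
#' sampling, patient records of 120 s composed of 10-14 s rhythm intervals,
#' a nonshockable:shockable segment imbalance of about 4:1, occasional
#' noise intervals, and a small share of borderline rhythms (fine VF, slow
#' VT, asystole) that the exclusion rules must catch.
#'
#' @param n_patients Number of synthetic patients (>= 2).
#' @param fs Sampling rate in Hz.
#' @param record_seconds Record duration per patient.
#' @param imbalance_ratio Target NSh:Sh ratio among usable segments.
#' @param noise_prob Probability that a record contains one noise interval.
#' @param quantization_uV Amplitude quantization step in microvolts
#'   (0 = off; 1.031 emulates defibrillator-pad acquisition).
#' @param ohca_like Use the harder-regime morphologies: lower-amplitude,
#'   lower-frequency VF and wide irregular organized rhythms.
#' @param seed Cohort seed; all randomness derives from it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 20L, fs = 250, record_seconds = 120,
                          imbalance_ratio = 4, noise_prob = 0.1,
                          quantization_uV = 0, ohca_like = FALSE, seed = 1L) {
  if (n_patients < 2L) stop("need at least 2 patients")
  if (imbalance_ratio <= 0 || !is.finite(imbalance_ratio))
    stop("imbalance_ratio must be positive and finite")
  nsh_shape <- c(NSR = 50, AF = 10, SVT = 5, PEA = 11)
  sh_shape <- c(VF = 15, VT = 4)
  edge <- c(fine_VF = 0.02, slow_VT = 0.02, AS = 0.01)
  main <- 1 - sum(edge)
  mix <- c(main / (1 + imbalance_ratio) * sh_shape / sum(sh_shape),
           main * imbalance_ratio / (1 + imbalance_ratio) *
             nsh_shape / sum(nsh_shape),
           edge)
  structure(list(n_patients = as.integer(n_patients), fs = fs,
                 record_seconds = record_seconds,
                 imbalance_ratio = imbalance_ratio, mix = mix,
                 noise_prob = noise_prob, quantization_uV = quantization_uV,
                 ohca_like = isTRUE(ohca_like), seed = as.integer(seed)),
            class = "cohort_config")
}

gen_interval_signal <- function(label, fs, dur, seed, ohca_like) {
  r <- function(a, b) stats::runif(1, a, b)
  rng <- local_rng(seed)
  sub <- function() as.integer(stats::runif(1, 1, 2^30))
  sig <- switch(label,
    NSR = gen_sinus(r(60, 100), amp = r(0.8, 1.2), fs = fs, dur = dur,
                    seed = sub(), wide = ohca_like),
    SVT = gen_sinus(r(160, 200), amp = r(0.7, 1.1), fs = fs, dur = dur,
                    jitter = 0.02, seed = sub()),
    AF = gen_sinus(r(70, 120), amp = r(0.7, 1.1), fs = fs, dur = dur,
                   jitter = 0.15, seed = sub()) +
      0.05 * sin(2 * pi * 6 * seq_len(round(dur * fs)) / fs),
    block = gen_sinus(r(30, 50), amp = r(0.8, 1.2), fs = fs, dur = dur,
                      seed = sub()),
    PEA = gen_sinus(r(30, 60), amp = r(0.5, 0.9), fs = fs, dur = dur,
                    jitter = 0.12, seed = sub(), wide = TRUE),
    VF = if (ohca_like)
      gen_vf(r(3, 4.5), amp = r(0.25, 0.5), fs = fs, dur = dur, seed = sub())
    else gen_vf(r(4, 6.5), amp = r(0.5, 1), fs = fs, dur = dur, seed = sub()),
    VT = gen_sinus(r(160, 220), amp = r(0.9, 1.3), fs = fs, dur = dur,
                   jitter = 0.015, seed = sub(), wide = TRUE),
    fine_VF = gen_edge_case("fine_vf", fs, dur, sub())$signal,
    slow_VT = gen_edge_case("slow_vt", fs, dur, sub())$signal,
    AS = gen_edge_case("asystole", fs, dur, sub())$signal,
    stop("no generator for rhythm label ", label))
  restore_rng(rng)
  sig
}

#' Generate a synthetic ECG cohort
#'
#' One annotated record per synthetic patient: a sequence of 10-14 s rhythm
#' intervals drawn from the configured mix, with optional noise intervals
#' and amplitude quantization. After standard segment extraction, the
#' NSh:Sh segment ratio is close to the configured imbalance.
#'
#' @param cfg A [cohort_config()].
#' @return List of [ecg_record()] objects (`source_db = "synthetic"`).
#' @export
gen_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  lapply(seq_len(cfg$n_patients), function(i) {
    gen_synth_record(sprintf("synth%03d", i),
                     derive_seed(cfg$seed, i), cfg)
  })
}

derive_seed <- function(seed, i) as.integer((seed * 1009L + i * 7919L) %% 2147483647L)

gen_synth_record <- function(patient_id, seed, cfg) {
  rng <- local_rng(seed)
  on.exit(restore_rng(rng))
  fs <- cfg$fs
  n_total <- round(cfg$record_seconds * fs)
  x <- numeric(0)
  iv <- list()
  while (length(x) < n_total) {
    lab <- sample(names(cfg$mix), 1L, prob = cfg$mix)
    dur <- stats::runif(1, 10, 14)
    sig <- gen_interval_signal(lab, fs, dur,
                               as.integer(stats::runif(1, 1, 2^30)),
                               cfg$ohca_like)
    iv[[length(iv) + 1L]] <- data.frame(start = length(x),
                                        end = length(x) + length(sig),
                                        label = lab, stringsAsFactors = FALSE)
    x <- c(x, sig)
  }
  x <- x[seq_len(n_total)]
  ri <- do.call(rbind, iv)
  ri$end[nrow(ri)] <- min(ri$end[nrow(ri)], n_total)
  ri <- ri[ri$start < ri$end, , drop = FALSE]
  ni <- NULL
  if (stats::runif(1) < cfg$noise_prob) {
    ndur <- round(stats::runif(1, 4, 8) * fs)
    ns <- sample.int(n_total - ndur, 1L)
    x[(ns + 1):(ns + ndur)] <- x[(ns + 1):(ns + ndur)] +
      stats::rnorm(ndur, 0, 0.6)
    ni <- data.frame(start = ns, end = ns + ndur)
  }
  if (cfg$quantization_uV > 0) {
    step <- cfg$quantization_uV / 1000
    x <- round(x / step) * step
  }
  ecg_record(x, fs, patient_id, "synthetic", rhythm_intervals = ri,
             noise_intervals = ni)
}
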