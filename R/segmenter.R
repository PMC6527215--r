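# Cutting records into fixed-length rhythm segments, exclusion rules, and
# binary shock labels.

#' Map a rhythm label to the binary shock decision class
#'
#' VF, VT and ventricular flutter are shockable (`Sh`); organized rhythms are
#' nonshockable (`NSh`). Asystole, fine VF, slow VT, noise and saturation are
#' `excluded` from the binary decision: defibrillation benefit is unclear for
#' fine VF and slow VT, and asystole is handled upstream by amplitude
#' thresholding in an AED.
#'
#' @param rhythm Character vector of rhythm labels from [rhythm_vocabulary()].
#' @return Character vector over `c("Sh", "NSh", "excluded")`.
#' @export
to_binary_label <- function(rhythm) {
  sh <- c("VF", "VT", "ventricular_flutter")
  nsh <- c("NSR", "SVT", "AF", "block", "ectopic", "PR", "PEA")
  excl <- c("AS", "fine_VF", "slow_VT", "noise", "saturation")
  bad <- setdiff(rhythm, c(sh, nsh, excl))
  if (length(bad)) stop("unknown rhythm label(s): ", paste(bad, collapse = ", "))
  out <- ifelse(rhythm %in% sh, "Sh", ifelse(rhythm %in% nsh, "NSh", "excluded"))
  unname(out)
}

#' Reclassify borderline rhythms from amplitude and rate measurements
#'
#' Applies the clinical edge-case rules used when curating shock-decision
#' data: any rhythm with rate below 12 bpm or peak-to-peak amplitude below
#' 100 uV is asystole; VF with peak amplitude below 200 uV is fine VF; VT
#' slower than 150 bpm is slow VT. All bounds are strict inequalities, and
#' the asystole rule takes precedence.
#'
#' @param rate Heart rate in bpm.
#' @param peak_amp Peak amplitude `max|x - median(x)|` in microvolts.
#' @param p2p_amp Peak-to-peak amplitude in microvolts.
#' @param base_label The annotated rhythm label.
#' @return The (possibly reclassified) rhythm label.
#' @export
check_special_rhythm <- function(rate, peak_amp, p2p_amp, base_label) {
  stopifnot(rate >= 0, peak_amp >= 0, p2p_amp >= 0)
  if (rate < 12 || p2p_amp < 100) return("AS")
  if (base_label == "VF" && peak_amp < 200) return("fine_VF")
  if (base_label == "VT" && rate < 150) return("slow_VT")
  base_label
}

#' Measure rate and amplitude of an ECG segment
#'
#' Peak-to-peak amplitude is `max(x) - min(x)`; peak amplitude is
#' `max|x - median(x)|` (both in microvolts, input in millivolts). Rate is
#' estimated by local-maxima detection with an adaptive threshold of half the
#' peak amplitude and a 200 ms refractory period.
#'
#' @param x Numeric vector, millivolts; at least one second of samples.
#' @param fs Sampling rate in Hz.
#' @return Named numeric vector `c(rate, peak_amp, p2p_amp)` (bpm, uV, uV).
#' @export
measure_segment <- function(x, fs) {
  if (length(x) < fs) stop("need at least 1 s of samples")
  p2p <- (max(x) - min(x)) * 1000
  pk <- max(abs(x - stats::median(x))) * 1000
  if (pk == 0) return(c(rate = 0, peak_amp = 0, p2p_amp = 0))
  thr <- 0.5 * pk / 1000
  xc <- x - stats::median(x)
  n <- length(x)
  is_peak <- c(FALSE, xc[2:(n - 1)] > xc[1:(n - 2)] &
                 xc[2:(n - 1)] >= xc[3:n], FALSE) & (xc > thr)
  idx <- which(is_peak)
  refr <- round(0.2 * fs)
  keep <- integer()
  last <- -Inf
  for (i in idx) {
    if (i - last >= refr) { keep <- c(keep, i); last <- i }
  }
  rate <- if (length(keep) >= 2L)
    60 * (length(keep) - 1L) / ((keep[length(keep)] - keep[1L]) / fs)
  else 60 * length(keep) / (n / fs)
  c(rate = rate, peak_amp = pk, p2p_amp = p2p)
}

#' Extract fixed-length labeled segments from a record
#'
#' Windows of `L` seconds tile each rhythm interval from its start; the
#' leftover tail shorter than `L` is dropped, so no window ever spans two
#' rhythm labels. Windows overlapping any noise or saturation interval are
#' discarded, as are windows from excluded rhythms (asystole, fine VF, slow
#' VT, noise, saturation). The record is assumed already preprocessed.
#'
#' @param rec An [ecg_record()].
#' @param L Segment length in seconds; `L * fs` must be an integer.
#' @param fs Sampling rate; defaults to the record's rate.
#' @return A `segment_set`: list with `samples` (matrix, one row per
#'   segment), `meta` (data frame: patient_id, source_db, rhythm, label,
#'   t_start), `L` and `fs`.
#' @export
extract_segments <- function(rec, L, fs = rec$fs) {
  stopifnot(inherits(rec, "ecg_record"), L > 0)
  if (abs(L * fs - round(L * fs)) > 1e-9)
    stop("L * fs must be an integer number of samples")
  n_seg <- as.integer(round(L * fs))
  ri <- rec$rhythm_intervals
  ni <- rec$noise_intervals
  rows <- list(); meta <- list()
  if (nrow(ri)) for (k in seq_len(nrow(ri))) {
    lab <- ri$label[k]
    if (to_binary_label(lab) == "excluded") next
    starts <- seq(ri$start[k], by = n_seg,
                  length.out = (ri$end[k] - ri$start[k]) %/% n_seg)
    for (s0 in starts) {
      e0 <- s0 + n_seg
      if (nrow(ni) && any(pmax(ni$start, s0) < pmin(ni$end, e0))) next
      rows[[length(rows) + 1L]] <- rec$samples[(s0 + 1L):e0]
      meta[[length(meta) + 1L]] <-
        data.frame(patient_id = rec$patient_id, source_db = rec$source_db,
                   rhythm = lab, label = to_binary_label(lab),
                   t_start = s0 / fs, stringsAsFactors = FALSE)
    }
  }
  samples <- if (length(rows)) do.call(rbind, rows) else
    matrix(numeric(), 0L, n_seg)
  meta <- if (length(meta)) do.call(rbind, meta) else
    data.frame(patient_id = character(), source_db = character(),
               rhythm = character(), label = character(), t_start = numeric())
  segment_set(samples, meta, L, fs)
}

#' Construct a segment set
#'
#' @param samples Numeric matrix, one segment per row, `L * fs` columns.
#' @param meta Data frame with one row per segment: `patient_id`,
#'   `source_db`, `rhythm`, `label`, `t_start`.
#' @param L Segment length in seconds.
#' @param fs Sampling rate in Hz.
#' @return A list of class `segment_set`.
#' @export
segment_set <- function(samples, meta, L, fs) {
  stopifnot(is.matrix(samples), nrow(samples) == nrow(meta),
            ncol(samples) == round(L * fs) || nrow(samples) == 0L)
  structure(list(samples = samples, meta = meta, L = L, fs = fs),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  tab <- table(factor(x$meta$label, levels = c("Sh", "NSh")))
  cat(sprintf("<segment_set> %d segments of %g s at %g Hz (Sh %d / NSh %d)\n",
              nrow(x$samples), x$L, x$fs, tab["Sh"], tab["NSh"]))
  invisible(x)
}

#' Combine segment sets
#'
#' @param ... `segment_set` objects sharing `L` and `fs`.
#' @return A single `segment_set`.
#' @export
bind_segment_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1]], "segment_set"))
    sets <- sets[[1]]
  sets <- Filter(function(s) nrow(s$samples) > 0L, sets)
  if (!length(sets)) stop("no non-empty segment sets to combine")
  L <- sets[[1]]$L; fs <- sets[[1]]$fs
  stopifnot(all(vapply(sets, function(s) s$L == L && s$fs == fs, logical(1))))
  segment_set(do.call(rbind, lapply(sets, `[[`, "samples")),
              do.call(rbind, lapply(sets, `[[`, "meta")), L, fs)
}

#' Subset a segment set
#'
#' @param x A `segment_set`.
#' @param i Row index vector.
#' @return The subsetted `segment_set`.
#' @export
subset_segments <- function(x, i) {
  segment_set(x$samples[i, , drop = FALSE], x$meta[i, , drop = FALSE],
              x$L, x$fs)
}

#' Export / import a segment set as plain text
#'
#' Writes `<stem>_meta.csv` (one row per segment) and `<stem>_samples.csv`
#' (the samples matrix, no header).
#'
#' @param x A `segment_set`.
#' @param stem Output path stem.
#' @return Invisibly, `stem` (write) or the `segment_set` (read).
#' @export
write_segment_set <- function(x, stem) {
  meta <- cbind(x$meta, L = x$L, fs = x$fs)
  utils::write.csv(meta, paste0(stem, "_meta.csv"), row.names = FALSE)
  utils::write.table(format(x$samples, digits = 9, trim = TRUE, scientific = FALSE),
                     paste0(stem, "_samples.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(stem)
}

#' @rdname write_segment_set
#' @export
read_segment_set <- function(stem) {
  meta <- utils::read.csv(paste0(stem, "_meta.csv"), stringsAsFactors = FALSE)
  samples <- as.matrix(utils::read.table(paste0(stem, "_samples.csv"), sep = ","))
  dimnames(samples) <- NULL
  segment_set(samples, meta[setdiff(names(meta), c("L", "fs"))],
              meta$L[1], meta$fs[1])
}
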