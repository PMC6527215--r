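# Annotated ECG records, fixture I/O, resampling, patient-wise partitioning.

#' Rhythm label vocabulary
#'
#' The closed set of rhythm labels used throughout the package. Shockable
#' rhythms are VF, VT and ventricular flutter; organized rhythms (NSR, SVT,
#' AF, heart block, ectopic activity, pulsed rhythms, PEA) are nonshockable;
#' asystole (AS), fine VF, slow VT, noise and saturation are excluded from
#' the binary shock decision.
#'
#' @return Character vector of valid rhythm labels.
#' @export
rhythm_vocabulary <- function() {
  c("VF", "VT", "ventricular_flutter", "NSR", "SVT", "AF", "block",
    "ectopic", "PR", "PEA", "AS", "fine_VF", "slow_VT", "noise", "saturation")
}

source_db_levels <- function() c("vfdb", "cudb", "ahadb", "ohca", "synthetic")

#' Construct an annotated ECG record
#'
#' An `ecg_record` holds one patient's continuous single-channel ECG in
#' millivolts together with its rhythm annotations and noise intervals.
#' All intervals use 0-based, half-open sample indexing `[start, end)`.
#'
#' @param samples Numeric vector, ECG amplitude in millivolts.
#' @param fs Sampling rate in Hz (positive).
#' @param patient_id Character scalar identifying the patient.
#' @param source_db One of `"vfdb"`, `"cudb"`, `"ahadb"`, `"ohca"`,
#'   `"synthetic"`.
#' @param rhythm_intervals Data frame with columns `start`, `end` (0-based
#'   half-open sample indices) and `label` (from [rhythm_vocabulary()]);
#'   intervals must be sorted and non-overlapping.
#' @param noise_intervals Data frame with columns `start`, `end`: intervals
#'   contaminated by noise or device saturation.
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(samples, fs, patient_id, source_db = "synthetic",
                       rhythm_intervals = NULL, noise_intervals = NULL) {
  if (!is.numeric(samples) || length(samples) == 0L)
    stop("`samples` must be a non-empty numeric vector")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive scalar")
  source_db <- match.arg(source_db, source_db_levels())
  n <- length(samples)
  if (is.null(rhythm_intervals))
    rhythm_intervals <- data.frame(start = integer(), end = integer(),
                                   label = character())
  if (is.null(noise_intervals))
    noise_intervals <- data.frame(start = integer(), end = integer())
  ri <- as.data.frame(rhythm_intervals)
  if (nrow(ri)) {
    bad <- setdiff(ri$label, rhythm_vocabulary())
    if (length(bad))
      stop("unknown rhythm label(s): ", paste(bad, collapse = ", "))
    if (any(ri$start >= ri$end))
      stop("rhythm intervals must satisfy start < end")
    if (any(ri$start < 0) || any(ri$end > n))
      stop("rhythm intervals must lie within [0, length)")
    if (is.unsorted(ri$start))
      stop("rhythm intervals must be sorted by start")
    if (nrow(ri) > 1L && any(ri$end[-nrow(ri)] > ri$start[-1L]))
      stop("rhythm intervals must be non-overlapping")
  }
  ni <- as.data.frame(noise_intervals)
  if (nrow(ni) && (any(ni$start >= ni$end) || any(ni$start < 0) || any(ni$end > n)))
    stop("noise intervals must be half-open, within [0, length)")
  structure(list(samples = as.numeric(samples), fs = fs,
                 patient_id = as.character(patient_id), source_db = source_db,
                 rhythm_intervals = ri, noise_intervals = ni),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> patient %s (%s): %.1f s at %g Hz, %d rhythm interval(s), %d noise interval(s)\n",
              x$patient_id, x$source_db, length(x$samples) / x$fs, x$fs,
              nrow(x$rhythm_intervals), nrow(x$noise_intervals)))
  invisible(x)
}

#' Write an ECG record in the plain-text fixture format
#'
#' The fixture format is a JSON header (`<name>.json`: patient id, source
#' database, sampling rate, intervals) plus a sample file (`<name>.txt`, one
#' sample per line, millivolts, 6 decimal places). Amplitudes are therefore
#' quantized to 1e-6 mV on write.
#'
#' @param rec An [ecg_record()].
#' @param dir Directory to write into (created if needed).
#' @param name Record name (file stem); defaults to the patient id.
#' @return Invisibly, the path stem of the written record.
#' @export
write_fixture_record <- function(rec, dir, name = rec$patient_id) {
  stopifnot(inherits(rec, "ecg_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- file.path(dir, name)
  hdr <- list(patient_id = rec$patient_id, source_db = rec$source_db,
              fs = rec$fs, n_samples = length(rec$samples),
              rhythm_intervals = rec$rhythm_intervals,
              noise_intervals = rec$noise_intervals)
  jsonlite::write_json(hdr, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  writeLines(sprintf("%.6f", rec$samples), paste0(stem, ".txt"))
  invisible(stem)
}

#' Read an ECG record from the fixture format
#'
#' @param stem Path stem of the record (without `.json`/`.txt` extension).
#' @return An [ecg_record()].
#' @export
read_fixture_record <- function(stem) {
  jpath <- paste0(stem, ".json"); tpath <- paste0(stem, ".txt")
  if (!file.exists(jpath) || !file.exists(tpath))
    stop("fixture record not found at stem: ", stem)
  hdr <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  x <- as.numeric(readLines(tpath))
  if (length(x) != hdr$n_samples)
    stop("fixture sample count mismatch for ", stem)
  as_iv <- function(d) {
    if (is.null(d) || length(d) == 0L) return(NULL)
    as.data.frame(d)
  }
  ecg_record(x, hdr$fs, hdr$patient_id, hdr$source_db,
             rhythm_intervals = as_iv(hdr$rhythm_intervals),
             noise_intervals = as_iv(hdr$noise_intervals))
}

#' Resample a signal to a target rate
#'
#' Polyphase rational resampling: the signal is upsampled by the numerator of
#' the rational rate ratio, low-pass filtered with a linear-phase FIR
#' (cutoff 0.45 times the lower of the two Nyquist-defining rates, designed
#' with [signal::fir1()]), and decimated. Group delay is compensated so the
#' output is aligned with the input.
#'
#' @param x Numeric vector.
#' @param fs_in,fs_out Input and output sampling rates in Hz.
#' @return Numeric vector of length `round(length(x) * fs_out / fs_in)`.
#' @export
resample_to_target <- function(x, fs_in, fs_out = 250) {
  if (!is.numeric(fs_in) || fs_in <= 0 || !is.numeric(fs_out) || fs_out <= 0)
    stop("sampling rates must be positive")
  if (fs_in == fs_out) return(as.numeric(x))
  x <- as.numeric(x)
  fr <- MASS::fractions(fs_out / fs_in)
  pq <- as.integer(strsplit(attr(fr, "fracs"), "/")[[1]])
  if (length(pq) == 1L) pq <- c(pq, 1L)
  p <- pq[1]; q <- pq[2]
  n_out <- round(length(x) * fs_out / fs_in)
  fs_up <- fs_in * p
  wc <- 0.45 * min(fs_in, fs_out) / (fs_up / 2)
  ord <- 2L * ceiling(5 / wc)
  h <- signal::fir1(ord, wc) * p
  up <- numeric(length(x) * p)
  up[seq(1L, length(up), by = p)] <- x
  d <- ord / 2
  padded <- c(rep(up[1L], d), up, rep(up[length(up)], d + p))
  y <- stats::filter(padded, h, sides = 1)
  y <- y[(2L * d + 1L):(2L * d + length(up))]
  as.numeric(y[seq(1L, by = q, length.out = n_out)])
}

#' Patient-wise train/test partitioning
#'
#' Randomly assigns patients to a training and a test set, independently
#' within each source database, so that all segments of one patient fall on
#' one side of the split. Per database, `round(train_frac * n_patients)`
#' patients are assigned to training.
#'
#' @param records List of [ecg_record()] objects.
#' @param train_frac Fraction of patients per database used for training.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return A list of class `split_result` with elements `train_ids`,
#'   `test_ids` (character vectors of patient ids) and `seed`.
#' @export
split_patients <- function(records, train_frac = 0.8, seed) {
  stopifnot(length(records) > 0L, train_frac > 0, train_frac < 1)
  ids <- vapply(records, function(r) r$patient_id, character(1))
  dbs <- vapply(records, function(r) r$source_db, character(1))
  pat <- unique(data.frame(patient_id = ids, source_db = dbs,
                           stringsAsFactors = FALSE))
  rng <- local_rng(seed)
  train_ids <- character(); test_ids <- character()
  for (db in sort(unique(pat$source_db))) {
    pd <- sort(pat$patient_id[pat$source_db == db])
    if (length(pd) < 2L)
      stop("database '", db, "' has fewer than 2 patients; cannot split")
    n_train <- round(train_frac * length(pd))
    n_train <- max(1L, min(length(pd) - 1L, n_train))
    tr <- sort(sample(pd, n_train))
    train_ids <- c(train_ids, tr)
    test_ids <- c(test_ids, setdiff(pd, tr))
  }
  restore_rng(rng)
  structure(list(train_ids = train_ids, test_ids = test_ids, seed = seed),
            class = "split_result")
}

# Scoped RNG: seed without clobbering the caller's RNG state.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
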