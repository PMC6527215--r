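# Minimal WFDB (physionet) reader: .hea header, .dat signal (formats 212/16),
# .atr rhythm annotations. Only what the shock-decision pipeline needs: the
# first channel, in millivolts, plus rhythm/noise intervals.

# physionet rhythm annotation aux strings -> package vocabulary
wfdb_rhythm_map <- function() {
  c("(VF"    = "VF",
    "(VFIB"  = "VF",
    "(VT"    = "VT",
    "(VFL"   = "ventricular_flutter",
    "(N"     = "NSR",
    "(NSR"   = "NSR",
    "(SVTA"  = "SVT",
    "(SVT"   = "SVT",
    "(AFIB"  = "AF",
    "(AF"    = "AF",
    "(B"     = "block",
    "(BI"    = "block",
    "(BII"   = "block",
    "(HGEA"  = "ectopic",
    "(VER"   = "ectopic",
    "(PVC"   = "ectopic",
    "(IVR"   = "ectopic",
    "(PR"    = "PR",
    "(PEA"   = "PEA",
    "(ASYS"  = "AS",
    "(NOISE" = "noise",
    "(NOD"   = "NSR",
    "(SBR"   = "block")
}

read_wfdb_header <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  rec_name <- sub("/.*$", "", top[1])
  n_sig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(sub("/.*$", "", top[3])) else 250
  n_samp <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_
  sig <- lapply(seq_len(n_sig), function(i) {
    f <- strsplit(trimws(lines[1 + i]), "[ \t]+")[[1]]
    fmt <- sub("x.*$", "", f[2])   # strip samples-per-frame multiplier
    gain_field <- if (length(f) >= 3) f[3] else "200"
    gain <- as.numeric(sub("[(/].*$", "", gain_field))
    if (!is.finite(gain) || gain == 0) gain <- 200
    baseline <- if (grepl("\\(", gain_field))
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_field)) else 0
    adczero <- if (length(f) >= 5) as.numeric(f[5]) else 0
    if (!grepl("\\(", gain_field)) baseline <- adczero
    list(file = f[1], fmt = fmt, gain = gain, baseline = baseline)
  })
  list(record = rec_name, n_sig = n_sig, fs = fs, n_samples = n_samp,
       signals = sig)
}

read_dat_212 <- function(path, n_values) {
  raw <- readBin(path, "raw", n = ceiling(n_values / 2) * 3)
  b <- as.integer(raw)
  n_pairs <- length(b) %/% 3
  b1 <- b[seq(1, by = 3, length.out = n_pairs)]
  b2 <- b[seq(2, by = 3, length.out = n_pairs)]
  b3 <- b[seq(3, by = 3, length.out = n_pairs)]
  s1 <- b1 + bitwShiftL(bitwAnd(b2, 0x0F), 8)
  s2 <- b3 + bitwShiftL(bitwAnd(b2, 0xF0), 4)
  s1 <- ifelse(s1 > 2047, s1 - 4096, s1)
  s2 <- ifelse(s2 > 2047, s2 - 4096, s2)
  out <- numeric(2 * n_pairs)
  out[seq(1, by = 2, length.out = n_pairs)] <- s1
  out[seq(2, by = 2, length.out = n_pairs)] <- s2
  out[seq_len(n_values)]
}

read_dat_16 <- function(path, n_values) {
  readBin(path, "integer", n = n_values, size = 2, signed = TRUE,
          endian = "little")
}

# .atr: stream of 16-bit little-endian words; code = bits 10-15, time
# increment = bits 0-9. Special codes: 59 SKIP (4-byte long interval),
# 60 NUM, 61 SUB, 62 CHN, 63 AUX (aux string follows), 0 EOF.
read_wfdb_annotations <- function(atr_path) {
  raw <- readBin(atr_path, "raw", n = file.size(atr_path))
  b <- as.integer(raw)
  i <- 1L; t_cur <- 0
  times <- integer(); codes <- integer(); auxs <- character()
  while (i + 1L <= length(b)) {
    word <- b[i] + 256L * b[i + 1L]
    i <- i + 2L
    code <- bitwShiftR(word, 10)
    field <- bitwAnd(word, 1023L)
    if (code == 0L && field == 0L) break                 # EOF
    if (code == 59L) {                                   # SKIP: long interval
      hi <- b[i] + 256L * b[i + 1L]
      lo <- b[i + 2L] + 256L * b[i + 3L]
      i <- i + 4L
      t_cur <- t_cur + hi * 65536 + lo
    } else if (code %in% c(60L, 61L, 62L)) {
      # NUM/SUB/CHN modifiers: ignored
    } else if (code == 63L) {                            # AUX string
      len <- field
      ar <- raw[i:(i + len - 1L)]
      aux <- rawToChar(ar[ar != as.raw(0)])
      i <- i + len + (len %% 2L)
      if (length(codes)) auxs[length(codes)] <- trimws(aux)
    } else {
      t_cur <- t_cur + field
      times <- c(times, t_cur)
      codes <- c(codes, code)
      auxs <- c(auxs, NA_character_)
    }
  }
  data.frame(time = times, code = codes, aux = auxs, stringsAsFactors = FALSE)
}

#' Read a WFDB record (physionet .hea/.dat/.atr triplet)
#'
#' Reads the header, extracts the first signal channel only, converts it to
#' millivolts using the header gain/baseline, and converts rhythm-change
#' annotations (`+` annotations with `(XXX` aux strings) into half-open
#' rhythm intervals spanning from each rhythm change to the next.
#' Annotation sample numbers are 0-based, matching the package's internal
#' indexing. Intervals labeled `noise` or `saturation` are additionally
#' recorded as noise intervals.
#'
#' @param path Path stem of the record (with or without `.hea` extension).
#' @param patient_id Patient identifier; defaults to the record name.
#' @param source_db Source database tag for the record.
#' @return An [ecg_record()] with the first channel in millivolts.
#' @export
read_wfdb_record <- function(path, patient_id = NULL, source_db = "vfdb") {
  stem <- sub("\\.hea$", "", path)
  hea <- paste0(stem, ".hea")
  if (!file.exists(hea)) stop("WFDB header not found: ", hea)
  hdr <- read_wfdb_header(hea)
  dat <- file.path(dirname(stem), hdr$signals[[1]]$file)
  if (!file.exists(dat)) stop("WFDB signal file not found: ", dat)
  n_sig <- hdr$n_sig
  n_samp <- hdr$n_samples
  fmt <- hdr$signals[[1]]$fmt
  n_values <- if (is.na(n_samp)) {
    sz <- file.size(dat)
    if (fmt == "212") (sz %/% 3) * 2 else sz %/% 2
  } else n_samp * n_sig
  adc <- switch(fmt,
                "212" = read_dat_212(dat, n_values),
                "16"  = read_dat_16(dat, n_values),
                stop("unsupported WFDB signal format: ", fmt))
  # frame-interleaved channels; keep channel 1 only
  ch1 <- adc[seq(1L, length(adc), by = n_sig)]
  s <- hdr$signals[[1]]
  mv <- (ch1 - s$baseline) / s$gain
  atr <- paste0(stem, ".atr")
  ri <- NULL; ni <- NULL
  if (file.exists(atr)) {
    ann <- read_wfdb_annotations(atr)
    rhy <- ann[!is.na(ann$aux) & grepl("^\\(", ann$aux), , drop = FALSE]
    if (nrow(rhy)) {
      map <- wfdb_rhythm_map()
      lab <- map[trimws(rhy$aux)]
      if (anyNA(lab))
        stop("unknown rhythm annotation code(s): ",
             paste(unique(trimws(rhy$aux)[is.na(lab)]), collapse = ", "))
      start <- rhy$time
      end <- c(rhy$time[-1L], length(mv))
      keep <- start < end
      ri <- data.frame(start = start[keep], end = end[keep],
                       label = unname(lab[keep]), stringsAsFactors = FALSE)
      nz <- ri$label %in% c("noise", "saturation")
      if (any(nz)) ni <- ri[nz, c("start", "end")]
    }
  }
  ecg_record(mv, hdr$fs, patient_id %||% hdr$record, source_db,
             rhythm_intervals = ri, noise_intervals = ni)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
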