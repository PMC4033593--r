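#' Signal trace
#'
#' A uniformly sampled physiological trace: ECG in millivolts or compression
#' depth in millimetres.
#'
#' @param samples numeric vector of finite amplitudes.
#' @param fs sampling rate in Hz, > 0.
#' @param start_time time of the first sample in seconds.
#' @return An object of class `signal_trace`.
#' @export
signal_trace <- function(samples, fs, start_time = 0) {
  stopifnot(is.numeric(samples), length(samples) >= 1)
  if (any(!is.finite(samples))) stop("samples must be finite")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop("fs must be a positive scalar")
  structure(list(samples = as.numeric(samples), fs = as.numeric(fs),
                 start_time = as.numeric(start_time)),
            class = "signal_trace")
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace> %d samples @ %g Hz (%.2f s), start %.3f s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs, x$start_time))
  invisible(x)
}

#' Duration of a trace in seconds
#' @param trace a [signal_trace()].
#' @export
trace_duration <- function(trace) length(trace$samples) / trace$fs

#' Chest-compression marks
#'
#' The instants `t_k` (seconds) of individual chest compressions, usually
#' detected from the compression-depth channel. Marks must be strictly
#' increasing and non-negative; with `validate_rate = TRUE` consecutive
#' intervals are additionally required to lie in (0.2, 2.0) s, the range of
#' physiologically plausible compression periods (30 to 300 per minute).
#'
#' @param t numeric vector of compression instants in seconds (may be empty).
#' @param validate_rate check inter-compression intervals against the
#'   physiologic range.
#' @return An object of class `cc_marks`.
#' @export
cc_marks <- function(t = numeric(0), validate_rate = FALSE) {
  stopifnot(is.numeric(t))
  t <- as.numeric(t)
  if (length(t) && any(!is.finite(t))) stop("marks must be finite")
  if (length(t) && any(t < 0)) stop("marks must be non-negative")
  if (length(t) >= 2 && any(diff(t) <= 0)) stop("marks must be strictly increasing")
  if (validate_rate && length(t) >= 2) {
    d <- diff(t)
    if (any(d <= 0.2 | d >= 2.0))
      stop("inter-compression intervals outside (0.2, 2.0) s")
  }
  structure(list(t = t), class = "cc_marks")
}

#' @export
print.cc_marks <- function(x, ...) {
  cat(sprintf("<cc_marks> %d compressions", length(x$t)))
  if (length(x$t) >= 2)
    cat(sprintf(", median rate %.0f cpm", 60 / stats::median(diff(x$t))))
  cat("\n")
  invisible(x)
}

#' Signal record
#'
#' One analysis record: an ECG trace, an optional compression-depth (CD)
#' trace, compression marks, and a ground-truth rhythm label when known.
#'
#' @param ecg ECG [signal_trace()] in mV.
#' @param cd optional compression-depth [signal_trace()] in mm.
#' @param marks a [cc_marks()] object (may be empty).
#' @param rhythm_label one of `"VF"`, `"VT"`, `"ASY"`, `"PEA"`, `"PR"`,
#'   or `"unknown"`.
#' @param patient_id,record_id identifier strings.
#' @return An object of class `signal_record`.
#' @export
signal_record <- function(ecg, cd = NULL, marks = cc_marks(),
                          rhythm_label = "unknown",
                          patient_id = "p0", record_id = "r0") {
  stopifnot(inherits(ecg, "signal_trace"), inherits(marks, "cc_marks"))
  rhythm_label <- match.arg(rhythm_label,
                            c("unknown", "VF", "VT", "ASY", "PEA", "PR"))
  if (!is.null(cd)) {
    stopifnot(inherits(cd, "signal_trace"))
    if (abs(trace_duration(cd) - trace_duration(ecg)) > 1 / min(ecg$fs, cd$fs))
      stop("ecg and cd must cover the same time span")
  }
  t_end <- ecg$start_time + trace_duration(ecg)
  if (length(marks$t) && (min(marks$t) < ecg$start_time || max(marks$t) > t_end))
    stop("compression marks fall outside the record time span")
  structure(list(ecg = ecg, cd = cd, marks = marks,
                 rhythm_label = rhythm_label,
                 patient_id = patient_id, record_id = record_id),
            class = "signal_record")
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("<signal_record> %s/%s rhythm=%s, %.1f s ECG @ %g Hz, %d CC marks%s\n",
              x$patient_id, x$record_id, x$rhythm_label,
              trace_duration(x$ecg), x$ecg$fs, length(x$marks$t),
              if (is.null(x$cd)) "" else ", CD channel"))
  invisible(x)
}

#' Is a rhythm label shockable?
#'
#' VF and fast VT are shockable; asystole, PEA and pulse-generating rhythms
#' are not.
#' @param label character vector of rhythm labels.
#' @return Logical vector (`NA` for `"unknown"`).
#' @export
is_shockable <- function(label) {
  ifelse(label %in% c("VF", "VT"), TRUE,
         ifelse(label %in% c("ASY", "PEA", "PR"), FALSE, NA))
}

# ---- file I/O ---------------------------------------------------------------

#' Read a signal record from disk
#'
#' Two formats are supported. `"csv"`: a header line `time,ecg_mv,cd_mm`
#' (the `cd_mm` column optional) with one row per sample; the sampling rate
#' is inferred from the time column. Compression marks are read from a
#' sidecar file `<path>.marks` (one instant in seconds per line) when it
#' exists. `"wfdb"`: a WFDB-style header `<base>.hea` naming channels `ECG`
#' and `CD` with a 16-bit little-endian `.dat` file; marks come from
#' `<base>.marks`.
#'
#' @param path file path (`.csv` file, or the `.hea` file / base name for
#'   wfdb).
#' @param format `"csv"` or `"wfdb"`.
#' @param rhythm_label,patient_id,record_id metadata to attach.
#' @return A validated [signal_record()].
#' @export
read_record <- function(path, format = c("csv", "wfdb"),
                        rhythm_label = "unknown",
                        patient_id = "p0", record_id = NULL) {
  format <- match.arg(format)
  if (is.null(record_id))
    record_id <- sub("\\.(csv|hea)$", "", basename(path))
  if (format == "csv") .read_record_csv(path, rhythm_label, patient_id, record_id)
  else .read_record_wfdb(path, rhythm_label, patient_id, record_id)
}

.read_marks_file <- function(path) {
  if (!file.exists(path)) return(cc_marks())
  t <- scan(path, what = numeric(), quiet = TRUE)
  cc_marks(t)
}

.read_record_csv <- function(path, rhythm_label, patient_id, record_id) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path)
  if (!all(c("time", "ecg_mv") %in% names(d)))
    stop("CSV must have columns 'time' and 'ecg_mv'")
  if (nrow(d) < 2) stop("record too short")
  dt <- diff(d$time)
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt))
    stop("time column must be uniformly sampled")
  fs <- 1 / stats::median(dt)
  fs <- round(fs * 1e6) / 1e6
  t0 <- d$time[1]
  ecg <- signal_trace(d$ecg_mv, fs = fs, start_time = t0)
  cd <- if ("cd_mm" %in% names(d)) signal_trace(d$cd_mm, fs = fs, start_time = t0) else NULL
  marks <- .read_marks_file(paste0(path, ".marks"))
  signal_record(ecg, cd, marks, rhythm_label, patient_id, record_id)
}

#' Write a signal record to disk
#'
#' Inverse of [read_record()]. CSV output stores time, ECG and (when
#' present) CD columns; compression marks go to a `<path>.marks` sidecar.
#' WFDB output writes `<base>.hea` plus a 16-bit `.dat`; amplitudes are
#' quantized by the stored gain (1000 units/mV for ECG, 100 units/mm for CD).
#'
#' @param record a [signal_record()].
#' @param path output path (csv) or base name (wfdb).
#' @param format `"csv"` or `"wfdb"`.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  stopifnot(inherits(record, "signal_record"))
  if (format == "csv") {
    n <- length(record$ecg$samples)
    d <- data.frame(time = record$ecg$start_time + (seq_len(n) - 1) / record$ecg$fs,
                    ecg_mv = record$ecg$samples)
    if (!is.null(record$cd)) d$cd_mm <- record$cd$samples
    utils::write.csv(d, path, row.names = FALSE)
    if (length(record$marks$t))
      writeLines(format(record$marks$t, digits = 10), paste0(path, ".marks"))
  } else {
    .write_record_wfdb(record, path)
  }
  invisible(path)
}

# Minimal WFDB-style support: format-16 signed 16-bit little-endian samples,
# interleaved channels, gains in units per physical unit, zero baseline.
.write_record_wfdb <- function(record, base) {
  nsig <- if (is.null(record$cd)) 1L else 2L
  n <- length(record$ecg$samples)
  gains <- c(1000, 100)[seq_len(nsig)]
  names_ch <- c("ECG", "CD")[seq_len(nsig)]
  hea <- c(sprintf("%s %d %g %d", basename(base), nsig, record$ecg$fs, n),
           sprintf("%s.dat 16 %g 16 0 0 0 0 %s", basename(base), gains, names_ch))
  writeLines(hea, paste0(base, ".hea"))
  m <- rbind(record$ecg$samples * gains[1],
             if (nsig == 2L) record$cd$samples * gains[2])
  v <- as.integer(round(pmin(pmax(as.numeric(m), -32768), 32767)))
  con <- file(paste0(base, ".dat"), "wb")
  on.exit(close(con))
  writeBin(v, con, size = 2L, endian = "little")
  if (length(record$marks$t))
    writeLines(format(record$marks$t, digits = 10), paste0(base, ".marks"))
  invisible(base)
}

.read_record_wfdb <- function(path, rhythm_label, patient_id, record_id) {
  base <- sub("\\.hea$", "", path)
  hea_path <- paste0(base, ".hea")
  if (!file.exists(hea_path)) stop("header not found: ", hea_path)
  lines <- readLines(hea_path)
  hd <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(hd[2]); fs <- as.numeric(hd[3]); n <- as.integer(hd[4])
  sig <- lapply(lines[1 + seq_len(nsig)], function(l) strsplit(trimws(l), "\\s+")[[1]])
  fmt <- vapply(sig, `[`, "", 2)
  if (any(fmt != "16")) stop("only WFDB format 16 is supported")
  gains <- as.numeric(vapply(sig, `[`, "", 3))
  chnames <- vapply(sig, function(s) s[length(s)], "")
  con <- file(paste0(base, ".dat"), "rb")
  on.exit(close(con))
  v <- readBin(con, "integer", n = n * nsig, size = 2L, signed = TRUE,
               endian = "little")
  m <- matrix(as.numeric(v), nrow = nsig)
  i_ecg <- match("ECG", chnames)
  if (is.na(i_ecg)) stop("missing ECG channel")
  ecg <- signal_trace(m[i_ecg, ] / gains[i_ecg], fs = fs)
  i_cd <- match("CD", chnames)
  cd <- if (!is.na(i_cd)) signal_trace(m[i_cd, ] / gains[i_cd], fs = fs) else NULL
  marks <- .read_marks_file(paste0(base, ".marks"))
  signal_record(ecg, cd, marks, rhythm_label, patient_id, record_id)
}

# ---- preprocessing ----------------------------------------------------------

#' ECG conditioning band-pass
#'
#' Causal order-10 Butterworth band-pass, 0.5 to 30 Hz, realized as cascaded
#' second-order sections ([butter_sos()]): the monitor bandwidth typical of
#' automated external defibrillators. Removes baseline wander and
#' high-frequency noise ahead of artifact filtering and feature extraction.
#'
#' @param trace ECG [signal_trace()] at `fs` Hz (250 Hz by default; any other
#'   rate is rejected so that downstream sample counts stay consistent).
#' @param fs required sampling rate in Hz.
#' @return Band-limited [signal_trace()], same length and rate.
#' @export
bandpass_ecg <- function(trace, fs = 250) {
  stopifnot(inherits(trace, "signal_trace"))
  if (trace$fs != fs)
    stop(sprintf("expected fs = %g Hz, got %g Hz; resample first", fs, trace$fs))
  sos <- .cached_sos("bp_ecg", fs, function() butter_sos(5, c(0.5, 30), "pass", fs))
  signal_trace(sos_apply(sos, trace$samples), fs = fs, start_time = trace$start_time)
}

# per-session cache of filter designs
.sos_cache <- new.env(parent = emptyenv())
.cached_sos <- function(key, fs, fun) {
  k <- paste0(key, "@", fs)
  if (is.null(.sos_cache[[k]])) .sos_cache[[k]] <- fun()
  .sos_cache[[k]]
}

#' Split a record into 9-s analysis segments of three 3-s windows
#'
#' Segments are aligned to the start of the record and non-overlapping; a
#' trailing remainder shorter than 9 s is dropped. Each 3-s window holds
#' exactly `3 * fs` samples (750 at 250 Hz).
#'
#' @param record a [signal_record()] (or a bare [signal_trace()]) already
#'   preprocessed to the analysis rate.
#' @param fs expected sampling rate.
#' @return A list of segments; each segment is a list with `windows` (a
#'   `3*fs` x 3 matrix, one window per column), `start_time`, and
#'   `label` (`"Sh"`, `"NSh"` or `NA` from the record's rhythm label).
#' @export
extract_segments <- function(record, fs = 250) {
  trace <- if (inherits(record, "signal_record")) record$ecg else record
  stopifnot(inherits(trace, "signal_trace"))
  if (trace$fs != fs)
    stop(sprintf("expected fs = %g Hz, got %g Hz", fs, trace$fs))
  label <- NA_character_
  if (inherits(record, "signal_record")) {
    sh <- is_shockable(record$rhythm_label)
    if (!is.na(sh)) label <- if (sh) "Sh" else "NSh"
  }
  wlen <- 3L * fs
  nseg <- floor(length(trace$samples) / (3L * wlen))
  lapply(seq_len(nseg), function(i) {
    i0 <- (i - 1L) * 3L * wlen
    list(windows = matrix(trace$samples[i0 + seq_len(3L * wlen)], ncol = 3L),
         start_time = trace$start_time + i0 / fs,
         label = label)
  })
}

#' Resample and band-limit a record for analysis
#'
#' Brings the ECG (and CD channel, when present) to the analysis rate and
#' applies the 0.5 to 30 Hz conditioning band-pass to the ECG.
#'
#' @param record a [signal_record()].
#' @param fs analysis sampling rate in Hz.
#' @return A preprocessed [signal_record()].
#' @export
preprocess_record <- function(record, fs = 250) {
  stopifnot(inherits(record, "signal_record"))
  ecg <- bandpass_ecg(resample_to_fs(record$ecg, fs), fs = fs)
  cd <- if (!is.null(record$cd)) resample_to_fs(record$cd, fs) else NULL
  out <- record
  out$ecg <- ecg
  out$cd <- cd
  out
}
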