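# Recording ingestion, channel presets, zero-phase filtering and window
# segmentation.

#' Construct an EEG recording object
#'
#' A `recording` bundles a channels-by-samples signal matrix (microvolts)
#' with its sampling rate, ordered 10-20 channel labels and task
#' annotations. Annotations mark contiguous task epochs; windows are cut
#' strictly within an epoch so that every window carries an unambiguous
#' task label.
#'
#' @param signal numeric matrix, channels in rows, samples in columns.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_labels character vector of 10-20 channel names, one per
#'   row of `signal`. Labels are normalised (trailing dots stripped,
#'   canonical capitalisation restored).
#' @param annotations data frame with columns `onset` (seconds),
#'   `duration` (seconds) and `task` (one of `"left"`, `"right"`,
#'   `"rest"`, `"baseline"`). May have zero rows.
#' @param subject_id identifier attached to windows cut from this
#'   recording.
#' @return An object of class `recording`.
#' @export
recording <- function(signal, fs, channel_labels,
                      annotations = empty_annotations(),
                      subject_id = "unknown") {
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  channel_labels <- normalize_channel_label(channel_labels)
  if (nrow(signal) != length(channel_labels)) {
    stop("recording: ", nrow(signal), " signal rows but ",
         length(channel_labels), " channel labels", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("recording: sampling rate must be a single positive number",
         call. = FALSE)
  }
  annotations <- as.data.frame(annotations)
  required <- c("onset", "duration", "task")
  if (!all(required %in% names(annotations))) {
    stop("recording: annotations need columns onset, duration, task",
         call. = FALSE)
  }
  allowed <- c("left", "right", "rest", "baseline")
  if (nrow(annotations) > 0) {
    bad <- setdiff(unique(annotations$task), allowed)
    if (length(bad) > 0) {
      stop("recording: unknown task label(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    t_end <- ncol(signal) / fs
    if (any(annotations$onset < 0) ||
        any(annotations$onset + annotations$duration > t_end + 1e-9)) {
      stop("recording: annotation extends beyond the signal", call. = FALSE)
    }
  }
  structure(
    list(signal = signal, fs = fs, channel_labels = channel_labels,
         annotations = annotations, subject_id = as.character(subject_id)),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> subject=%s  %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, nrow(x$signal), ncol(x$signal), x$fs,
              ncol(x$signal) / x$fs))
  cat("  channels:", paste(utils::head(x$channel_labels, 8), collapse = " "),
      if (length(x$channel_labels) > 8) "..." else "", "\n")
  cat("  annotations:", nrow(x$annotations), "epochs\n")
  invisible(x)
}

empty_annotations <- function() {
  data.frame(onset = numeric(0), duration = numeric(0),
             task = character(0), stringsAsFactors = FALSE)
}

# Canonical 10-20 / 10-10 montage spellings used to restore capitalisation
# after stripping the source dataset's padded labels (e.g. "Fcz..").
montage_64 <- c(
  "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6",
  "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
  "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6",
  "Fp1", "Fpz", "Fp2",
  "AF7", "AF3", "AFz", "AF4", "AF8",
  "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
  "FT7", "FT8", "T7", "T8", "T9", "T10", "TP7", "TP8",
  "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
  "PO7", "PO3", "POz", "PO4", "PO8",
  "O1", "Oz", "O2", "Iz"
)

#' Normalise 10-20 channel labels
#'
#' Strips trailing dots and whitespace (as used by some EDF exporters to
#' pad labels) and restores canonical 10-20 capitalisation by
#' case-insensitive lookup against the standard 64-channel montage.
#' Labels not in the montage are returned trimmed but otherwise unchanged.
#'
#' @param labels character vector of raw channel labels.
#' @return character vector of normalised labels.
#' @export
normalize_channel_label <- function(labels) {
  trimmed <- sub("[. ]+$", "", trimws(as.character(labels)))
  idx <- match(toupper(trimmed), toupper(montage_64))
  out <- ifelse(is.na(idx), trimmed, montage_64[idx])
  as.character(out)
}

preset_8 <- c("Fz", "FCz", "C3", "C4", "F1", "F2", "AF3", "AF4")
preset_16 <- c(preset_8,
               "F4", "Fp1", "Fp2", "C1", "C2", "FC1", "FC2", "F3")

#' Channel presets
#'
#' The three electrode subsets compared by the authentication system:
#' a frontocentral 8-channel montage, a 16-channel extension, or all 64
#' recorded channels. The 8- and 16-channel sets follow the scalp
#' topography of motor function.
#'
#' @param name `"8"`, `"16"` or `"64"`.
#' @param all_labels for preset `"64"`, the recorded channel labels (the
#'   preset keeps their order).
#' @return An object of class `channel_preset` with fields `name` and
#'   `labels`.
#' @export
channel_preset <- function(name = c("8", "16", "64"), all_labels = NULL) {
  name <- match.arg(as.character(name), c("8", "16", "64"))
  labels <- switch(name,
    "8" = preset_8,
    "16" = preset_16,
    "64" = {
      if (is.null(all_labels)) {
        stop("channel_preset: preset \"64\" needs the recorded labels",
             call. = FALSE)
      }
      normalize_channel_label(all_labels)
    }
  )
  structure(list(name = name, labels = labels), class = "channel_preset")
}

#' Select and order channels by preset
#'
#' Reorders the recording's rows to the preset's label order. All preset
#' labels must be present.
#'
#' @param rec a [recording()].
#' @param preset a [channel_preset()] or a preset name (`"8"`, `"16"`,
#'   `"64"`).
#' @return A `recording` restricted to the preset's channels.
#' @export
select_channels <- function(rec, preset) {
  stopifnot(inherits(rec, "recording"))
  if (!inherits(preset, "channel_preset")) {
    preset <- channel_preset(preset, all_labels = rec$channel_labels)
  }
  idx <- match(preset$labels, rec$channel_labels)
  if (anyNA(idx)) {
    missing <- preset$labels[is.na(idx)]
    stop("select_channels: channel(s) not in recording: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  recording(rec$signal[idx, , drop = FALSE], rec$fs,
            rec$channel_labels[idx], rec$annotations, rec$subject_id)
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward and backward
#' (`signal::filtfilt`), giving net zero phase delay. Defaults match the
#' preprocessing of the authentication pipeline: 1-50 Hz.
#'
#' @param rec a [recording()].
#' @param lo,hi passband edges in Hz; `0 < lo < hi < fs/2`.
#' @param order filter order of the underlying Butterworth design.
#' @return The filtered `recording`.
#' @export
bandpass_zero_phase <- function(rec, lo = 1, hi = 50, order = 4) {
  stopifnot(inherits(rec, "recording"))
  nyq <- rec$fs / 2
  if (!(lo > 0 && lo < hi && hi < nyq)) {
    stop("bandpass_zero_phase: need 0 < lo < hi < fs/2 (fs/2 = ", nyq, ")",
         call. = FALSE)
  }
  bf <- signal::butter(order, c(lo, hi) / nyq, type = "pass")
  filtered <- t(apply(rec$signal, 1L,
                      function(x) signal::filtfilt(bf, x)))
  recording(filtered, rec$fs, rec$channel_labels, rec$annotations,
            rec$subject_id)
}

#' Construct a trial window
#'
#' @param data channels-by-samples numeric matrix.
#' @param task `"left"` or `"right"`.
#' @param subject_id subject identifier.
#' @param fs sampling rate in Hz.
#' @param channel_labels channel labels for the rows of `data`.
#' @param window_len_s window length in seconds.
#' @param source_trial_index index of the annotated trial the window was
#'   cut from.
#' @return An object of class `trial_window`.
#' @export
trial_window <- function(data, task, subject_id, fs, channel_labels,
                         window_len_s = 2, source_trial_index = NA_integer_) {
  task <- match.arg(task, c("left", "right"))
  data <- as.matrix(data)
  if (ncol(data) != round(window_len_s * fs)) {
    stop("trial_window: expected ", round(window_len_s * fs),
         " samples, got ", ncol(data), call. = FALSE)
  }
  structure(
    list(data = data, task = task, subject_id = as.character(subject_id),
         fs = fs, channel_labels = channel_labels,
         window_len_s = window_len_s,
         source_trial_index = as.integer(source_trial_index)),
    class = "trial_window"
  )
}

#' @export
print.trial_window <- function(x, ...) {
  cat(sprintf("<trial_window> subject=%s task=%s trial=%d  %d ch x %d samples @ %g Hz\n",
              x$subject_id, x$task, x$source_trial_index,
              nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}

#' Segment annotated task epochs into overlapping windows
#'
#' Cuts sliding windows of `win_s` seconds with fractional `overlap`
#' within each annotated `left`/`right` epoch (never across epochs).
#' Per epoch of length T seconds the number of windows is
#' `floor((T - win_s) / (win_s * (1 - overlap))) + 1`; epochs shorter than
#' one window yield none (with a warning). With the defaults, a 4 s trial
#' yields 5 windows starting every 0.5 s, so 21 trials yield 105 windows.
#'
#' @param rec a [recording()].
#' @param win_s window length in seconds (default 2).
#' @param overlap fractional overlap between consecutive windows in
#'   `[0, 1)` (default 0.75).
#' @param tasks annotation labels to segment (default the two
#'   authentication tasks).
#' @return A list of [trial_window()] objects.
#' @export
segment_windows <- function(rec, win_s = 2, overlap = 0.75,
                            tasks = c("left", "right")) {
  stopifnot(inherits(rec, "recording"))
  if (!(overlap >= 0 && overlap < 1)) {
    stop("segment_windows: overlap must be in [0, 1)", call. = FALSE)
  }
  step_s <- win_s * (1 - overlap)
  n_samp <- round(win_s * rec$fs)
  ann <- rec$annotations
  ann <- ann[ann$task %in% tasks, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(ann))) {
    T_s <- ann$duration[i]
    if (T_s < win_s - 1e-9) {
      warning("segment_windows: trial ", i, " (", ann$task[i], ", ",
              signif(T_s, 3), " s) shorter than the window; skipped",
              call. = FALSE)
      next
    }
    n_win <- floor((T_s - win_s) / step_s + 1e-9) + 1
    for (k in seq_len(n_win)) {
      start <- round((ann$onset[i] + (k - 1) * step_s) * rec$fs) + 1L
      idx <- start:(start + n_samp - 1L)
      out[[length(out) + 1L]] <- trial_window(
        rec$signal[, idx, drop = FALSE], ann$task[i], rec$subject_id,
        rec$fs, rec$channel_labels, win_s, i
      )
    }
  }
  out
}

## ---- EDF and array-bundle I/O ------------------------------------------

pad_ascii <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a recording to EDF
#'
#' Writes classic EDF (16-bit samples, one-second data records). The
#' sampling rate must be a whole number; the signal is zero-padded to a
#' whole number of seconds. Annotations are written to a plain-CSV
#' sidecar `<path>.annotations.csv` (columns onset, duration, task),
#' re-read automatically by [load_recording()].
#'
#' @param rec a [recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) {
    stop("write_edf: sampling rate must be an integer number of Hz",
         call. = FALSE)
  }
  fs <- as.integer(round(fs))
  nc <- nrow(rec$signal)
  n_rec <- ceiling(ncol(rec$signal) / fs)
  sig <- rec$signal
  if (ncol(sig) < n_rec * fs) {
    sig <- cbind(sig, matrix(0, nc, n_rec * fs - ncol(sig)))
  }
  # per-channel physical scaling onto the 16-bit digital range
  pmin <- apply(sig, 1, min)
  pmax <- apply(sig, 1, max)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  dmin <- -32768L
  dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(pad_ascii(x, width), con,
                                     nchars = width, eos = NULL)
  wr("0", 8)
  wr("X X X X", 80)
  wr(paste("Startdate 01-JAN-2000", rec$subject_id), 80)
  wr("01.01.00", 8)
  wr("00.00.00", 8)
  wr(256L * (1L + nc), 8)
  wr("", 44)
  wr(n_rec, 8)
  wr(1L, 8)
  wr(nc, 4)
  for (lab in rec$channel_labels) wr(lab, 16)
  for (i in seq_len(nc)) wr("EEG electrode", 80)
  for (i in seq_len(nc)) wr("uV", 8)
  for (i in seq_len(nc)) wr(formatC(pmin[i], digits = 6, format = "g"), 8)
  for (i in seq_len(nc)) wr(formatC(pmax[i], digits = 6, format = "g"), 8)
  for (i in seq_len(nc)) wr(dmin, 8)
  for (i in seq_len(nc)) wr(dmax, 8)
  for (i in seq_len(nc)) wr("", 80)
  for (i in seq_len(nc)) wr(fs, 8)
  for (i in seq_len(nc)) wr("", 32)

  scale <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    block <- sig[, cols, drop = FALSE]
    dig <- round((block - pmin) * scale + dmin)
    dig <- pmin(pmax(dig, dmin), dmax)
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }

  if (nrow(rec$annotations) > 0) {
    utils::write.csv(rec$annotations,
                     paste0(path, ".annotations.csv"), row.names = FALSE)
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)                               # version
  rd(80)                              # patient
  rec_field <- rd(80)
  rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nc <- suppressWarnings(as.integer(rd(4)))
  if (is.na(nc) || nc < 1) {
    stop("read_edf: malformed EDF header (no signal count)", call. = FALSE)
  }
  labels <- vapply(seq_len(nc), function(i) rd(16), "")
  if (all(labels == "")) {
    stop("read_edf: EDF file has no channel label table", call. = FALSE)
  }
  for (i in seq_len(nc)) rd(80)       # transducer
  for (i in seq_len(nc)) rd(8)        # physical dimension
  pmin <- vapply(seq_len(nc), function(i) as.numeric(rd(8)), 0)
  pmax <- vapply(seq_len(nc), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(nc), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(nc), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(nc)) rd(80)       # prefiltering
  spr <- vapply(seq_len(nc), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(nc)) rd(32)
  seek(con, header_bytes)
  if (length(unique(spr)) != 1L) {
    stop("read_edf: channels with differing sampling rates are not supported",
         call. = FALSE)
  }
  fs <- spr[1] / rec_dur
  sig <- matrix(0, nc, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = nc * spr[1], size = 2,
                   endian = "little")
    block <- matrix(raw, nrow = spr[1], ncol = nc)
    cols <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    sig[, cols] <- t(block)
  }
  sig <- (sig - dmin) / (dmax - dmin) * (pmax - pmin) + pmin
  subject <- sub("^Startdate \\S+ ?", "", rec_field)
  if (subject == "") subject <- "unknown"
  ann_path <- paste0(path, ".annotations.csv")
  ann <- if (file.exists(ann_path)) {
    utils::read.csv(ann_path, stringsAsFactors = FALSE)
  } else {
    empty_annotations()
  }
  recording(sig, fs, labels, ann, subject)
}

#' Write a recording as an array bundle
#'
#' The array bundle is the package's native serialisation: a single RDS
#' file holding the signal matrix, sampling rate, labels, annotations and
#' subject id. Unlike EDF it round-trips the signal exactly.
#'
#' @param rec a [recording()].
#' @param path output file path (conventionally `.rds`).
#' @return `path`, invisibly.
#' @export
write_bundle <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  saveRDS(list(format = "eegauth-bundle", version = 1L,
               signal = rec$signal, fs = rec$fs,
               channel_labels = rec$channel_labels,
               annotations = rec$annotations,
               subject_id = rec$subject_id),
          path)
  invisible(path)
}

read_bundle <- function(path) {
  x <- readRDS(path)
  if (!is.list(x) || !identical(x$format, "eegauth-bundle")) {
    stop("read_bundle: not an eegauth array bundle: ", path, call. = FALSE)
  }
  recording(x$signal, x$fs, x$channel_labels, x$annotations, x$subject_id)
}

#' Load an EEG recording
#'
#' Reads either classic EDF (with optional `<path>.annotations.csv`
#' sidecar) or the package's array bundle. Channel labels are normalised
#' to canonical 10-20 spellings.
#'
#' @param path file path.
#' @param format `"edf"` or `"bundle"`; `"auto"` guesses from the file
#'   extension.
#' @return A [recording()].
#' @export
load_recording <- function(path, format = c("auto", "edf", "bundle")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("load_recording: file not found: ", path, call. = FALSE)
  }
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
              else "bundle"
  }
  switch(format, edf = read_edf(path), bundle = read_bundle(path))
}
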