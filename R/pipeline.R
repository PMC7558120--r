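# End-to-end driver helpers: recording -> windows -> feature matrices,
# organised per subject and task for the cross-validation machinery.

#' Preprocess one recording into trial windows
#'
#' Channel-preset selection, 1-50 Hz zero-phase band-pass, and
#' segmentation of the annotated task epochs into 2 s windows with 75%
#' overlap (defaults of the authentication pipeline).
#'
#' @param rec a [recording()].
#' @param preset channel preset (name or [channel_preset()]); NULL keeps
#'   all channels.
#' @param lo,hi band-pass edges in Hz.
#' @param win_s,overlap window length (s) and fractional overlap.
#' @return List of [trial_window()]s.
#' @export
preprocess_recording <- function(rec, preset = "8", lo = 1, hi = 50,
                                 win_s = 2, overlap = 0.75) {
  if (!is.null(preset)) rec <- select_channels(rec, preset)
  rec <- bandpass_zero_phase(rec, lo, hi)
  segment_windows(rec, win_s, overlap)
}

#' Extract feature matrices for a cohort
#'
#' Runs preprocessing and the 18-feature bank over every subject and
#' task. This is the expensive step of the pipeline and is independent
#' of any train/test split, so it is computed once per cohort.
#'
#' @param cohort an `eeg_cohort` from [generate_cohort()], or a named
#'   list of [recording()]s.
#' @param preset channel preset; defaults to the cohort's own preset (or
#'   `"8"` for a plain recording list).
#' @param lo,hi,win_s,overlap see [preprocess_recording()].
#' @param cfg an [emd_config()].
#' @param p an [entropy_params()].
#' @return An object of class `cohort_features`: `subjects` is a named
#'   list, each with `left` and `right` lists of [feature_matrix()]s.
#' @export
extract_cohort_features <- function(cohort, preset = NULL, lo = 1, hi = 50,
                                    win_s = 2, overlap = 0.75,
                                    cfg = emd_config(),
                                    p = entropy_params()) {
  if (inherits(cohort, "eeg_cohort")) {
    if (is.null(preset)) preset <- cohort$spec$preset
    recordings <- cohort$recordings
  } else {
    if (is.null(preset)) preset <- "8"
    recordings <- cohort
  }
  stopifnot(length(names(recordings)) == length(recordings))
  subjects <- list()
  for (id in names(recordings)) {
    windows <- preprocess_recording(recordings[[id]], preset, lo, hi,
                                    win_s, overlap)
    fms <- lapply(windows, build_feature_matrix, cfg = cfg, p = p)
    tasks <- vapply(windows, function(w) w$task, "")
    subjects[[id]] <- list(left = fms[tasks == "left"],
                           right = fms[tasks == "right"])
  }
  structure(list(subjects = subjects, preset = preset,
                 win_s = win_s, overlap = overlap),
            class = "cohort_features")
}

#' @export
print.cohort_features <- function(x, ...) {
  n_win <- vapply(x$subjects, function(s)
    length(s$left) + length(s$right), 0)
  cat(sprintf("<cohort_features> %d subjects, preset %s, %s windows/subject\n",
              length(x$subjects), x$preset,
              paste(unique(n_win), collapse = "/")))
  invisible(x)
}
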