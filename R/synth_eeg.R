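# Synthetic multi-subject EEG cohorts with controllable between-subject
# separability, so the full authentication pipeline can be exercised and
# validated without any external download.
#
# Each channel mixes: an AR(2) broadband background, a shared-per-group
# mu (~10 Hz) oscillator, a shared-per-group beta (~22 Hz) oscillator,
# and white noise whose weight ("complexity") governs the entropy level.
# Subjects differ in band amplitudes, oscillator frequencies, AR
# coefficients and complexity, with a between-subject spread proportional
# to the cohort's `separation` parameter (0 = identical subjects). The
# two channel groups (left/right hemisphere) carry distinct gains and
# share their oscillators, planting the 2-cluster channel structure; the
# motor task attenuates the mu rhythm of the contralateral group, so the
# two tasks are distinguishable and the AND gate is meaningful.

ar2_stationary <- function(a) {
  length(a) == 2 && (a[1] + a[2] < 1) && (a[2] - a[1] < 1) && abs(a[2]) < 1
}

#' AR(2) coefficients from a resonance pole
#'
#' Maps a complex-conjugate pole pair (modulus `rho` < 1, resonance
#' frequency `freq` Hz at sampling rate `fs`) to AR(2) coefficients
#' `c(2 rho cos(2 pi freq / fs), -rho^2)`; always stationary. The
#' synthetic background uses a low-frequency resonance so the broadband
#' white-noise term alone controls the high-frequency irregularity.
#'
#' @param rho pole modulus in (0, 1).
#' @param freq resonance frequency in Hz.
#' @param fs sampling rate in Hz.
#' @return Length-2 coefficient vector.
#' @export
ar2_from_pole <- function(rho = 0.95, freq = 2, fs = 160) {
  stopifnot(rho > 0, rho < 1, freq >= 0, freq < fs / 2)
  c(2 * rho * cos(2 * pi * freq / fs), -rho^2)
}

# hemisphere split: odd electrode numbers = left, even = right; midline
# (z) channels are assigned alternately to keep the groups balanced.
split_channel_groups <- function(labels) {
  num <- suppressWarnings(as.integer(gsub("\\D", "", labels)))
  is_z <- grepl("z$", labels, ignore.case = TRUE) | is.na(num)
  group <- ifelse(!is_z & num %% 2 == 1, "a",
                  ifelse(!is_z, "b", NA))
  z_idx <- which(is.na(group))
  if (length(z_idx) > 0) {
    group[z_idx] <- rep(c("a", "b"), length.out = length(z_idx))
  }
  list(a = labels[group == "a"], b = labels[group == "b"])
}

#' Synthetic subject specification
#'
#' Fixed per-subject generative parameters; drawn around the cohort base
#' by [generate_cohort()], or constructed directly for focused tests.
#'
#' @param subject_id identifier.
#' @param channel_labels channel labels of the montage.
#' @param mu_power,beta_power per-channel oscillator amplitudes
#'   (microvolts; scalars are recycled).
#' @param mu_freq,beta_freq oscillator centre frequencies (Hz), inside
#'   the mu (7.5-12.5) and beta (16-31) bands.
#' @param ar_coeffs AR(2) background coefficients (must be stationary);
#'   default a low-frequency resonance from [ar2_from_pole()].
#' @param ar_sd innovation SD of the AR background (microvolts).
#' @param complexity white-noise SD (microvolts) controlling the entropy
#'   level of the high-frequency modes.
#' @param channel_groups list with elements `a` and `b` partitioning the
#'   labels; defaults to the hemisphere split.
#' @param attenuation multiplicative mu attenuation of the
#'   task-contralateral group (default 0.45).
#' @param seed subject-level seed.
#' @return An object of class `subject_spec`.
#' @export
subject_spec <- function(subject_id, channel_labels,
                         mu_power = 6, beta_power = 3,
                         mu_freq = 10, beta_freq = 22,
                         ar_coeffs = ar2_from_pole(), ar_sd = 0.5,
                         complexity = 2,
                         channel_groups = NULL,
                         attenuation = 0.45, seed = 1L) {
  if (!ar2_stationary(ar_coeffs)) {
    stop("subject_spec: AR(2) coefficients are not stationary",
         call. = FALSE)
  }
  stopifnot(all(mu_power >= 0), all(beta_power >= 0), complexity >= 0)
  nc <- length(channel_labels)
  if (is.null(channel_groups)) {
    channel_groups <- split_channel_groups(channel_labels)
  }
  structure(list(
    subject_id = as.character(subject_id),
    channel_labels = channel_labels,
    mu_power = rep_len(mu_power, nc), beta_power = rep_len(beta_power, nc),
    mu_freq = mu_freq, beta_freq = beta_freq,
    ar_coeffs = ar_coeffs, ar_sd = ar_sd, complexity = complexity,
    channel_groups = channel_groups, attenuation = attenuation,
    seed = as.integer(seed)
  ), class = "subject_spec")
}

#' Generate one synthetic trial epoch
#'
#' @param spec a [subject_spec()].
#' @param task `"left"` or `"right"`; the mu oscillator of the
#'   contralateral channel group is attenuated.
#' @param trial_len_s epoch length in seconds (default 4).
#' @param fs sampling rate in Hz (default 160).
#' @param seed trial-level seed (deterministic given spec + seed).
#' @return Channels-by-samples numeric matrix.
#' @export
generate_subject_trial <- function(spec, task = c("left", "right"),
                                   trial_len_s = 4, fs = 160, seed = 1L) {
  task <- match.arg(task)
  stopifnot(inherits(spec, "subject_spec"))
  rng <- local_rng(seed)
  nc <- length(spec$channel_labels)
  n <- round(trial_len_s * fs)
  t <- (seq_len(n) - 1) / fs

  in_a <- spec$channel_labels %in% spec$channel_groups$a
  # contralateral control: left hand -> right hemisphere (group b)
  att <- rep(1, nc)
  att[if (task == "left") !in_a else in_a] <- spec$attenuation

  osc <- function(freq) {
    phase <- rng$runif(1, 0, 2 * pi)
    mod_phase <- rng$runif(1, 0, 2 * pi)
    envl <- 1 + 0.3 * sin(2 * pi * 0.7 * t + mod_phase)
    envl * sin(2 * pi * freq * t + phase)
  }
  mu_a <- osc(spec$mu_freq);  mu_b <- osc(spec$mu_freq)
  be_a <- osc(spec$beta_freq); be_b <- osc(spec$beta_freq)

  sig <- matrix(0, nc, n)
  for (ch in seq_len(nc)) {
    bg <- stats::filter(rng$rnorm(n, 0, spec$ar_sd), spec$ar_coeffs,
                        method = "recursive")
    mu_osc <- if (in_a[ch]) mu_a else mu_b
    be_osc <- if (in_a[ch]) be_a else be_b
    sig[ch, ] <- as.numeric(bg) +
      att[ch] * spec$mu_power[ch] * mu_osc +
      spec$beta_power[ch] * be_osc +
      rng$rnorm(n, 0, spec$complexity)
  }
  sig
}

#' Cohort specification
#'
#' @param n_subjects number of subjects (>= 3).
#' @param n_trials_per_task annotated trials per task per subject
#'   (>= 21; default 21, which yields 105 two-second windows per task at
#'   75% overlap).
#' @param trial_len_s trial epoch length in seconds (default 4).
#' @param fs sampling rate in Hz (default 160).
#' @param preset channel preset name (`"8"`, `"16"`, `"64"`).
#' @param separation non-negative scalar scaling the between-subject
#'   spread of all generative parameters; 0 makes subjects identically
#'   distributed.
#' @param seed cohort seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 5L, n_trials_per_task = 21L,
                        trial_len_s = 4, fs = 160, preset = "8",
                        separation = 1, seed = 1L) {
  stopifnot(n_subjects >= 3, n_trials_per_task >= 21, separation >= 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_trials_per_task = as.integer(n_trials_per_task),
                 trial_len_s = trial_len_s, fs = fs,
                 preset = as.character(preset),
                 separation = separation, seed = as.integer(seed)),
            class = "cohort_spec")
}

draw_subject_spec <- function(id, labels, separation, rng) {
  nc <- length(labels)
  groups <- split_channel_groups(labels)
  # distinct group gains plant the 2-cluster structure
  ggain <- ifelse(labels %in% groups$a, 1.3, 0.7)
  chan_jitter <- 1 + 0.08 * separation * rng$rnorm(nc)
  mu_gain <- exp(separation * rng$rnorm(1, 0, 0.4))
  beta_gain <- exp(separation * rng$rnorm(1, 0, 0.4))
  mu_freq <- min(max(10 + separation * rng$rnorm(1, 0, 1.0), 8), 12.4)
  beta_freq <- min(max(22 + separation * rng$rnorm(1, 0, 2.0), 16.5), 30)
  rho <- min(max(0.95 + 0.015 * separation * rng$rnorm(1), 0.85), 0.985)
  bg_freq <- min(max(2 * exp(separation * rng$rnorm(1, 0, 0.4)), 0.5), 6)
  ar <- ar2_from_pole(rho, bg_freq, 160)
  complexity <- 2 * exp(separation * rng$rnorm(1, 0, 0.5))
  subject_spec(
    id, labels,
    mu_power = 6 * mu_gain * ggain * abs(chan_jitter),
    beta_power = 3 * beta_gain * ggain * abs(chan_jitter),
    mu_freq = mu_freq, beta_freq = beta_freq,
    ar_coeffs = ar, ar_sd = 0.5 * exp(0.2 * separation * rng$rnorm(1)),
    complexity = complexity, channel_groups = groups,
    seed = rng$derive_seed()
  )
}

#' Generate a synthetic cohort of recordings
#'
#' Draws one [subject_spec()] per subject around the common base (spread
#' proportional to `separation`) and synthesises, per subject, a
#' continuous recording of `2 * n_trials_per_task` annotated task epochs
#' in seeded random order.
#'
#' @param spec a [cohort_spec()].
#' @return An object of class `eeg_cohort`: list with `recordings`
#'   (named list of [recording()]s), `specs`, and the `cohort_spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  labels <- if (spec$preset == "64") montage_64
            else channel_preset(spec$preset)$labels
  rng <- local_rng(spec$seed)
  recs <- list()
  specs <- list()
  for (s in seq_len(spec$n_subjects)) {
    id <- sprintf("S%03d", s)
    sspec <- draw_subject_spec(id, labels, spec$separation, rng)
    srng <- local_rng(sspec$seed)
    tasks <- rep(c("left", "right"), each = spec$n_trials_per_task)
    tasks <- tasks[srng$sample_int(length(tasks))]
    n_trial <- round(spec$trial_len_s * spec$fs)
    sig <- matrix(0, length(labels), n_trial * length(tasks))
    ann <- data.frame(onset = (seq_along(tasks) - 1) * spec$trial_len_s,
                      duration = spec$trial_len_s, task = tasks,
                      stringsAsFactors = FALSE)
    for (k in seq_along(tasks)) {
      cols <- ((k - 1) * n_trial + 1):(k * n_trial)
      sig[, cols] <- generate_subject_trial(sspec, tasks[k],
                                            spec$trial_len_s, spec$fs,
                                            seed = srng$derive_seed())
    }
    recs[[id]] <- recording(sig, spec$fs, labels, ann, id)
    specs[[id]] <- sspec
  }
  structure(list(recordings = recs, specs = specs, spec = spec),
            class = "eeg_cohort")
}

#' @export
print.eeg_cohort <- function(x, ...) {
  cat(sprintf("<eeg_cohort> %d subjects, %d trials/task, preset %s, separation %g, seed %d\n",
              x$spec$n_subjects, x$spec$n_trials_per_task, x$spec$preset,
              x$spec$separation, x$spec$seed))
  invisible(x)
}

#' Write a cohort to disk
#'
#' One file per subject (EDF with annotation sidecar, or array bundle).
#'
#' @param cohort an `eeg_cohort`.
#' @param dir output directory (created if needed).
#' @param format `"edf"` or `"bundle"`.
#' @return Character vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("edf", "bundle")) {
  format <- match.arg(format)
  stopifnot(inherits(cohort, "eeg_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "edf") ".edf" else ".rds"
  paths <- character(0)
  for (id in names(cohort$recordings)) {
    p <- file.path(dir, paste0(id, ext))
    if (format == "edf") write_edf(cohort$recordings[[id]], p)
    else write_bundle(cohort$recordings[[id]], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
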