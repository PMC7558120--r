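test_that("EDF round-trip preserves structure and signal within 16-bit tolerance", {
  rec <- make_test_recording()
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- load_recording(path, "edf")
  expect_equal(back$fs, 160)
  expect_identical(back$channel_labels, rec$channel_labels)
  expect_equal(dim(back$signal), dim(rec$signal))
  expect_equal(back$annotations$task, rec$annotations$task)
  expect_equal(back$annotations$onset, rec$annotations$onset)
  # 16-bit quantisation over the per-channel range
  span <- max(rec$signal) - min(rec$signal)
  expect_lt(max(abs(back$signal - rec$signal)), span / 65535 * 2)
  expect_equal(back$subject_id, "T01")
})

test_that("array bundle round-trips the signal exactly", {
  rec <- make_test_recording(n_channels = 3, n_trials = 2,
                             labels = c("Fz", "Cz", "Pz"))
  path <- withr::local_tempfile(fileext = ".rds")
  write_bundle(rec, path)
  back <- load_recording(path, "bundle")
  expect_identical(back$signal, rec$signal)
  expect_identical(back$channel_labels, rec$channel_labels)
  expect_identical(back$annotations, rec$annotations)
})

test_that("unreadable or malformed files raise errors", {
  expect_error(load_recording(file.path(tempdir(), "nope.edf")),
               "not found")
  bad <- withr::local_tempfile(fileext = ".edf")
  writeBin(raw(64), bad)
  # header fields full of NULs also raise coercion warnings; only the
  # error matters here
  suppressWarnings(expect_error(load_recording(bad, "edf")))
  notbundle <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), notbundle)
  expect_error(load_recording(notbundle, "bundle"), "bundle")
})

test_that("channel labels are normalised from dataset-style spellings", {
  expect_identical(normalize_channel_label(c("FCZ..", "fz", "Af3", "C3..")),
                   c("FCz", "Fz", "AF3", "C3"))
  # unknown labels pass through trimmed
  expect_identical(normalize_channel_label("EOG1."), "EOG1")
})

test_that("channel presets select and order the documented montages", {
  rec <- make_test_recording(n_channels = 8)
  # scramble the channel order, selection must restore preset order
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  scrambled <- recording(rec$signal[perm, ], rec$fs,
                         rec$channel_labels[perm], rec$annotations,
                         rec$subject_id)
  sel <- select_channels(scrambled, "8")
  expect_identical(sel$channel_labels,
                   c("Fz", "FCz", "C3", "C4", "F1", "F2", "AF3", "AF4"))
  expect_identical(sel$signal[1, ], rec$signal[1, ])  # Fz row restored

  p16 <- channel_preset("16")
  expect_length(p16$labels, 16)
  expect_true(all(c("F4", "Fp1", "Fp2", "C1", "C2", "FC1", "FC2", "F3")
                  %in% p16$labels))
  expect_identical(p16$labels[1:8],
                   c("Fz", "FCz", "C3", "C4", "F1", "F2", "AF3", "AF4"))

  # missing channel errors by name
  rec7 <- recording(rec$signal[-2, ], rec$fs, rec$channel_labels[-2],
                    rec$annotations, rec$subject_id)
  expect_error(select_channels(rec7, "8"), "FCz")
})

test_that("selecting a preset after the full montage equals selecting it directly", {
  labels64 <- eegauth:::montage_64
  set.seed(4)
  sig <- matrix(rnorm(64 * 320), 64)
  rec <- recording(sig, 160, labels64)
  via64 <- select_channels(select_channels(rec, "64"), "8")
  direct <- select_channels(rec, "8")
  expect_identical(via64$signal, direct$signal)
  expect_identical(via64$channel_labels, direct$channel_labels)
})

test_that("zero-phase band-pass passes band tones, kills drift, keeps symmetry", {
  fs <- 160
  t <- (0:(fs * 8 - 1)) / fs
  tone10 <- sin(2 * pi * 10 * t)
  drift <- sin(2 * pi * 0.1 * t)
  rec <- recording(rbind(tone10, drift), fs, c("C3", "C4"))
  out <- bandpass_zero_phase(rec)
  # FFT amplitude ratio oracle
  a_in <- fft_amplitude(tone10, fs, 10)
  a_out <- fft_amplitude(out$signal[1, ], fs, 10)
  expect_lt(abs(a_out / a_in - 1), 0.02)
  d_in <- fft_amplitude(drift, fs, 0.1)
  d_out <- fft_amplitude(out$signal[2, ], fs, 0.1)
  expect_lt(20 * log10(d_out / d_in), -20)

  # symmetric pulse stays centred (zero net phase)
  pulse <- exp(-((seq_len(640) - 320)^2) / 50)
  prec <- recording(matrix(pulse, 1), fs, "Cz")
  pout <- bandpass_zero_phase(prec, 1, 50)
  expect_equal(which.max(pout$signal[1, ]), 320)

  expect_error(bandpass_zero_phase(rec, 1, 90), "fs/2")
})

test_that("band-pass is near-idempotent at band-centre tones", {
  fs <- 160
  t <- (0:(fs * 8 - 1)) / fs
  rec <- recording(matrix(sin(2 * pi * 15 * t), 1), fs, "Cz")
  once <- bandpass_zero_phase(rec)
  twice <- bandpass_zero_phase(once)
  a1 <- fft_amplitude(once$signal[1, ], fs, 15)
  a2 <- fft_amplitude(twice$signal[1, ], fs, 15)
  expect_lt(abs(a2 / a1 - 1), 0.02)
})

test_that("window segmentation arithmetic matches the overlap formula", {
  rec <- make_test_recording(n_channels = 2, n_trials = 1,
                             labels = c("C3", "C4"))
  wins <- segment_windows(rec)
  expect_length(wins, 5)
  starts <- vapply(wins, function(w) w$source_trial_index, 0L)
  expect_true(all(starts == 1))
  expect_equal(ncol(wins[[1]]$data), 320)
  expect_identical(wins[[1]]$data[, 1], rec$signal[, 1])
  # starts at 0, .5, 1, 1.5, 2 s
  w3 <- wins[[3]]
  expect_identical(w3$data[, 1], rec$signal[, 160 + 1])
})

test_that("21 four-second trials yield 105 windows per task", {
  rec <- make_test_recording(n_channels = 2, n_trials = 42,
                             labels = c("C3", "C4"))
  wins <- segment_windows(rec)
  tasks <- vapply(wins, function(w) w$task, "")
  expect_equal(sum(tasks == "left"), 105)
  expect_equal(sum(tasks == "right"), 105)
})

test_that("short trials yield zero windows with a warning", {
  fs <- 160
  sig <- matrix(rnorm(2 * fs * 2), 2)
  ann <- data.frame(onset = 0, duration = 1.9, task = "left")
  rec <- recording(sig, fs, c("C3", "C4"), ann)
  expect_warning(wins <- segment_windows(rec), "shorter")
  expect_length(wins, 0)
})

test_that("window count matches brute-force enumeration of start offsets", {
  fs <- 160
  win_s <- 2
  step <- 0.5
  set.seed(11)
  for (T_s in round(runif(12, 2, 60), 1)) {
    sig <- matrix(rnorm(ceiling(T_s * fs) + fs), 1)
    ann <- data.frame(onset = 0, duration = T_s, task = "left")
    rec <- recording(sig, fs, "Cz", ann)
    wins <- segment_windows(rec)
    brute <- sum(seq(0, T_s, by = step) + win_s <= T_s + 1e-9)
    expect_length(wins, brute)
  }
})
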