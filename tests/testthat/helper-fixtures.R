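# Shared fixtures and independent oracles used across the test files.

# A small deterministic recording: sum of tones + noise, with annotated
# left/right epochs.
make_test_recording <- function(n_channels = 8, fs = 160, n_trials = 4,
                                trial_len_s = 4, seed = 1,
                                labels = c("Fz", "FCz", "C3", "C4",
                                           "F1", "F2", "AF3", "AF4")) {
  set.seed(seed)
  labels <- labels[seq_len(n_channels)]
  n <- fs * trial_len_s * n_trials
  t <- (seq_len(n) - 1) / fs
  sig <- t(sapply(seq_len(n_channels), function(ch) {
    3 * sin(2 * pi * (8 + ch) * t + ch) + rnorm(n)
  }))
  ann <- data.frame(
    onset = (seq_len(n_trials) - 1) * trial_len_s,
    duration = trial_len_s,
    task = rep(c("left", "right"), length.out = n_trials),
    stringsAsFactors = FALSE
  )
  recording(sig, fs, labels, ann, "T01")
}

# Random trial window for feature-bank tests.
make_test_window <- function(n_channels = 4, fs = 160, win_s = 2,
                             seed = 1) {
  set.seed(seed)
  n <- fs * win_s
  t <- (seq_len(n) - 1) / fs
  data <- t(sapply(seq_len(n_channels), function(ch) {
    2 * sin(2 * pi * 10 * t + ch) + sin(2 * pi * 22 * t) + rnorm(n)
  }))
  trial_window(data, "left", "T01", fs, paste0("ch", seq_len(n_channels)),
               win_s)
}

# Independent brute-force ApEn: double-loop template counting, written
# directly from the definition (Chebyshev distance, self-matches
# included).
brute_apen <- function(x, m = 2, r_frac = 0.15) {
  n <- length(x)
  r <- r_frac * sd(x)
  phi <- function(mm) {
    nt <- n - mm + 1
    cnt <- numeric(nt)
    for (i in seq_len(nt)) {
      for (j in seq_len(nt)) {
        d <- max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)]))
        if (d <= r) cnt[i] <- cnt[i] + 1
      }
    }
    mean(log(cnt / nt))
  }
  phi(m) - phi(m + 1)
}

# Independent brute-force SampEn: pair counting over the first N - m
# templates, self-matches excluded.
brute_sampen <- function(x, m = 2, r_frac = 0.15) {
  n <- length(x)
  r <- r_frac * sd(x)
  count <- function(mm) {
    nt <- n - m          # same template range for both lengths
    total <- 0
    for (i in seq_len(nt - 1)) {
      for (j in (i + 1):nt) {
        d <- max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)]))
        if (d <= r) total <- total + 1
      }
    }
    total
  }
  B <- count(m)
  A <- count(m + 1)
  if (A == B || B == 0) return(0)
  if (A == 0) return(log(B * (n - m)))
  -log(A / B)
}

# FFT amplitude of the nearest bin to a target frequency.
fft_amplitude <- function(x, fs, freq) {
  n <- length(x)
  sp <- abs(fft(x)) / n * 2
  bin <- round(freq * n / fs) + 1
  sp[bin]
}

# Extrema / zero-crossing counts for the IMF admissibility check.
count_extrema <- function(x) {
  d <- diff(x)
  s <- sign(d)
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(diff(s) != 0)
}

count_zc <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(diff(s) != 0)
}

# Tiny precomputed feature-matrix stacks with planted channel structure.
planted_group_stack <- function(n_windows = 40, n_channels = 6,
                                rho_within = 0.9, seed = 1) {
  set.seed(seed)
  group <- rep(c("a", "b"), each = n_channels / 2)
  lapply(seq_len(n_windows), function(w) {
    base_a <- rnorm(18)
    base_b <- rnorm(18)
    vals <- sapply(seq_len(n_channels), function(ch) {
      base <- if (group[ch] == "a") base_a else base_b
      sqrt(rho_within) * base + sqrt(1 - rho_within) * rnorm(18)
    })
    feature_matrix(vals, paste0("ch", seq_len(n_channels)), "P01", "left")
  })
}
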