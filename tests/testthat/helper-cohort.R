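# Synthetic `cohort_features` objects built directly from random feature
# matrices (no EMD), for fast authenticator/evaluation tests. Subjects
# get a mean shift of size `shift` on a few feature rows, and each task
# a small task effect, so decoders can succeed when shift > 0.
make_fm_cohort <- function(n_subjects = 3, n_windows = 30, n_channels = 4,
                           shift = 2, seed = 1) {
  set.seed(seed)
  labs <- paste0("ch", seq_len(n_channels))
  subjects <- list()
  for (s in seq_len(n_subjects)) {
    id <- sprintf("S%03d", s)
    offset <- matrix(0, 18, n_channels)
    offset[c(1, 5, 9, 17), ] <- shift * rnorm(4)
    per_task <- list()
    for (task in c("left", "right")) {
      task_off <- offset + 0.3 * (task == "left")
      per_task[[task]] <- lapply(seq_len(n_windows), function(w) {
        feature_matrix(matrix(rnorm(18 * n_channels), 18, n_channels) +
                         task_off, labs, id, task)
      })
    }
    subjects[[id]] <- per_task
  }
  structure(list(subjects = subjects, preset = as.character(n_channels),
                 win_s = 2, overlap = 0.75),
            class = "cohort_features")
}

# Small auth config for fast end-to-end structure tests.
fast_config <- function(n = 30) {
  auth_config(beam_width = 2L, max_size = 2L, n_train_per_class = n)
}
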