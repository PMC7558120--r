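# Empirical mode decomposition with dB-parameterised stop criteria.
#
# The signal is sifted into intrinsic mode functions (IMFs), ordered from
# highest to lowest characteristic frequency, plus a residue:
#   signal = IMF1 + IMF2 + ... + IMFn + residue.
# Two dB thresholds control termination. Sifting of one candidate IMF
# stops when the energy of the candidate exceeds the energy of the mean
# of its upper/lower envelopes by `resolution_db` decibels
# (10*log10(E_candidate / E_mean_envelope) >= resolution_db), i.e. the
# local mean is negligible relative to the mode. The decomposition stops
# when the residue energy has dropped `residual_energy_db` decibels below
# the original signal energy, or the residue is monotone.

#' EMD configuration
#'
#' @param resolution_db sifting stop threshold in dB (default 40):
#'   a candidate IMF is accepted when its energy exceeds that of its
#'   envelope mean by this many dB.
#' @param residual_energy_db decomposition stop threshold in dB (default
#'   60): extraction stops when the residue energy is this many dB below
#'   the input energy.
#' @param max_imfs maximum number of IMFs to extract.
#' @param max_sift_iters safeguard on sifting iterations per IMF.
#' @return An object of class `emd_config`.
#' @export
emd_config <- function(resolution_db = 40, residual_energy_db = 60,
                       max_imfs = 12L, max_sift_iters = 200L) {
  stopifnot(resolution_db > 0, residual_energy_db > 0,
            max_imfs >= 1, max_sift_iters >= 1)
  structure(list(resolution_db = resolution_db,
                 residual_energy_db = residual_energy_db,
                 max_imfs = as.integer(max_imfs),
                 max_sift_iters = as.integer(max_sift_iters)),
            class = "emd_config")
}

#' Empirical mode decomposition
#'
#' Decomposes a single-channel signal into intrinsic mode functions and
#' a residue by cubic-spline sifting (natural splines through the
#' extrema, with the two outermost extrema mirrored beyond each end to
#' control edge swings on short windows). The sifting core is compiled;
#' see [emd_config()] for the dB stop criteria.
#'
#' @param x numeric vector, length >= 8, not constant.
#' @param cfg an [emd_config()].
#' @return An object of class `imf_set` with fields `imfs` (list of
#'   numeric vectors, highest frequency first) and `residue`.
#' @export
emd <- function(x, cfg = emd_config()) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8) stop("emd: signal too short (need >= 8 samples)", call. = FALSE)
  if (stats::sd(x) == 0) stop("emd: constant signal", call. = FALSE)
  res <- emd_cpp(x, cfg$resolution_db, cfg$residual_energy_db,
                 cfg$max_imfs, cfg$max_sift_iters)
  structure(list(imfs = res$imfs, residue = res$residue,
                 input_length = n),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMFs + residue (signal length %d)\n",
              length(x$imfs), x$input_length))
  invisible(x)
}

#' First k intrinsic mode functions
#'
#' Returns exactly `k` vectors, highest-frequency mode first. If the
#' decomposition produced fewer than `k` IMFs the remaining slots are
#' zero vectors (with a warning), so downstream feature shapes stay
#' fixed.
#'
#' @param set an `imf_set` from [emd()].
#' @param k number of modes (default 4, the modes carrying most of the
#'   information in 2 s motor-task windows).
#' @return A list of `k` numeric vectors.
#' @export
first_imfs <- function(set, k = 4L) {
  stopifnot(inherits(set, "imf_set"), k >= 1)
  k <- as.integer(k)
  n_have <- length(set$imfs)
  out <- set$imfs[seq_len(min(k, n_have))]
  if (n_have < k) {
    warning("first_imfs: only ", n_have, " IMFs available; padding ",
            k - n_have, " with zeros", call. = FALSE)
    for (i in seq_len(k - n_have)) {
      out[[n_have + i]] <- numeric(set$input_length)
    }
  }
  out
}
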