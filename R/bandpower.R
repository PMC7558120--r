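# Multitaper spectral estimation for the mu and beta band-power features.
#
# Discrete prolate spheroidal (Slepian) tapers are obtained from the
# standard symmetric tridiagonal eigenproblem (Gruenbacher & Hummels
# formulation), which is numerically stable for the short windows used
# here. The PSD is the average of the tapered periodograms; band power is
# the mean PSD over the frequency bins inside the band.

.taper_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' @param n taper length in samples.
#' @param nw time-bandwidth product (default 3).
#' @param k number of tapers (default `2 * nw - 1`).
#' @return An `n x k` matrix of orthonormal tapers, in decreasing order
#'   of spectral concentration.
#' @export
dpss_tapers <- function(n, nw = 3, k = 2 * nw - 1) {
  key <- paste(n, nw, k, sep = "_")
  hit <- .taper_cache[[key]]
  if (!is.null(hit)) return(hit)
  stopifnot(n >= 8, nw > 0, k >= 1, k < n)
  w <- nw / n
  i <- seq_len(n) - 1
  diag_main <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  off <- seq_len(n - 1) * (n - seq_len(n - 1)) / 2
  A <- diag(diag_main)
  A[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  A[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  eg <- eigen(A, symmetric = TRUE)
  v <- eg$vectors[, seq_len(k), drop = FALSE]
  # fix sign convention: each taper's mean (symmetric part) positive
  for (j in seq_len(k)) {
    s <- sum(v[, j])
    if (s == 0) s <- v[2, j] - v[1, j]
    if (s < 0) v[, j] <- -v[, j]
  }
  .taper_cache[[key]] <- v
  v
}

#' Multitaper power spectral density
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param nw time-bandwidth product (default 3).
#' @param k number of tapers (default `2 * nw - 1` = 5).
#' @return A list with `freq` (Hz, one-sided) and `psd` (power per Hz).
#' @export
multitaper_psd <- function(x, fs, nw = 3, k = 2 * nw - 1) {
  x <- as.numeric(x)
  n <- length(x)
  v <- dpss_tapers(n, nw, k)
  n_freq <- floor(n / 2) + 1L
  spec <- numeric(n_freq)
  for (j in seq_len(k)) {
    ft <- stats::fft(x * v[, j])[seq_len(n_freq)]
    spec <- spec + (Mod(ft)^2) / fs
  }
  spec <- spec / k
  # fold two-sided power into the one-sided spectrum (not DC / Nyquist)
  interior <- 2:(n_freq - if (n %% 2 == 0) 1L else 0L)
  spec[interior] <- 2 * spec[interior]
  list(freq = (seq_len(n_freq) - 1) * fs / n, psd = spec)
}

#' Average band power from the multitaper PSD
#'
#' Mean of the multitaper PSD over the frequency bins in `[lo, hi]`.
#' The mu (7.5-12.5 Hz) and beta (16-31 Hz) sensorimotor bands are the
#' two used as channel features.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param band numeric length-2, band edges `(lo, hi)` in Hz, `hi < fs/2`.
#' @param nw,k multitaper settings, see [multitaper_psd()].
#' @return Scalar mean PSD over the band.
#' @export
band_power <- function(x, fs, band, nw = 3, k = 2 * nw - 1) {
  stopifnot(length(band) == 2, band[1] < band[2])
  if (band[2] >= fs / 2) {
    stop("band_power: band upper edge must be below fs/2", call. = FALSE)
  }
  p <- multitaper_psd(x, fs, nw, k)
  sel <- p$freq >= band[1] & p$freq <= band[2]
  if (!any(sel)) {
    stop("band_power: no frequency bins inside the band at this resolution",
         call. = FALSE)
  }
  mean(p$psd[sel])
}

#' Default sensorimotor bands
#' @return Named list with `mu` (7.5-12.5 Hz) and `beta` (16-31 Hz).
#' @export
sensorimotor_bands <- function() {
  list(mu = c(7.5, 12.5), beta = c(16, 31))
}
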