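# Entropy measures computed per intrinsic mode function.
#
# Shannon and log-energy entropies follow the wavelet-toolbox convention:
# the "probability" of a sample is its normalised energy
# q_i = x_i^2 / sum(x^2). Approximate and sample entropy are the standard
# template-matching regularity statistics (Chebyshev distance, embedding
# length m, tolerance r as a fraction of the series standard deviation);
# approximate entropy includes self-matches, sample entropy does not.

#' Entropy parameters
#'
#' @param m embedding (template) length, default 2.
#' @param r_frac tolerance as a fraction of the series standard
#'   deviation, default 0.15.
#' @return An object of class `entropy_params`.
#' @export
entropy_params <- function(m = 2L, r_frac = 0.15) {
  stopifnot(m >= 1, r_frac > 0, r_frac < 1)
  structure(list(m = as.integer(m), r_frac = r_frac),
            class = "entropy_params")
}

#' Shannon entropy of normalised sample energies
#'
#' `S = -sum(q_i * log(q_i))` with `q_i = x_i^2 / sum(x^2)` and the
#' convention `0 * log(0) = 0`. Natural logarithm. Invariant to amplitude
#' scaling. An all-zero vector returns 0 with a warning.
#'
#' @param x numeric vector, length >= 2.
#' @return Non-negative scalar.
#' @export
shannon_entropy <- function(x) {
  x <- as.numeric(x)
  stopifnot(length(x) >= 2)
  e <- x^2
  tot <- sum(e)
  if (tot == 0) {
    warning("shannon_entropy: all-zero input; returning 0", call. = FALSE)
    return(0)
  }
  q <- e / tot
  q <- q[q > 0]
  -sum(q * log(q))
}

#' Log-energy entropy of normalised sample energies
#'
#' `L = sum(log(q_i))` over `q_i = x_i^2 / sum(x^2)`. Samples with zero
#' energy are skipped (their count is reported in a warning) since
#' `log(0)` is undefined. An all-zero vector is an error.
#'
#' @param x numeric vector, length >= 2.
#' @return Scalar (typically negative).
#' @export
log_energy <- function(x) {
  x <- as.numeric(x)
  stopifnot(length(x) >= 2)
  e <- x^2
  tot <- sum(e)
  if (tot == 0) stop("log_energy: all-zero input", call. = FALSE)
  q <- e / tot
  n_zero <- sum(q == 0)
  if (n_zero > 0) {
    warning("log_energy: skipped ", n_zero, " zero-energy sample(s)",
            call. = FALSE)
  }
  sum(log(q[q > 0]))
}

# Both template entropies from one pass of pairwise template matching.
template_entropies <- function(x, p) {
  n <- length(x)
  s <- stats::sd(x)
  if (s == 0) return(list(apen = 0, sampen = 0, capped = FALSE))
  cnt <- entropy_counts(x, p$m, p$r_frac * s)
  apen <- mean(log(cnt$cm / (n - p$m + 1))) -
    mean(log(cnt$cm1 / (n - p$m)))
  capped <- FALSE
  sampen <- if (cnt$A == cnt$B || cnt$B == 0) {
    0
  } else if (cnt$A == 0) {
    capped <- TRUE
    log(cnt$B * (n - p$m))
  } else {
    -log(cnt$A / cnt$B)
  }
  list(apen = apen, sampen = sampen, capped = capped)
}

#' Approximate entropy
#'
#' Standard ApEn(m, r, N): `phi_m - phi_{m+1}` where
#' `phi_m = mean_i log(C_i^m / (N - m + 1))` and `C_i^m` counts templates
#' within Chebyshev distance `r = r_frac * sd(x)` of template i,
#' including the self-match. A constant series returns 0 (every template
#' matches every other).
#'
#' @param x numeric vector, length > m + 1.
#' @param p an [entropy_params()].
#' @return Non-negative scalar.
#' @export
approx_entropy <- function(x, p = entropy_params()) {
  x <- as.numeric(x)
  stopifnot(length(x) > p$m + 1)
  template_entropies(x, p)$apen
}

#' Sample entropy
#'
#' Standard SampEn(m, r, N): `-log(A / B)` where `B` counts template
#' pairs (self-matches excluded) within tolerance at length m and `A`
#' the same pairs still within tolerance at length m + 1. Conventions
#' for degenerate counts: `A == B` (including the constant series)
#' returns 0; `B > 0` with `A == 0` returns the documented cap
#' `log(B * (N - m))` with a warning, keeping the feature finite.
#'
#' @inheritParams approx_entropy
#' @return Non-negative scalar.
#' @export
sample_entropy <- function(x, p = entropy_params()) {
  x <- as.numeric(x)
  stopifnot(length(x) > p$m + 1)
  te <- template_entropies(x, p)
  if (te$capped) {
    warning("sample_entropy: no template pair extends to length m + 1; ",
            "returning the cap log(B * (N - m))", call. = FALSE)
  }
  te$sampen
}
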