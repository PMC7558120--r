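# The 18-feature bank: four entropies of each of the first four IMFs
# plus multitaper mu and beta band powers of the (filtered) channel
# signal. Rows are fixed in this order:
#   shannon_imf1..4, logenergy_imf1..4, sampen_imf1..4, apen_imf1..4,
#   mu_power, beta_power.

feature_row_names <- function() {
  c(paste0("shannon_imf", 1:4),
    paste0("logenergy_imf", 1:4),
    paste0("sampen_imf", 1:4),
    paste0("apen_imf", 1:4),
    "mu_power", "beta_power")
}

#' Construct a feature matrix object
#'
#' @param values 18-by-C numeric matrix (18 features per channel).
#' @param channel_labels labels for the C columns.
#' @param subject_id,task provenance of the source window.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, channel_labels, subject_id = "unknown",
                           task = NA_character_) {
  values <- as.matrix(values)
  if (nrow(values) != 18L) {
    stop("feature_matrix: expected 18 feature rows, got ", nrow(values),
         call. = FALSE)
  }
  if (ncol(values) != length(channel_labels)) {
    stop("feature_matrix: ", ncol(values), " columns but ",
         length(channel_labels), " channel labels", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("feature_matrix: non-finite feature values", call. = FALSE)
  }
  rownames(values) <- feature_row_names()
  colnames(values) <- channel_labels
  structure(list(values = values, feature_names = feature_row_names(),
                 channel_labels = channel_labels,
                 subject_id = as.character(subject_id), task = task),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> subject=%s task=%s  18 x %d\n",
              x$subject_id, x$task, ncol(x$values)))
  invisible(x)
}

# Feature column for a single channel of a window.
channel_features <- function(x, fs, cfg, p, bands) {
  set <- emd(x, cfg)
  imfs <- first_imfs(set, 4L)
  sh <- vapply(imfs, shannon_entropy, 0)
  le <- vapply(imfs, function(v) {
    if (all(v == 0)) 0 else log_energy(v)
  }, 0)
  te <- lapply(imfs, template_entropies, p = p)
  se <- vapply(te, function(e) e$sampen, 0)
  ae <- vapply(te, function(e) e$apen, 0)
  mu <- band_power(x, fs, bands$mu)
  be <- band_power(x, fs, bands$beta)
  c(sh, le, se, ae, mu, be)
}

#' Build the 18 x C feature matrix of a trial window
#'
#' Per channel: empirical mode decomposition, Shannon / log-energy /
#' sample / approximate entropy of the first four IMFs (16 features),
#' plus mu- and beta-band multitaper power of the channel signal
#' (2 features).
#'
#' @param w a [trial_window()].
#' @param cfg an [emd_config()].
#' @param p an [entropy_params()].
#' @param bands band definition list as from [sensorimotor_bands()].
#' @return A [feature_matrix()] (18 rows, one column per channel).
#' @export
build_feature_matrix <- function(w, cfg = emd_config(),
                                 p = entropy_params(),
                                 bands = sensorimotor_bands()) {
  stopifnot(inherits(w, "trial_window"))
  nc <- nrow(w$data)
  vals <- matrix(NA_real_, 18L, nc)
  for (ch in seq_len(nc)) {
    vals[, ch] <- tryCatch(
      suppressWarnings(channel_features(w$data[ch, ], w$fs, cfg, p, bands)),
      error = function(e) {
        stop("build_feature_matrix: channel ", w$channel_labels[ch], ": ",
             conditionMessage(e), call. = FALSE)
      }
    )
  }
  feature_matrix(vals, w$channel_labels, w$subject_id, w$task)
}
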