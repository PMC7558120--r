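# Biometric evaluation: FAR / FRR / accuracy pooled over users and
# folds, ROC analysis, expanded imposter-pool bookkeeping, and paired
# statistical comparison of systems.

#' Confusion counts for one user and fold
#'
#' @param TP,FN correctly granted / incorrectly denied genuine attempts.
#' @param TN,FP correctly denied / incorrectly granted imposter attempts.
#' @param user_id,fold provenance.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(TP, FN, TN, FP, user_id = NA_character_,
                             fold = NA_integer_) {
  stopifnot(TP >= 0, FN >= 0, TN >= 0, FP >= 0)
  structure(list(TP = TP, FN = FN, TN = TN, FP = FP,
                 user_id = user_id, fold = fold),
            class = "confusion_counts")
}

sum_field <- function(counts, field) {
  sum(vapply(counts, function(cc) as.numeric(cc[[field]]), 0))
}

#' False rejection rate
#'
#' Pooled ratio over users and folds:
#' `FRR = sum(FN) / sum(TP + FN)`.
#'
#' @param counts list of [confusion_counts()].
#' @return Rate in `[0, 1]`.
#' @export
compute_frr <- function(counts) {
  if (inherits(counts, "confusion_counts")) counts <- list(counts)
  denom <- sum_field(counts, "TP") + sum_field(counts, "FN")
  if (denom == 0) stop("compute_frr: no genuine attempts", call. = FALSE)
  sum_field(counts, "FN") / denom
}

#' False acceptance rate
#'
#' Pooled ratio over users and folds:
#' `FAR = sum(FP) / sum(TN + FP)`.
#'
#' @param counts list of [confusion_counts()].
#' @return Rate in `[0, 1]`.
#' @export
compute_far <- function(counts) {
  if (inherits(counts, "confusion_counts")) counts <- list(counts)
  denom <- sum_field(counts, "TN") + sum_field(counts, "FP")
  if (denom == 0) stop("compute_far: no imposter attempts", call. = FALSE)
  sum_field(counts, "FP") / denom
}

#' Pooled accuracy
#'
#' `(sum(TP) + sum(TN)) / (all attempts)`; algebraically consistent with
#' the pooled FAR and FRR under the attempt-count weights.
#'
#' @param counts list of [confusion_counts()].
#' @return Rate in `[0, 1]`.
#' @export
compute_accuracy <- function(counts) {
  if (inherits(counts, "confusion_counts")) counts <- list(counts)
  tot <- sum_field(counts, "TP") + sum_field(counts, "FN") +
    sum_field(counts, "TN") + sum_field(counts, "FP")
  if (tot == 0) stop("compute_accuracy: no attempts", call. = FALSE)
  (sum_field(counts, "TP") + sum_field(counts, "TN")) / tot
}

#' Expanded imposter pool for one fold
#'
#' Every window of every other subject that was not used for training in
#' the fold is scored as an imposter attempt. Training uses the sampled
#' imposter windows outside the fold's test block; the test-block
#' imposters and all never-sampled windows form the pool. The user's own
#' windows are never part of it.
#'
#' @param others_counts named integer vector: other subject id -> number
#'   of windows.
#' @param imposter_src data frame (subject, window) of the sampled
#'   training imposters, as produced by [assemble_training()].
#' @param train_rows rows of `imposter_src` used for training in this
#'   fold.
#' @return Data frame (subject, window) of pool attempts.
#' @export
expand_imposter_pool <- function(others_counts, imposter_src, train_rows) {
  all_others <- do.call(rbind, lapply(names(others_counts), function(s) {
    data.frame(subject = s, window = seq_len(others_counts[[s]]),
               stringsAsFactors = FALSE)
  }))
  trained <- paste(imposter_src$subject[train_rows],
                   imposter_src$window[train_rows])
  keep <- !(paste(all_others$subject, all_others$window) %in% trained)
  out <- all_others[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps a threshold over the decision values; at each threshold the
#' true-positive rate (TPR = 1 - FRR) and false-acceptance rate (FAR)
#' are recorded. AUC by the trapezoidal rule. Invariant under strictly
#' monotone transforms of the scores.
#'
#' @param scores numeric decision values (larger = more genuine-like).
#' @param labels vector with two levels; `positive` marks genuine
#'   attempts.
#' @param positive label of the genuine class.
#' @return List with `far`, `tpr` (curve points from (0,0) to (1,1)),
#'   `thresholds` and `auc`.
#' @export
roc_curve <- function(scores, labels, positive = "genuine") {
  labels <- as.character(labels)
  is_pos <- labels == positive
  if (!any(is_pos) || all(is_pos)) {
    stop("roc_curve: both classes must be present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- is_pos[ord]
  # unique thresholds (ties move together)
  keep <- c(diff(s) != 0, TRUE)
  tp <- cumsum(p)[keep]
  fp <- cumsum(!p)[keep]
  tpr <- c(0, tp / sum(is_pos))
  far <- c(0, fp / sum(!is_pos))
  auc <- sum(diff(far) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(far = far, tpr = tpr,
       thresholds = c(Inf, s[keep]), auc = auc)
}

#' Paired Wilcoxon comparison of per-user FAR between two systems
#'
#' Two-sided Wilcoxon signed-rank test on the paired per-user FAR
#' vectors, Bonferroni-corrected for `n_comparisons` planned contrasts
#' (default 3, i.e. alpha = 0.05 / 3). Identical vectors give p = 1.
#'
#' @param far_a,far_b per-user FAR vectors of equal length, same user
#'   order.
#' @param n_comparisons number of planned comparisons.
#' @param alpha family-wise error rate before correction.
#' @return List with `p_value`, `significant`, `alpha_corrected`.
#' @export
compare_systems_far <- function(far_a, far_b, n_comparisons = 3L,
                                alpha = 0.05) {
  stopifnot(length(far_a) == length(far_b))
  d <- far_a - far_b
  if (all(d == 0)) {
    return(list(p_value = 1, significant = FALSE,
                alpha_corrected = alpha / n_comparisons))
  }
  p <- suppressWarnings(
    stats::wilcox.test(far_a, far_b, paired = TRUE, exact = FALSE)$p.value
  )
  list(p_value = p, significant = p < alpha / n_comparisons,
       alpha_corrected = alpha / n_comparisons)
}

#' Evaluate the gated authenticator over a whole cohort
#'
#' Runs [run_user_authentication()] for every subject and aggregates a
#' system report: pooled (over users and folds) FAR, FRR and accuracy of
#' the two-task gate against the expanded imposter pools, the mean
#' balanced test-fold accuracy of the per-task SVMs, per-user FARs, and
#' the ROC/AUC of the pooled gate scores.
#'
#' @param cohort a `cohort_features` object.
#' @param config an [auth_config()].
#' @param seed integer seed; per-user seeds are derived from it.
#' @return An object of class `system_report`.
#' @export
evaluate_cohort <- function(cohort, config = auth_config(), seed = 1L) {
  stopifnot(inherits(cohort, "cohort_features"))
  rng <- local_rng(seed)
  users <- names(cohort$subjects)
  results <- list()
  for (u in users) {
    results[[u]] <- run_user_authentication(u, cohort, config,
                                            seed = rng$derive_seed())
  }
  system_report(results, config, seed)
}

#' Build a system report from per-user authentication results
#'
#' @param results named list of `user_auth_result` objects.
#' @param config the [auth_config()] used.
#' @param seed the cohort-level seed.
#' @return An object of class `system_report`.
#' @export
system_report <- function(results, config = auth_config(), seed = NA) {
  users <- names(results)
  all_counts <- list()
  per_user <- data.frame(user = users, far = NA_real_, frr = NA_real_,
                         accuracy = NA_real_, stringsAsFactors = FALSE)
  scores <- numeric(0)
  labels <- character(0)
  cv_acc <- numeric(0)
  for (i in seq_along(users)) {
    res <- results[[users[i]]]
    ucounts <- lapply(res$gated, function(g)
      confusion_counts(g$TP, g$FN, g$TN, g$FP, res$user_id, g$fold))
    all_counts <- c(all_counts, ucounts)
    per_user$far[i] <- compute_far(ucounts)
    per_user$frr[i] <- compute_frr(ucounts)
    per_user$accuracy[i] <- compute_accuracy(ucounts)
    for (g in res$gated) {
      scores <- c(scores, g$scores)
      labels <- c(labels, g$labels)
    }
    for (task in c("left", "right")) {
      cv_acc <- c(cv_acc, vapply(res$tasks[[task]]$folds,
                                 function(f) f$cv_accuracy, 0))
    }
  }
  sel_sizes <- unlist(lapply(results, function(res)
    lapply(c("left", "right"), function(task)
      vapply(res$tasks[[task]]$folds, function(f) length(f$selected), 0L))))
  roc <- roc_curve(scores, labels)
  structure(list(
    far = compute_far(all_counts),
    frr = compute_frr(all_counts),
    accuracy = compute_accuracy(all_counts),
    cv_accuracy = mean(cv_acc),
    far_sd = stats::sd(per_user$far),
    frr_sd = stats::sd(per_user$frr),
    accuracy_sd = stats::sd(per_user$accuracy),
    auc = roc$auc,
    per_user = per_user,
    selected_sizes = sel_sizes,
    counts = all_counts,
    roc = roc[c("far", "tpr")],
    config = config, seed = seed,
    n_users = length(users)
  ), class = "system_report")
}

#' @export
print.system_report <- function(x, ...) {
  cat(sprintf("<system_report> %d users, reducer=%s, seed=%s\n",
              x$n_users, x$config$reduce, format(x$seed)))
  cat(sprintf("  accuracy %.4f (sd %.4f)   cv accuracy %.4f\n",
              x$accuracy, x$accuracy_sd, x$cv_accuracy))
  cat(sprintf("  FRR      %.4f (sd %.4f)\n", x$frr, x$frr_sd))
  cat(sprintf("  FAR      %.4f (sd %.4f)   AUC %.4f\n",
              x$far, x$far_sd, x$auc))
  invisible(x)
}

#' Plot ROC curves of one or more system reports
#'
#' TPR (= 1 - FRR) against FAR, with the FAR axis truncated (default at
#' 0.1) to emphasise the low-FAR region that matters for authentication.
#'
#' @param reports a `system_report` or named list of them.
#' @param far_max right edge of the FAR axis.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, NULL.
#' @export
plot_roc <- function(reports, far_max = 0.1, ...) {
  if (inherits(reports, "system_report")) reports <- list(system = reports)
  cols <- seq_along(reports)
  graphics::plot(NULL, xlim = c(0, far_max), ylim = c(0, 1),
                 xlab = "FAR", ylab = "TPR (1 - FRR)", ...)
  for (i in seq_along(reports)) {
    r <- reports[[i]]$roc
    graphics::lines(r$far, r$tpr, col = cols[i], lwd = 2)
  }
  graphics::legend("bottomright", legend = names(reports), col = cols,
                   lwd = 2, bty = "n")
  invisible(NULL)
}

#' Box plot of per-user FAR distributions
#'
#' @param reports a `system_report` or named list of them (one box per
#'   system).
#' @param ... passed to [graphics::boxplot()].
#' @return Invisibly, NULL.
#' @export
plot_far_distribution <- function(reports, ...) {
  if (inherits(reports, "system_report")) reports <- list(system = reports)
  fars <- lapply(reports, function(r) r$per_user$far)
  graphics::boxplot(fars, ylab = "per-user FAR", ...)
  invisible(NULL)
}

#' Serialise a system report to JSON
#'
#' Stable, byte-reproducible serialisation (full double precision) of
#' the aggregate rates, per-user table and ROC points; used by the
#' determinism checks and the command-line tools.
#'
#' @param report a `system_report`.
#' @param path optional output path; when NULL the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
report_to_json <- function(report, path = NULL) {
  payload <- list(
    accuracy = report$accuracy, accuracy_sd = report$accuracy_sd,
    cv_accuracy = report$cv_accuracy,
    frr = report$frr, frr_sd = report$frr_sd,
    far = report$far, far_sd = report$far_sd,
    auc = report$auc,
    per_user = report$per_user,
    roc = report$roc,
    n_users = report$n_users,
    reducer = report$config$reduce
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
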