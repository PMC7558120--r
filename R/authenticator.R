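# Per-user authentication decoders: balanced genuine/imposter training
# assemblies, leak-free min-max normalisation, RBF-SVM training with the
# median-distance kernel-scale heuristic, the two-task AND gate, and the
# sequential 5-fold cross-validation driver.

#' Authentication pipeline configuration
#'
#' @param reduce channel reducer, `"cluster"` or `"pca"`.
#' @param beam_width beam width of the forward selection (default 5).
#' @param max_size number of selected features (default 10).
#' @param n_train_per_class genuine and imposter windows per training
#'   assembly (default 105, i.e. 21 four-second trials cut into five
#'   2 s windows each).
#' @param outer_folds outer cross-validation folds (default 5,
#'   sequential contiguous blocks per class).
#' @param inner_folds inner folds of the selection scorer (default 5).
#' @param cost SVM box constraint (default 1).
#' @return A list of class `auth_config`.
#' @export
auth_config <- function(reduce = c("cluster", "pca"), beam_width = 5L,
                        max_size = 10L, n_train_per_class = 105L,
                        outer_folds = 5L, inner_folds = 5L, cost = 1) {
  reduce <- match.arg(reduce)
  structure(list(reduce = reduce, beam_width = as.integer(beam_width),
                 max_size = as.integer(max_size),
                 n_train_per_class = as.integer(n_train_per_class),
                 outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds), cost = cost),
            class = "auth_config")
}

#' Assemble a balanced training set for one user and task
#'
#' Takes the user's first `n_per_class` windows as the genuine class and
#' samples `n_per_class` imposter windows uniformly without replacement
#' from the pooled windows of all other subjects.
#'
#' @param user_fms list of the user's [feature_matrix()] windows for one
#'   task.
#' @param others_fms named list, other subject id -> list of
#'   [feature_matrix()] windows for the same task.
#' @param n_per_class windows per class (default 105).
#' @param seed integer seed for the imposter sample.
#' @return A list of class `training_assembly` with `user_fms`,
#'   `imposter_fms`, and `imposter_src` (data frame: subject, window).
#' @export
assemble_training <- function(user_fms, others_fms, n_per_class = 105L,
                              seed = 1L) {
  if (length(user_fms) < n_per_class) {
    stop("assemble_training: user has ", length(user_fms),
         " windows, need ", n_per_class, call. = FALSE)
  }
  if (length(others_fms) < 2) {
    stop("assemble_training: need windows from at least 2 other subjects, ",
         "got ", length(others_fms), call. = FALSE)
  }
  pool <- do.call(rbind, lapply(names(others_fms), function(s) {
    data.frame(subject = s, window = seq_along(others_fms[[s]]),
               stringsAsFactors = FALSE)
  }))
  if (nrow(pool) < n_per_class) {
    stop("assemble_training: imposter pool has ", nrow(pool),
         " windows, need ", n_per_class, call. = FALSE)
  }
  rng <- local_rng(seed)
  pick <- sort(rng$sample_int(nrow(pool), n_per_class))
  src <- pool[pick, , drop = FALSE]
  rownames(src) <- NULL
  imposter_fms <- lapply(seq_len(nrow(src)), function(i) {
    others_fms[[src$subject[i]]][[src$window[i]]]
  })
  structure(list(user_fms = user_fms[seq_len(n_per_class)],
                 imposter_fms = imposter_fms, imposter_src = src,
                 n_per_class = as.integer(n_per_class), seed = seed),
            class = "training_assembly")
}

#' Min-max normalisation fitted on training data
#'
#' Per feature, `x' = (x - min_train) / (max_train - min_train)`.
#' Training values land in `[0, 1]`; held-out values may fall outside and
#' are deliberately not clipped. A constant training feature maps to 0
#' (with a warning).
#'
#' @param train numeric matrix (rows = windows) the ranges are fitted on.
#' @param other optional matrix transformed with the training ranges.
#' @return List with `train`, `other` (or NULL) and `fit` (`min`, `max`).
#' @export
minmax_fit_apply <- function(train, other = NULL) {
  stopifnot(is.matrix(train), nrow(train) >= 1)
  mn <- apply(train, 2, min)
  mx <- apply(train, 2, max)
  span <- mx - mn
  if (any(span == 0)) {
    warning("minmax_fit_apply: ", sum(span == 0),
            " constant training feature(s) mapped to 0", call. = FALSE)
  }
  span[span == 0] <- 1
  norm <- function(m) sweep(sweep(m, 2, mn), 2, span, "/")
  list(train = norm(train),
       other = if (is.null(other)) NULL else norm(other),
       fit = list(min = mn, max = mx))
}

minmax_apply <- function(m, fit) {
  span <- fit$max - fit$min
  span[span == 0] <- 1
  sweep(sweep(m, 2, fit$min), 2, span, "/")
}

#' Train a per-user authentication SVM
#'
#' Fits the binary RBF-SVM on min-max-normalised, standardised, selected
#' features. The kernel scale is set by the median pairwise distance
#' heuristic on the training rows.
#'
#' @param x numeric matrix of reduced feature vectors (windows x 36).
#' @param y labels, coerced to a factor with levels
#'   `c("genuine", "imposter")`.
#' @param selected integer vector of selected feature columns.
#' @param user_id,task model provenance.
#' @param cost SVM box constraint.
#' @return An object of class `auth_model`.
#' @export
train_svm <- function(x, y, selected, user_id = "unknown",
                      task = NA_character_, cost = 1) {
  stopifnot(length(selected) >= 1)
  y <- factor(as.character(y), levels = c("genuine", "imposter"))
  if (anyNA(y)) {
    stop("train_svm: labels must be 'genuine' or 'imposter'", call. = FALSE)
  }
  if (nlevels(droplevels(y)) < 2) {
    stop("train_svm: both classes must be present", call. = FALSE)
  }
  mm <- minmax_fit_apply(x)
  xs <- mm$train[, selected, drop = FALSE]
  if (all(apply(xs, 2, stats::sd) == 0)) {
    warning("train_svm: degenerate (constant) selected features",
            call. = FALSE)
  }
  svm <- fit_rbf_svm(xs, y, cost)
  structure(list(user_id = as.character(user_id), task = task,
                 svm = svm, minmax = mm$fit, selected = selected,
                 cost = cost),
            class = "auth_model")
}

#' @export
print.auth_model <- function(x, ...) {
  cat(sprintf("<auth_model> user=%s task=%s  %d features, gamma=%.4g\n",
              x$user_id, x$task, length(x$selected), x$svm$gamma))
  invisible(x)
}

#' Decision values of an authentication model
#'
#' @param model an [train_svm()] `auth_model`.
#' @param x matrix (or single vector) of 36-element reduced features on
#'   the model's original scale.
#' @return Numeric decision values; positive means genuine.
#' @export
decision_values <- function(model, x) {
  stopifnot(inherits(model, "auth_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  xn <- minmax_apply(x, model$minmax)
  model$svm$predict(xn[, model$selected, drop = FALSE])
}

#' Two-task gated authentication
#'
#' Entry is granted only if the claimed user's decoders for both motor
#' tasks classify their respective trial as genuine (logical AND),
#' prioritising a low false-acceptance rate.
#'
#' @param model_left,model_right `auth_model`s of the same user for the
#'   left- and right-hand task.
#' @param trial_left,trial_right 36-element reduced feature vectors (or
#'   [reduced_vector()] objects) of the attempt.
#' @return `"granted"` or `"denied"`.
#' @export
authenticate <- function(model_left, model_right, trial_left, trial_right) {
  stopifnot(inherits(model_left, "auth_model"),
            inherits(model_right, "auth_model"))
  if (!identical(model_left$user_id, model_right$user_id)) {
    stop("authenticate: models belong to different users (",
         model_left$user_id, " vs ", model_right$user_id, ")",
         call. = FALSE)
  }
  v <- function(t) if (inherits(t, "reduced_vector")) t$values else t
  dl <- decision_values(model_left, v(trial_left))
  dr <- decision_values(model_right, v(trial_right))
  if (dl > 0 && dr > 0) "granted" else "denied"
}

# Sequential per-class fold blocks: windows of each class are divided,
# in order, into `k` contiguous blocks; fold j tests block j of both
# classes. No shuffling, mirroring a sequential 80/20 split and keeping
# overlapping windows of the same trial mostly within one fold.
sequential_fold_blocks <- function(n, k) {
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  lapply(seq_len(k), function(j) starts[j]:ends[j])
}

#' Cross-validate one user's decoder on one task
#'
#' Runs the full leak-free pipeline per fold: the reducer fit, min-max
#' normalisation, beam feature selection and SVM training all see only
#' the training 80%; the held-out 20% (a contiguous block of each class)
#' and the expanded imposter pool (every other-subject window never
#' sampled into this user's training assembly) provide the confusion
#' counts.
#'
#' @param user_fms the user's windows ([feature_matrix()] list) for the
#'   task.
#' @param others_fms named list of other subjects' window lists.
#' @param config an [auth_config()].
#' @param seed integer seed (imposter sampling and inner folds derive
#'   from it).
#' @return List of per-fold results; see [run_user_authentication()] for
#'   the gated aggregation.
#' @export
run_task_cv <- function(user_fms, others_fms, config = auth_config(),
                        seed = 1L) {
  rng <- local_rng(seed)
  assembly_seed <- rng$derive_seed()
  assembly <- assemble_training(user_fms, others_fms,
                                config$n_train_per_class, assembly_seed)
  n <- config$n_train_per_class
  blocks <- sequential_fold_blocks(n, config$outer_folds)
  src_key <- paste(assembly$imposter_src$subject,
                   assembly$imposter_src$window)

  # flat index of every other-subject window, for the expanded pool
  all_others <- do.call(rbind, lapply(names(others_fms), function(s) {
    data.frame(subject = s, window = seq_along(others_fms[[s]]),
               stringsAsFactors = FALSE)
  }))
  all_others_key <- paste(all_others$subject, all_others$window)
  others_flat <- unlist(lapply(others_fms, identity), recursive = FALSE)

  folds <- vector("list", config$outer_folds)
  for (j in seq_len(config$outer_folds)) {
    test_idx <- blocks[[j]]
    train_idx <- setdiff(seq_len(n), test_idx)
    train_fms <- c(assembly$user_fms[train_idx],
                   assembly$imposter_fms[train_idx])
    y_train <- factor(rep(c("genuine", "imposter"),
                          times = c(length(train_idx), length(train_idx))),
                      levels = c("genuine", "imposter"))

    reducer <- fit_reducer(train_fms, config$reduce)
    x_train <- reducer$transform(train_fms)
    sel_seed <- rng$derive_seed()
    mm <- minmax_fit_apply(x_train)
    sel <- forward_select(mm$train, y_train,
                          beam_width = config$beam_width,
                          max_size = config$max_size,
                          seed = sel_seed, cost = config$cost)
    model <- train_svm(x_train, y_train, sel$selected,
                       user_id = assembly$user_fms[[1]]$subject_id,
                       task = assembly$user_fms[[1]]$task,
                       cost = config$cost)

    dv_genuine <- decision_values(model,
                                  reducer$transform(assembly$user_fms[test_idx]))
    dv_imp_block <- decision_values(model,
                                    reducer$transform(assembly$imposter_fms[test_idx]))

    # expanded pool: every other-subject window not used for training in
    # this fold (i.e. not among the sampled imposters outside the test
    # block)
    trained_keys <- src_key[train_idx]
    avail <- !(all_others_key %in% trained_keys)
    dv_pool <- decision_values(model, reducer$transform(others_flat[avail]))

    tp <- sum(dv_genuine > 0)
    folds[[j]] <- list(
      fold = j,
      selected = sel$selected,
      selection_score = sel$score,
      TP = tp, FN = length(dv_genuine) - tp,
      FP = sum(dv_pool > 0), TN = sum(dv_pool <= 0),
      cv_accuracy = (sum(dv_genuine > 0) + sum(dv_imp_block <= 0)) /
        (length(dv_genuine) + length(dv_imp_block)),
      imposter_pool_size = sum(avail),
      dv_genuine = dv_genuine,
      pool_subject = all_others$subject[avail],
      pool_window = all_others$window[avail],
      dv_pool = dv_pool,
      test_user_idx = test_idx,
      train_user_idx = train_idx,
      train_imposter_keys = trained_keys,
      test_imposter_keys = src_key[test_idx]
    )
  }
  structure(list(folds = folds, assembly_src = assembly$imposter_src,
                 config = config, seed = seed),
            class = "task_cv")
}

#' Cross-validate one user's two-task gated authenticator
#'
#' Runs [run_task_cv()] independently for the left- and right-hand task
#' (independent feature selection per task) and combines them through
#' the AND gate. Gated genuine attempts pair the user's test windows of
#' the two tasks by position; gated imposter attempts pair, per subject,
#' the windows available (untrained) in both tasks for that fold. The
#' gate score of an attempt is the smaller of the two decision values.
#'
#' @param user_id subject identifier within `cohort`.
#' @param cohort a `cohort_features` object from
#'   [extract_cohort_features()].
#' @param config an [auth_config()].
#' @param seed integer seed.
#' @return A list of class `user_auth_result` with per-task CV results
#'   and per-fold gated confusion counts and scores.
#' @export
run_user_authentication <- function(user_id, cohort,
                                    config = auth_config(), seed = 1L) {
  stopifnot(inherits(cohort, "cohort_features"))
  subjects <- names(cohort$subjects)
  if (!user_id %in% subjects) {
    stop("run_user_authentication: unknown subject ", user_id,
         call. = FALSE)
  }
  rng <- local_rng(seed)
  task_res <- list()
  for (task in c("left", "right")) {
    user_fms <- cohort$subjects[[user_id]][[task]]
    others_fms <- lapply(setdiff(subjects, user_id),
                         function(s) cohort$subjects[[s]][[task]])
    names(others_fms) <- setdiff(subjects, user_id)
    task_res[[task]] <- run_task_cv(user_fms, others_fms, config,
                                    seed = rng$derive_seed())
  }

  gated <- vector("list", config$outer_folds)
  for (j in seq_len(config$outer_folds)) {
    fl <- task_res$left$folds[[j]]
    fr <- task_res$right$folds[[j]]
    # genuine attempts: user test windows paired by position
    n_gen <- min(length(fl$dv_genuine), length(fr$dv_genuine))
    gen_score <- pmin(fl$dv_genuine[seq_len(n_gen)],
                      fr$dv_genuine[seq_len(n_gen)])
    # imposter attempts: per-subject windows available in both tasks
    kl <- paste(fl$pool_subject, fl$pool_window)
    kr <- paste(fr$pool_subject, fr$pool_window)
    common <- intersect(kl, kr)
    imp_score <- pmin(fl$dv_pool[match(common, kl)],
                      fr$dv_pool[match(common, kr)])
    tp <- sum(gen_score > 0)
    gated[[j]] <- list(
      fold = j,
      TP = tp, FN = n_gen - tp,
      FP = sum(imp_score > 0), TN = sum(imp_score <= 0),
      scores = c(gen_score, imp_score),
      labels = c(rep("genuine", n_gen), rep("imposter", length(imp_score))),
      imposter_pool_size = length(imp_score)
    )
  }
  structure(list(user_id = user_id, tasks = task_res, gated = gated,
                 config = config, seed = seed),
            class = "user_auth_result")
}
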