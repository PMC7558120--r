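test_that("training assemblies are balanced, seeded and validated", {
  coh <- make_fm_cohort(n_subjects = 4, n_windows = 40)
  user <- coh$subjects$S001$left
  others <- lapply(coh$subjects[c("S002", "S003", "S004")],
                   function(s) s$left)
  asm <- assemble_training(user, others, n_per_class = 30, seed = 3)
  expect_length(asm$user_fms, 30)
  expect_length(asm$imposter_fms, 30)
  expect_gte(length(unique(asm$imposter_src$subject)), 2)
  asm2 <- assemble_training(user, others, n_per_class = 30, seed = 3)
  expect_identical(asm$imposter_src, asm2$imposter_src)
  asm3 <- assemble_training(user, others, n_per_class = 30, seed = 4)
  expect_false(identical(asm$imposter_src, asm3$imposter_src))

  expect_error(assemble_training(user[1:10], others, 30, 1), "10")
  expect_error(assemble_training(user, others["S002"], 30, 1),
               "2 other subjects")
})

test_that("min-max normalisation follows the leak-free contract", {
  train <- cbind(c(2, 3, 4), c(0, 5, 10))
  out <- minmax_fit_apply(train, other = cbind(3, 5))
  expect_equal(out$train[, 1], c(0, 0.5, 1))
  expect_equal(out$other[1, 1], 0.5)
  # held-out values beyond the training range are not clipped
  out2 <- minmax_fit_apply(train, other = cbind(5, 20))
  expect_equal(out2$other[1, 1], 1.5)
  expect_equal(out2$other[1, 2], 2)
  expect_warning(out3 <- minmax_fit_apply(cbind(rep(4, 3))), "constant")
  expect_true(all(out3$train == 0))
})

test_that("the RBF authenticator separates well-separated clouds and is deterministic", {
  set.seed(81)
  n <- 210
  x <- matrix(rnorm(n * 10), n, 10)
  y <- rep(c("genuine", "imposter"), each = n / 2)
  x[1:(n / 2), ] <- x[1:(n / 2), ] + 10
  m <- train_svm(x, y, selected = 1:10, user_id = "u", task = "left")
  dv <- decision_values(m, x)
  expect_equal(mean((dv > 0) == (y == "genuine")), 1)
  m2 <- train_svm(x, y, selected = 1:10, user_id = "u", task = "left")
  expect_identical(decision_values(m2, x), dv)
  expect_error(train_svm(x, rep("genuine", n), 1:10), "classes")
})

test_that("the two-task gate is a logical AND and checks model ownership", {
  set.seed(82)
  n <- 60
  x <- matrix(rnorm(n * 36), n, 36)
  y <- rep(c("genuine", "imposter"), each = n / 2)
  x[1:(n / 2), 1] <- x[1:(n / 2), 1] + 8
  ml <- train_svm(x, y, selected = 1:4, user_id = "u", task = "left")
  mr <- train_svm(x, y, selected = 1:4, user_id = "u", task = "right")
  genuine_trial <- x[1, ]
  imposter_trial <- x[n, ]
  expect_identical(authenticate(ml, mr, genuine_trial, genuine_trial),
                   "granted")
  expect_identical(authenticate(ml, mr, genuine_trial, imposter_trial),
                   "denied")
  expect_identical(authenticate(ml, mr, imposter_trial, imposter_trial),
                   "denied")
  mo <- train_svm(x, y, selected = 1:4, user_id = "other", task = "right")
  expect_error(authenticate(ml, mo, genuine_trial, genuine_trial),
               "different users")
})

test_that("sequential folds split each class into contiguous blocks", {
  blocks <- eegauth:::sequential_fold_blocks(105, 5)
  expect_equal(lengths(blocks), rep(21, 5))
  expect_equal(blocks[[1]], 1:21)
  expect_equal(blocks[[5]], 85:105)
  expect_equal(sort(unlist(blocks)), 1:105)
})

test_that("task-level cross-validation is leak-free and structurally sound", {
  coh <- make_fm_cohort(n_subjects = 4, n_windows = 40, shift = 3,
                        seed = 5)
  others <- lapply(coh$subjects[c("S002", "S003", "S004")],
                   function(s) s$left)
  res <- run_task_cv(coh$subjects$S001$left, others,
                     fast_config(30), seed = 11)
  expect_length(res$folds, 5)
  for (f in res$folds) {
    # index audit: no test window participates in any fit
    expect_length(intersect(f$test_user_idx, f$train_user_idx), 0)
    expect_length(intersect(f$test_imposter_keys, f$train_imposter_keys), 0)
    # pool excludes exactly the imposters trained on in this fold
    expect_equal(f$imposter_pool_size, 3 * 40 - length(f$train_imposter_keys))
    expect_equal(f$TP + f$FN, 6)
    expect_equal(f$TN + f$FP, f$imposter_pool_size)
    expect_lte(length(f$selected), 2)
  }
})

test_that("the gated evaluation aggregates both tasks deterministically", {
  coh <- make_fm_cohort(n_subjects = 3, n_windows = 35, shift = 3,
                        seed = 6)
  res <- run_user_authentication("S002", coh, fast_config(30), seed = 21)
  res2 <- run_user_authentication("S002", coh, fast_config(30), seed = 21)
  expect_identical(lapply(res$gated, function(g) g[c("TP","FN","TN","FP")]),
                   lapply(res2$gated, function(g) g[c("TP","FN","TN","FP")]))
  expect_identical(res$gated[[1]]$scores, res2$gated[[1]]$scores)

  # AND-gate FAR cannot exceed either per-task FAR
  gate_counts <- lapply(res$gated, function(g)
    confusion_counts(g$TP, g$FN, g$TN, g$FP))
  task_far <- vapply(c("left", "right"), function(task) {
    cc <- lapply(res$tasks[[task]]$folds, function(f)
      confusion_counts(f$TP, f$FN, f$TN, f$FP))
    compute_far(cc)
  }, 0)
  expect_lte(compute_far(gate_counts), min(task_far) + 1e-12)

  # separable synthetic cohort: strong end-to-end recovery
  cc_all <- unlist(lapply(c("left", "right"), function(task)
    lapply(res$tasks[[task]]$folds, function(f) f$cv_accuracy)))
  expect_gt(mean(unlist(cc_all)), 0.9)
})
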