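test_that("FRR and FAR are pooled ratios over users and folds", {
  expect_equal(compute_frr(list(confusion_counts(90, 10, 0, 0))), 0.10)
  expect_equal(compute_far(list(confusion_counts(0, 0, 98, 2))), 0.02)
  two <- list(confusion_counts(8, 2, 0, 0), confusion_counts(6, 4, 0, 0))
  expect_equal(compute_frr(two), 6 / 20)
  pooled <- list(confusion_counts(0, 0, 99, 1), confusion_counts(0, 0, 97, 3))
  expect_equal(compute_far(pooled), 4 / 200)
  zero <- list(confusion_counts(10, 0, 50, 0))
  expect_equal(compute_frr(zero), 0)
  expect_equal(compute_far(zero), 0)
  expect_error(compute_far(list(confusion_counts(5, 5, 0, 0))), "imposter")
  expect_error(compute_frr(list(confusion_counts(0, 0, 5, 5))), "genuine")
})

test_that("accuracy is algebraically consistent with FAR and FRR", {
  set.seed(91)
  for (i in 1:20) {
    counts <- lapply(1:6, function(j)
      confusion_counts(sample(0:30, 1), sample(0:30, 1),
                       sample(0:300, 1), sample(0:30, 1)))
    tp <- sum(sapply(counts, `[[`, "TP")); fn <- sum(sapply(counts, `[[`, "FN"))
    tn <- sum(sapply(counts, `[[`, "TN")); fp <- sum(sapply(counts, `[[`, "FP"))
    if (tp + fn == 0 || tn + fp == 0) next
    acc <- compute_accuracy(counts)
    frr <- compute_frr(counts)
    far <- compute_far(counts)
    n_gen <- tp + fn; n_imp <- tn + fp
    expect_equal(acc, ((1 - frr) * n_gen + (1 - far) * n_imp) /
                   (n_gen + n_imp))
  }
})

test_that("pooled FAR equals the attempt-weighted mean of per-fold FARs", {
  set.seed(92)
  counts <- lapply(1:8, function(j)
    confusion_counts(0, 0, sample(50:300, 1), sample(0:20, 1)))
  per_fold_far <- sapply(counts, function(cc) cc$FP / (cc$TN + cc$FP))
  weights <- sapply(counts, function(cc) cc$TN + cc$FP)
  expect_equal(compute_far(counts),
               sum(per_fold_far * weights) / sum(weights))
})

test_that("the expanded imposter pool bookkeeping is exact", {
  others_counts <- c(S002 = 20, S003 = 20, S004 = 15)
  src <- data.frame(subject = c(rep("S002", 6), rep("S003", 5),
                                rep("S004", 4)),
                    window = c(1:6, 3:7, 10:13),
                    stringsAsFactors = FALSE)
  pool <- expand_imposter_pool(others_counts, src, train_rows = 1:12)
  # 55 total windows minus 12 trained
  expect_equal(nrow(pool), 55 - 12)
  expect_false(any(paste(pool$subject, pool$window) %in%
                     paste(src$subject[1:12], src$window[1:12])))
  # rows 13:15 of src (test-block imposters) remain in the pool
  expect_true(all(paste(src$subject[13:15], src$window[13:15]) %in%
                    paste(pool$subject, pool$window)))
  expect_false(any(pool$subject == "S001"))
})

test_that("ROC analysis: perfect separation, chance level, and invariances", {
  roc <- roc_curve(c(3, 2, 1, -1, -2), c("genuine", "genuine", "genuine",
                                         "imposter", "imposter"))
  expect_equal(roc$auc, 1)
  expect_equal(roc$far[1], 0)
  expect_equal(roc$tpr[1], 0)
  expect_equal(utils::tail(roc$far, 1), 1)
  expect_equal(utils::tail(roc$tpr, 1), 1)

  set.seed(93)
  scores <- rnorm(2000)
  labels <- sample(rep(c("genuine", "imposter"), 1000))
  roc2 <- roc_curve(scores, labels)
  expect_lt(abs(roc2$auc - 0.5), 0.05)

  # monotone transform invariance
  roc3 <- roc_curve(exp(scores / 2), labels)
  expect_equal(roc3$auc, roc2$auc)
  expect_true(roc2$auc >= 0 && roc2$auc <= 1)

  expect_error(roc_curve(1:5, rep("genuine", 5)), "both classes")
})

test_that("ROC AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(94)
  scores <- c(rnorm(80, 1), rnorm(120, 0))
  labels <- c(rep("genuine", 80), rep("imposter", 120))
  ours <- roc_curve(scores, labels)$auc
  ref <- suppressMessages(
    as.numeric(pROC::auc(pROC::roc(response = labels, predictor = scores,
                                   levels = c("imposter", "genuine"),
                                   direction = "<")))
  )
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("paired Wilcoxon system comparison with Bonferroni correction", {
  far <- runif(105, 0.01, 0.1)
  same <- compare_systems_far(far, far)
  expect_equal(same$p_value, 1)
  expect_false(same$significant)
  shifted <- compare_systems_far(far, far + 0.05)
  expect_true(shifted$significant)
  expect_lt(shifted$p_value, 0.05 / 3)
  # n_comparisons = 1 reduces to the uncorrected test
  uncorr <- compare_systems_far(far, far + 0.05, n_comparisons = 1)
  expect_equal(uncorr$alpha_corrected, 0.05)
  expect_equal(uncorr$p_value, shifted$p_value)
})

test_that("plot utilities render without error", {
  set.seed(95)
  rep <- structure(list(
    roc = list(far = c(0, 0.05, 1), tpr = c(0, 0.9, 1)),
    per_user = data.frame(user = c("a", "b"), far = c(0.01, 0.03))
  ), class = "system_report")
  path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(path)
  expect_no_error(plot_roc(list(A = rep, B = rep)))
  expect_no_error(plot_far_distribution(list(A = rep, B = rep)))
  grDevices::dev.off()
  expect_true(file.exists(path))
})

test_that("system reports aggregate a synthetic cohort sensibly", {
  coh <- make_fm_cohort(n_subjects = 3, n_windows = 35, shift = 3,
                        seed = 7)
  rep <- evaluate_cohort(coh, fast_config(30), seed = 31)
  expect_s3_class(rep, "system_report")
  expect_equal(rep$n_users, 3)
  expect_true(all(c(rep$far, rep$frr, rep$accuracy) >= 0))
  expect_true(all(c(rep$far, rep$frr, rep$accuracy) <= 1))
  expect_equal(nrow(rep$per_user), 3)
  # identity between aggregate accuracy and the pooled counts
  expect_equal(rep$accuracy, compute_accuracy(rep$counts))
  js <- report_to_json(rep)
  expect_true(jsonlite::validate(js))
})
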