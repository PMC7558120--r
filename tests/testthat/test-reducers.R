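test_that("cross-correlation of identical channels is all ones with zero spread", {
  set.seed(61)
  stack <- lapply(1:5, function(i) {
    col <- rnorm(18)
    feature_matrix(cbind(col, col, col), c("a", "b", "c"), "x", "left")
  })
  xc <- channel_crosscorr(stack)
  expect_equal(xc$mean_xcorr, matrix(1, 3, 3, dimnames = dimnames(xc$mean_xcorr)))
  expect_equal(max(abs(xc$std_xcorr)), 0)
})

test_that("planted two-group structure appears as correlation blocks and is recovered", {
  for (seed in 1:20) {
    stack <- planted_group_stack(n_windows = 30, rho_within = 0.9,
                                 seed = seed)
    xc <- channel_crosscorr(stack)
    within <- c(xc$mean_xcorr[1:3, 1:3][upper.tri(diag(3))],
                xc$mean_xcorr[4:6, 4:6][upper.tri(diag(3))])
    across <- xc$mean_xcorr[1:3, 4:6]
    expect_gt(mean(within), mean(across))
    cl <- cluster_channels(xc$mean_xcorr)
    got <- sort(cl$cluster_a)
    expect_true(identical(got, c("ch1", "ch2", "ch3")) ||
                identical(sort(cl$cluster_b), c("ch1", "ch2", "ch3")))
  }
})

test_that("degenerate clustering inputs follow the documented tie-breaks", {
  flat <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  cl <- cluster_channels(flat)
  expect_identical(cl$cluster_a, "a")
  expect_identical(cl$cluster_b, c("b", "c", "d"))
  two <- matrix(c(1, .2, .2, 1), 2, dimnames = list(c("x", "y"), c("x", "y")))
  cl2 <- cluster_channels(two)
  expect_identical(cl2$cluster_a, "x")
  expect_identical(cl2$cluster_b, "y")
})

test_that("zero-variance channel profiles yield zero correlations with warning", {
  stack <- lapply(1:3, function(i) {
    set.seed(i)
    feature_matrix(cbind(rnorm(18), rep(1, 18)), c("a", "b"), "x", "left")
  })
  expect_warning(xc <- channel_crosscorr(stack), "zero-variance")
  expect_equal(xc$mean_xcorr["a", "b"], 0)
})

test_that("cluster reduction averages channels within clusters", {
  set.seed(62)
  vals <- matrix(rnorm(18 * 8), 18, 8)
  labs <- paste0("ch", 1:8)
  fm <- feature_matrix(vals, labs, "x", "left")
  cl <- structure(list(cluster_a = labs[c(1, 3, 5)],
                       cluster_b = labs[c(2, 4, 6, 7, 8)]),
                  class = "channel_clustering")
  rv <- reduce_by_clusters(fm, cl)
  expect_length(rv$values, 36)
  expect_equal(rv$values[1:18], rowMeans(vals[, c(1, 3, 5)]))
  expect_equal(rv$values[19:36], rowMeans(vals[, c(2, 4, 6, 7, 8)]))

  # C = 2 with singleton clusters: output is the two original columns
  fm2 <- feature_matrix(vals[, 1:2], labs[1:2], "x", "left")
  cl2 <- structure(list(cluster_a = "ch1", cluster_b = "ch2"),
                   class = "channel_clustering")
  rv2 <- reduce_by_clusters(fm2, cl2)
  expect_equal(rv2$values, c(vals[, 1], vals[, 2]))
})

test_that("cluster reduction is invariant to channel order within a cluster", {
  set.seed(63)
  vals <- matrix(rnorm(18 * 6), 18, 6)
  labs <- paste0("ch", 1:6)
  fm <- feature_matrix(vals, labs, "x", "left")
  cl <- structure(list(cluster_a = c("ch1", "ch2", "ch3"),
                       cluster_b = c("ch4", "ch5", "ch6")),
                  class = "channel_clustering")
  clp <- structure(list(cluster_a = c("ch3", "ch1", "ch2"),
                        cluster_b = c("ch6", "ch4", "ch5")),
                   class = "channel_clustering")
  expect_equal(reduce_by_clusters(fm, cl)$values,
               reduce_by_clusters(fm, clp)$values)
})

test_that("PCA reducer: rank-1 data, planted factors, reconstruction identity", {
  set.seed(64)
  # rank-1: single component explains everything
  load1 <- rnorm(6)
  # rank-1 per-feature training matrices: every window a multiple of load1
  stack1 <- lapply(1:20, function(i) {
    w <- rnorm(1)
    feature_matrix(matrix(rep(w * load1, each = 18), 18, 6),
                   paste0("ch", 1:6), "x", "left")
  })
  fit1 <- fit_pca_reducer(stack1)
  ev <- fit1$fits[[1]]$eigenvalues
  expect_gt(ev[1] / sum(ev), 0.999)

  # planted 2-factor structure: top-2 capture >= 95%
  f1 <- rnorm(6); f2 <- rnorm(6)
  stack2 <- lapply(1:40, function(i) {
    g1 <- rnorm(1); g2 <- rnorm(1)
    vals <- g1 * f1 + g2 * f2 + 0.01 * rnorm(6)
    feature_matrix(matrix(rep(vals, each = 18), 18, 6) +
                     matrix(rnorm(18 * 6, sd = 0.01), 18, 6),
                   paste0("ch", 1:6), "x", "left")
  })
  fit2 <- fit_pca_reducer(stack2)
  for (f in c(1, 9, 18)) {
    ev <- fit2$fits[[f]]$eigenvalues
    expect_gt(sum(ev[1:2]) / sum(ev), 0.95)
  }

  # reconstruction identity: mean squared residual = variance not in top-2
  set.seed(65)
  stack3 <- lapply(1:30, function(i) {
    feature_matrix(matrix(rnorm(18 * 5), 18, 5), paste0("ch", 1:5),
                   "x", "left")
  })
  fit3 <- fit_pca_reducer(stack3)
  f <- 7
  X <- t(sapply(stack3, function(fm) fm$values[f, ]))
  ctr <- fit3$fits[[f]]$center
  rot <- fit3$fits[[f]]$rotation
  Xc <- sweep(X, 2, ctr)
  resid <- Xc - (Xc %*% rot) %*% t(rot)
  ev <- fit3$fits[[f]]$eigenvalues
  expect_equal(sum(resid^2) / (nrow(X) - 1), sum(ev[-(1:2)]),
               tolerance = 1e-8)
})

test_that("PCA components are orthonormal with non-increasing eigenvalues", {
  set.seed(66)
  stack <- lapply(1:25, function(i) {
    feature_matrix(matrix(rnorm(18 * 6), 18, 6), paste0("ch", 1:6),
                   "x", "left")
  })
  fit <- fit_pca_reducer(stack)
  for (f in c(1, 5, 18)) {
    rot <- fit$fits[[f]]$rotation
    expect_equal(crossprod(rot), diag(2), tolerance = 1e-10)
    ev <- fit$fits[[f]]$eigenvalues
    expect_true(all(diff(ev) <= 1e-10))
  }
})

test_that("both reducers emit 36-element vectors for all channel counts", {
  set.seed(67)
  for (nc in c(8, 16, 64)) {
    labs <- paste0("ch", seq_len(nc))
    stack <- lapply(1:12, function(i) {
      feature_matrix(matrix(rnorm(18 * nc), 18, nc), labs, "x", "left")
    })
    for (method in c("cluster", "pca")) {
      red <- fit_reducer(stack, method)
      out <- red$transform(stack[1:3])
      expect_equal(dim(out), c(3, 36))
      expect_true(all(is.finite(out)))
    }
  }
})

test_that("PCA transform before fit is rejected", {
  fm <- feature_matrix(matrix(rnorm(18 * 4), 18, 4), paste0("ch", 1:4),
                       "x", "left")
  expect_error(reduce_by_pca(fm, list()), "fit_pca_reducer")
})
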