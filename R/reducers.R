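# Channel-dimension reducers: 18 x C feature matrix -> 36-element vector.
#
# Two interchangeable reducers are provided. The cluster reducer groups
# the channels into the two clusters visible in the between-channel
# cross-correlation of the feature profiles, averages the feature matrix
# within each cluster (18 x 2) and concatenates the two cluster columns
# into a 36-vector. The PCA reducer learns, for each of the 18 feature
# rows, the top-2 principal components of that feature across channels
# on the training windows and projects each window onto them (18 x 2 ->
# 36). Both fits are frozen on training data before transforming held-out
# windows.

#' Construct a reduced feature vector
#'
#' @param values numeric vector of length 36.
#' @param provenance `"cluster"` or `"pca"`.
#' @param feature_names 36 labels.
#' @return An object of class `reduced_vector`.
#' @export
reduced_vector <- function(values, provenance, feature_names = NULL) {
  values <- as.numeric(values)
  if (length(values) != 36L) {
    stop("reduced_vector: expected 36 values, got ", length(values),
         call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("reduced_vector: non-finite values", call. = FALSE)
  }
  provenance <- match.arg(provenance, c("cluster", "pca"))
  if (is.null(feature_names)) {
    feature_names <- paste0("f", seq_len(36))
  }
  structure(list(values = values, provenance = provenance,
                 feature_names = feature_names),
            class = "reduced_vector")
}

# Stack a list of feature matrices into a windows x (18*C) array and
# remember the shape.
stack_values <- function(stack) {
  stopifnot(length(stack) >= 1)
  labs <- stack[[1]]$channel_labels
  for (fm in stack) {
    if (!identical(fm$channel_labels, labs)) {
      stop("inconsistent channel sets across feature matrices",
           call. = FALSE)
    }
  }
  arr <- vapply(stack, function(fm) fm$values,
                matrix(0, 18L, length(labs)))
  list(arr = arr, labels = labs)   # 18 x C x n_windows
}

#' Mean and SD of between-channel cross-correlation of feature profiles
#'
#' For every pair of channels, the Pearson correlation of their
#' 18-feature profiles is computed within each window; the mean and
#' standard deviation of those per-window correlations across windows
#' give the two C x C summary matrices whose block structure reveals the
#' channel clusters.
#'
#' @param stack list of [feature_matrix()] objects with identical channel
#'   sets (>= 2 windows).
#' @return List with `mean_xcorr` and `std_xcorr` (C x C, symmetric;
#'   diagonals 1 and 0), and `channel_labels`.
#' @export
channel_crosscorr <- function(stack) {
  if (length(stack) < 2) {
    stop("channel_crosscorr: need at least 2 feature matrices",
         call. = FALSE)
  }
  sv <- stack_values(stack)
  C <- length(sv$labels)
  if (C == 1) {
    return(list(mean_xcorr = matrix(1, 1, 1), std_xcorr = matrix(0, 1, 1),
                channel_labels = sv$labels))
  }
  n_win <- dim(sv$arr)[3]
  acc <- array(0, c(C, C, n_win))
  zero_var <- FALSE
  for (w in seq_len(n_win)) {
    m <- sv$arr[, , w]             # 18 x C
    sds <- apply(m, 2, stats::sd)
    cc <- suppressWarnings(stats::cor(m))
    if (any(sds == 0)) {
      zero_var <- TRUE
      cc[sds == 0, ] <- 0
      cc[, sds == 0] <- 0
    }
    diag(cc) <- 1
    acc[, , w] <- cc
  }
  if (zero_var) {
    warning("channel_crosscorr: zero-variance channel profile(s); ",
            "their pair correlations set to 0", call. = FALSE)
  }
  mean_xc <- apply(acc, c(1, 2), mean)
  std_xc <- apply(acc, c(1, 2), stats::sd)
  diag(mean_xc) <- 1
  diag(std_xc) <- 0
  dimnames(mean_xc) <- dimnames(std_xc) <- list(sv$labels, sv$labels)
  list(mean_xcorr = mean_xc, std_xcorr = std_xc,
       channel_labels = sv$labels)
}

#' Two-way channel clustering from the mean cross-correlation
#'
#' Average-linkage hierarchical clustering on the distance
#' `1 - mean_xcorr`, cut at two clusters. Deterministic; when the
#' correlation structure is entirely flat the cut degenerates to
#' {first channel} vs the rest by the linkage tie-break on channel order.
#'
#' @param mean_xcorr symmetric C x C correlation matrix (C >= 2), with
#'   channel labels as dimnames.
#' @return An object of class `channel_clustering` with `cluster_a`,
#'   `cluster_b` (label vectors; `cluster_a` contains the first channel)
#'   and the input matrix.
#' @export
cluster_channels <- function(mean_xcorr) {
  C <- nrow(mean_xcorr)
  stopifnot(C >= 2)
  labs <- rownames(mean_xcorr)
  if (is.null(labs)) labs <- paste0("ch", seq_len(C))
  off <- (1 - mean_xcorr)[upper.tri(mean_xcorr)]
  if (C == 2) {
    membership <- c(1L, 2L)
  } else if (diff(range(off)) < 1e-12) {
    # perfectly flat structure: documented tie-break, first channel alone
    membership <- c(1L, rep(2L, C - 1L))
  } else {
    d <- stats::as.dist(1 - mean_xcorr)
    hc <- stats::hclust(d, method = "average")
    membership <- stats::cutree(hc, k = 2)
  }
  # canonical orientation: cluster containing the first channel is A
  a_id <- membership[1]
  cluster_a <- labs[membership == a_id]
  cluster_b <- labs[membership != a_id]
  if (length(cluster_b) == 0) {
    # flat structure: documented tie-break, first channel alone
    cluster_a <- labs[1]
    cluster_b <- labs[-1]
  }
  structure(list(cluster_a = cluster_a, cluster_b = cluster_b,
                 mean_xcorr = mean_xcorr),
            class = "channel_clustering")
}

#' @export
print.channel_clustering <- function(x, ...) {
  cat("<channel_clustering>\n  A:", paste(x$cluster_a, collapse = " "),
      "\n  B:", paste(x$cluster_b, collapse = " "), "\n")
  invisible(x)
}

#' Fit the cluster reducer on training windows
#'
#' Convenience wrapper: cross-correlation summary followed by the 2-way
#' clustering.
#'
#' @param stack list of training [feature_matrix()] objects.
#' @return A `channel_clustering`.
#' @export
fit_cluster_reducer <- function(stack) {
  xc <- channel_crosscorr(stack)
  cl <- cluster_channels(xc$mean_xcorr)
  cl$std_xcorr <- xc$std_xcorr
  cl
}

#' Reduce a feature matrix by channel clusters
#'
#' Averages each feature row over the channels of each cluster (18 x 2)
#' and concatenates the two cluster columns (cluster A first) into the
#' 36-element SVM input.
#'
#' @param fm a [feature_matrix()].
#' @param clustering a `channel_clustering` covering `fm`'s channels.
#' @return A [reduced_vector()] with provenance `"cluster"`.
#' @export
reduce_by_clusters <- function(fm, clustering) {
  stopifnot(inherits(fm, "feature_matrix"),
            inherits(clustering, "channel_clustering"))
  ia <- match(clustering$cluster_a, fm$channel_labels)
  ib <- match(clustering$cluster_b, fm$channel_labels)
  if (anyNA(ia) || anyNA(ib)) {
    stop("reduce_by_clusters: clustering refers to channels absent from ",
         "the feature matrix", call. = FALSE)
  }
  if (length(ia) == 0 || length(ib) == 0) {
    stop("reduce_by_clusters: empty cluster", call. = FALSE)
  }
  a <- rowMeans(fm$values[, ia, drop = FALSE])
  b <- rowMeans(fm$values[, ib, drop = FALSE])
  reduced_vector(c(a, b), "cluster",
                 c(paste0(fm$feature_names, ".A"),
                   paste0(fm$feature_names, ".B")))
}

#' Fit the PCA reducer on training windows
#'
#' For each of the 18 feature rows, fits a PCA on the training matrix
#' [windows x C] of that feature's channel values and keeps the top-2
#' components. The fit (per-feature channel means and loadings) is frozen
#' before any held-out window is transformed.
#'
#' @param stack list of training [feature_matrix()] objects (>= 3).
#' @return An object of class `pca_reducer`.
#' @export
fit_pca_reducer <- function(stack) {
  if (length(stack) < 3) {
    stop("fit_pca_reducer: need at least 3 training windows", call. = FALSE)
  }
  sv <- stack_values(stack)
  C <- length(sv$labels)
  fits <- vector("list", 18L)
  for (f in seq_len(18L)) {
    X <- t(sv$arr[f, , , drop = TRUE])          # windows x C
    if (C == 1) X <- matrix(sv$arr[f, 1, ], ncol = 1)
    ctr <- colMeans(X)
    Xc <- sweep(X, 2, ctr)
    sv_d <- svd(Xc, nu = 0, nv = min(2L, C))
    rot <- sv_d$v
    if (ncol(rot) < 2) rot <- cbind(rot, 0)     # rank-deficient guard
    # deterministic sign: largest-magnitude loading positive
    for (j in 1:2) {
      pk <- which.max(abs(rot[, j]))
      if (rot[pk, j] < 0) rot[, j] <- -rot[, j]
    }
    ev <- (sv_d$d^2) / max(1, nrow(X) - 1)
    fits[[f]] <- list(center = ctr, rotation = rot,
                      eigenvalues = ev)
  }
  structure(list(fits = fits, channel_labels = sv$labels),
            class = "pca_reducer")
}

#' Reduce a feature matrix with a fitted PCA reducer
#'
#' Projects each feature row's channel values onto the two components
#' learned by [fit_pca_reducer()]; the 18 x 2 scores are concatenated
#' (all first components, then all second components) into the
#' 36-element SVM input.
#'
#' @param fm a [feature_matrix()].
#' @param fit a `pca_reducer`.
#' @return A [reduced_vector()] with provenance `"pca"`.
#' @export
reduce_by_pca <- function(fm, fit) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!inherits(fit, "pca_reducer")) {
    stop("reduce_by_pca: reducer must be fitted with fit_pca_reducer() ",
         "before transforming windows", call. = FALSE)
  }
  idx <- match(fit$channel_labels, fm$channel_labels)
  if (anyNA(idx)) {
    stop("reduce_by_pca: feature matrix lacks fitted channels",
         call. = FALSE)
  }
  scores <- matrix(0, 18L, 2L)
  for (f in seq_len(18L)) {
    x <- fm$values[f, idx] - fit$fits[[f]]$center
    scores[f, ] <- as.numeric(x %*% fit$fits[[f]]$rotation)
  }
  reduced_vector(c(scores[, 1], scores[, 2]), "pca",
                 c(paste0(fm$feature_names, ".PC1"),
                   paste0(fm$feature_names, ".PC2")))
}

#' Fit a reducer and transform feature matrices
#'
#' Dispatcher used by the cross-validation driver: fits the requested
#' reducer on the training stack only, then maps any stack of feature
#' matrices to a windows x 36 numeric matrix.
#'
#' @param train_stack list of training [feature_matrix()] objects.
#' @param method `"cluster"` or `"pca"`.
#' @return A list with `fit` and `transform(stack) -> matrix`.
#' @export
fit_reducer <- function(train_stack, method = c("cluster", "pca")) {
  method <- match.arg(method)
  fit <- switch(method,
    cluster = fit_cluster_reducer(train_stack),
    pca = fit_pca_reducer(train_stack)
  )
  transform <- function(stack) {
    rows <- lapply(stack, function(fm) {
      switch(method,
        cluster = reduce_by_clusters(fm, fit),
        pca = reduce_by_pca(fm, fit)
      )$values
    })
    do.call(rbind, rows)
  }
  list(method = method, fit = fit, transform = transform)
}
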