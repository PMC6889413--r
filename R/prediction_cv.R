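#' Cross-validation configuration
#'
#' Ten-times-repeated stratified 10-fold cross-validation with nested
#' 5-fold selection of the retained-feature count, mirroring the
#' evaluation protocol for single-subject outcome prediction.
#'
#' @param n_repeats Outer CV repeats (default 10).
#' @param n_outer_folds Outer folds (default 10).
#' @param n_inner_folds Inner folds for tuning k (default 5).
#' @param feature_grid Candidate numbers of retained voxels (capped at the
#'   available feature count at run time).
#' @param positive_class Label treated as the positive class (default
#'   `"responder"`).
#' @param gpc A [gpc_config()].
#' @param seed Integer seed; the full result is a pure function of
#'   (X, y, seed).
#' @return `cv_config` object.
#' @export
cv_config <- function(n_repeats = 10L, n_outer_folds = 10L,
                      n_inner_folds = 5L,
                      feature_grid = c(100L, 250L, 500L, 1000L, 2000L),
                      positive_class = "responder",
                      gpc = gpc_config(), seed = 1L) {
  stopifnot(n_repeats >= 1, n_outer_folds >= 2, n_inner_folds >= 2,
            length(feature_grid) >= 1, all(feature_grid >= 1))
  structure(list(n_repeats = as.integer(n_repeats),
                 n_outer_folds = as.integer(n_outer_folds),
                 n_inner_folds = as.integer(n_inner_folds),
                 feature_grid = sort(unique(as.integer(feature_grid))),
                 positive_class = positive_class,
                 gpc = gpc, seed = as.integer(seed)),
            class = "cv_config")
}

# y: +1/-1 vector. Stratified folds: shuffle within class, deal round-robin.
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Univariate feature ranking
#'
#' Indices of the `k` features with the largest absolute two-sample
#' (pooled) t statistics computed on training data only; ties broken by
#' lower index. Zero-variance features get t = 0 and are never preferred
#' over informative ones.
#'
#' @param X_train n x p training matrix.
#' @param y_train Labels in `{-1, +1}`.
#' @param k Number of features to keep (`k <= p`).
#' @return Integer vector of column indices, in rank order.
#' @export
select_features <- function(X_train, y_train, k) {
  p <- ncol(X_train)
  if (k > p) stop("k (", k, ") exceeds the feature count (", p, ")")
  i1 <- y_train > 0
  n1 <- sum(i1); n2 <- sum(!i1)
  if (n1 < 2 || n2 < 2) stop("need at least 2 subjects per class")
  m1 <- colMeans(X_train[i1, , drop = FALSE])
  m2 <- colMeans(X_train[!i1, , drop = FALSE])
  v1 <- colSums(sweep(X_train[i1, , drop = FALSE], 2, m1)^2)
  v2 <- colSums(sweep(X_train[!i1, , drop = FALSE], 2, m2)^2)
  sp <- sqrt((v1 + v2) / (n1 + n2 - 2) * (1 / n1 + 1 / n2))
  tv <- ifelse(sp > 0, (m1 - m2) / sp, 0)
  order(-abs(tv), seq_along(tv))[seq_len(k)]
}

#' Tune the retained-feature count by inner cross-validation
#'
#' Stratified inner k-fold CV over `config$feature_grid` (capped at the
#' available features): features are re-selected on every inner training
#' fold, a GPC is fitted, and the k with the highest mean inner balanced
#' accuracy wins; ties go to the smallest k.
#'
#' @param X_train,y_train Training data (labels `{-1, +1}`).
#' @param config A [cv_config()].
#' @param seed Seed for the inner fold split.
#' @return The selected k (integer).
#' @export
tune_k <- function(X_train, y_train, config, seed = config$seed) {
  grid <- config$feature_grid[config$feature_grid <= ncol(X_train)]
  if (length(grid) == 0) grid <- ncol(X_train)
  if (length(grid) == 1) return(as.integer(grid))
  k_in <- min(config$n_inner_folds, min(table(y_train)))
  if (k_in < 2)
    stop("cannot stratify inner folds: a class has fewer than 2 members")
  fold <- stratified_folds(y_train, k_in, seed)
  acc <- matrix(NA_real_, nrow = k_in, ncol = length(grid))
  for (f in seq_len(k_in)) {
    tr <- fold != f
    if (length(unique(y_train[tr])) < 2 || length(unique(y_train[!tr])) < 2)
      stop("inner fold lost a class despite stratification")
    for (gi in seq_along(grid)) {
      sel <- select_features(X_train[tr, , drop = FALSE], y_train[tr], grid[gi])
      m <- fit_gpc(X_train[tr, sel, drop = FALSE], y_train[tr], config$gpc)
      pr <- predict_proba(m, X_train[!tr, sel, drop = FALSE])
      acc[f, gi] <- fold_metrics(y_train[!tr], pr)["balanced_accuracy"]
    }
  }
  mean_acc <- colMeans(acc)
  as.integer(grid[which.max(mean_acc)])   # which.max takes the first = smallest k
}

# Metrics for one fold. y in {-1,+1} (+1 = positive class), prob = P(+1).
fold_metrics <- function(y, prob, threshold = 0.5) {
  pred <- ifelse(prob > threshold, 1, -1)
  tp <- sum(pred == 1 & y == 1);  fn <- sum(pred == -1 & y == 1)
  tn <- sum(pred == -1 & y == -1); fp <- sum(pred == 1 & y == -1)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  bacc <- mean(c(sens, spec))
  auc <- auc_rank(y, prob)
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  c(balanced_accuracy = bacc, sensitivity = sens, specificity = spec,
    auc = auc, ppv = ppv, npv = npv)
}

# Exact Mann-Whitney AUC (ties counted half).
auc_rank <- function(y, prob) {
  n1 <- sum(y == 1); n0 <- sum(y == -1)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(prob)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Repeated nested cross-validation of the GPC pipeline
#'
#' For each repeat: a fresh stratified outer split; per outer fold the
#' retained-feature count is tuned by inner CV on the training fold only,
#' features are selected and the GPC fitted on the training fold, and the
#' held-out fold is predicted. Standardization and feature selection never
#' see test rows (the fitting API only receives training data).
#'
#' @param X n x p feature matrix (e.g. one network's stage-2 maps).
#' @param y Labels: a factor/character with `config$positive_class` as the
#'   positive class, or `{-1, +1}` numeric.
#' @param config A [cv_config()].
#' @return A `cv_result`: `metrics` (one row per repeat x fold),
#'   `summary` (mean and SD per metric over all folds; per-fold NAs from
#'   empty denominators are excluded from that metric's mean), `oof_prob`
#'   (subjects x repeats out-of-fold probabilities), `selection_counts`
#'   (per-feature counts over all outer training folds), `tuned_k`,
#'   `total_runs`, `config`.
#' @export
run_repeated_cv <- function(X, y, config = cv_config()) {
  X <- as.matrix(X)
  yy <- encode_labels(y, config$positive_class)
  n <- length(yy)
  if (min(table(yy)) < 2) stop("need at least 2 subjects per class")
  k_out <- min(config$n_outer_folds, min(table(yy)))
  metrics <- NULL
  oof <- matrix(NA_real_, nrow = n, ncol = config$n_repeats)
  sel_counts <- integer(ncol(X))
  tuned <- integer(0)
  for (r in seq_len(config$n_repeats)) {
    fold <- stratified_folds(yy, k_out, derive_seed(config$seed, 20L, r))
    for (f in seq_len(k_out)) {
      tr <- fold != f
      Xtr <- X[tr, , drop = FALSE]
      ytr <- yy[tr]
      k <- tune_k(Xtr, ytr, config,
                  seed = derive_seed(config$seed, 21L, r * 1000L + f))
      sel <- select_features(Xtr, ytr, k)
      m <- fit_gpc(Xtr[, sel, drop = FALSE], ytr, config$gpc)
      pr <- predict_proba(m, X[!tr, sel, drop = FALSE])
      oof[!tr, r] <- pr
      sel_counts[sel] <- sel_counts[sel] + 1L
      tuned <- c(tuned, k)
      metrics <- rbind(metrics,
                       c(repeat_ = r, fold = f, k = k,
                         fold_metrics(yy[!tr], pr)))
    }
  }
  metrics <- as.data.frame(metrics)
  mcols <- c("balanced_accuracy", "sensitivity", "specificity",
             "auc", "ppv", "npv")
  summ <- data.frame(
    metric = mcols,
    mean = vapply(mcols, function(m) mean(metrics[[m]], na.rm = TRUE),
                  numeric(1)),
    sd = vapply(mcols, function(m) sd(metrics[[m]], na.rm = TRUE),
                numeric(1)),
    n_missing = vapply(mcols, function(m) sum(is.na(metrics[[m]])),
                       numeric(1)),
    row.names = NULL)
  structure(list(metrics = metrics, summary = summ, oof_prob = oof,
                 selection_counts = sel_counts, tuned_k = tuned,
                 total_runs = config$n_repeats * k_out,
                 n_outer_folds_used = k_out,
                 y = yy, config = config),
            class = "cv_result")
}

encode_labels <- function(y, positive_class) {
  if (is.numeric(y)) {
    if (!all(y %in% c(-1, 1))) stop("numeric y must be coded -1/+1")
    return(y)
  }
  y <- as.character(y)
  ifelse(y == positive_class, 1, -1)
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cv_result:", x$config$n_repeats, "repeats x", x$n_outer_folds_used,
      "folds\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Label-permutation significance of the cross-validated accuracy
#'
#' The observed statistic is the mean balanced accuracy from
#' [run_repeated_cv()]. Each permutation reruns the entire nested pipeline
#' on shuffled labels; `p = (1 + #(null >= observed)) / (1 + n_perm)`,
#' Bonferroni-corrected by `n_tests` (one test per network plus one for
#' gray matter). Permutation reruns use `perm_repeats` CV repeats
#' (default 1) to keep large permutation counts tractable; set it to
#' `config$n_repeats` for full fidelity.
#'
#' @inheritParams run_repeated_cv
#' @param n_perm Number of label permutations (>= 99).
#' @param n_tests Bonferroni multiplier (>= 1).
#' @param perm_repeats CV repeats per permutation (default 1).
#' @return `permutation_outcome`: observed statistic, null vector, raw and
#'   corrected p, seed.
#' @export
permutation_pvalue <- function(X, y, config = cv_config(), n_perm = 1000L,
                               n_tests = 49L, perm_repeats = 1L) {
  if (n_perm < 99) stop("n_perm must be >= 99")
  if (n_tests < 1) stop("n_tests must be >= 1")
  yy <- encode_labels(y, config$positive_class)
  obs <- run_repeated_cv(X, yy, config)
  observed <- obs$summary$mean[obs$summary$metric == "balanced_accuracy"]
  null <- numeric(n_perm)
  pcfg <- config
  pcfg$n_repeats <- as.integer(perm_repeats)
  for (j in seq_len(n_perm)) {
    set.seed(derive_seed(config$seed, 30L, j))
    yp <- sample(yy)
    pcfg$seed <- derive_seed(config$seed, 31L, j)
    res <- run_repeated_cv(X, yp, pcfg)
    null[j] <- res$summary$mean[res$summary$metric == "balanced_accuracy"]
  }
  p_raw <- (1 + sum(null >= observed)) / (1 + n_perm)
  structure(list(observed = observed, null = null, p_raw = p_raw,
                 p_corrected = min(1, p_raw * n_tests),
                 n_perm = n_perm, n_tests = n_tests,
                 seed = config$seed, cv = obs),
            class = "permutation_outcome")
}

#' @export
print.permutation_outcome <- function(x, ...) {
  cat(sprintf(
    "permutation_outcome: observed balanced accuracy %.3f, p = %.4g (raw), %.4g (Bonferroni x %d)\n",
    x$observed, x$p_raw, x$p_corrected, x$n_tests))
  invisible(x)
}

#' Clusters of consistently selected voxels
#'
#' Binarizes the per-voxel selection frequency at `threshold`, labels
#' 26-connected components, and tabulates them: voxel count, peak
#' frequency, peak-voxel coordinates (0-based voxel indices and world mm
#' via the affine), sorted by size descending.
#'
#' @param selection_counts Per-voxel counts from [run_repeated_cv()].
#' @param total_runs Total number of outer training folds.
#' @param mask Logical 3D array matching the feature columns.
#' @param threshold Frequency cutoff (default 0.5, i.e. "> 50% of runs").
#' @param affine Optional 4x4 voxel-to-world transform.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return data.frame with one row per cluster (possibly 0 rows).
#' @export
selection_clusters <- function(selection_counts, total_runs, mask,
                               threshold = 0.5, affine = NULL,
                               connectivity = 26L) {
  freq <- selection_counts / total_runs
  supra <- freq > threshold
  empty <- data.frame(cluster = integer(0), n_voxels = integer(0),
                      peak_frequency = numeric(0),
                      peak_x = integer(0), peak_y = integer(0),
                      peak_z = integer(0),
                      peak_mm_x = numeric(0), peak_mm_y = numeric(0),
                      peak_mm_z = numeric(0))
  if (!any(supra)) return(empty)
  bin <- unflatten(as.numeric(supra), mask) > 0
  labs <- label_components_cpp(as.vector(bin), dim(mask), connectivity)
  labs_in <- labs[as.vector(mask)]
  freq_full <- unflatten(freq, mask)
  rows <- lapply(sort(unique(labs_in[labs_in > 0])), function(l) {
    vox <- which(labs == l)
    pk <- vox[which.max(freq_full[vox])]
    ijk <- arrayInd(pk, dim(mask)) - 1L       # 0-based voxel coordinates
    mm <- if (is.null(affine)) rep(NA_real_, 3) else
      drop(affine %*% c(ijk, 1))[1:3]
    data.frame(cluster = l, n_voxels = length(vox),
               peak_frequency = max(freq_full[vox]),
               peak_x = ijk[1], peak_y = ijk[2], peak_z = ijk[3],
               peak_mm_x = mm[1], peak_mm_y = mm[2], peak_mm_z = mm[3])
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_voxels, -out$peak_frequency), ]
  out$cluster <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Reject-option accuracy curve
#'
#' For each uncertainty width `u` (total width of the rejection region
#' around 0.5, so `u = 0.10` rejects probabilities in 45-55%), excludes
#' the subjects whose out-of-fold probability falls inside
#' `(0.5 - u/2, 0.5 + u/2)` and recomputes balanced accuracy on the
#' remainder, per repeat; reports mean and SD across repeats plus the mean
#' number excluded. A (repeat, u) cell where a class vanishes after
#' exclusion is recorded as missing.
#'
#' @param oof_probabilities subjects x repeats matrix from
#'   [run_repeated_cv()].
#' @param y Labels (`{-1, +1}` or factor/character with positive class
#'   `"responder"`).
#' @param u_grid Uncertainty widths (default 0 to 0.8 by 0.1).
#' @param positive_class Positive label for non-numeric `y`.
#' @return `reject_curve` data.frame: `u`, `mean_excluded`,
#'   `balanced_accuracy`, `sd`, `n_missing_repeats`.
#' @export
reject_curve <- function(oof_probabilities, y,
                         u_grid = seq(0, 0.8, by = 0.1),
                         positive_class = "responder") {
  yy <- encode_labels(y, positive_class)
  P <- as.matrix(oof_probabilities)
  stopifnot(nrow(P) == length(yy))
  rows <- lapply(u_grid, function(u) {
    lo <- 0.5 - u / 2
    hi <- 0.5 + u / 2
    accs <- numeric(0)
    excl <- numeric(0)
    miss <- 0L
    for (r in seq_len(ncol(P))) {
      keep <- !(P[, r] > lo & P[, r] < hi)
      excl <- c(excl, sum(!keep))
      if (length(unique(yy[keep])) < 2) {
        miss <- miss + 1L
        next
      }
      fm <- fold_metrics(yy[keep], P[keep, r])
      accs <- c(accs, fm[["balanced_accuracy"]])
    }
    data.frame(u = u, mean_excluded = mean(excl),
               balanced_accuracy = if (length(accs)) mean(accs) else NA_real_,
               sd = if (length(accs) > 1) sd(accs) else NA_real_,
               n_missing_repeats = miss)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("reject_curve", "data.frame")
  out
}

#' Post-hoc cluster-network time-course correlations
#'
#' For each subject, the Pearson correlation between the cluster-averaged
#' voxel time course and the subject's stage-1 time course of the
#' designated network; correlations are Fisher-z averaged within group and
#' the group means back-transformed.
#'
#' @param cluster_masks List of logical vectors (one per cluster, over
#'   in-mask voxels) or logical 3D arrays.
#' @param scans List of subject scans (4D arrays or T x voxels matrices).
#' @param subject_timecourses List of T x d stage-1 matrices.
#' @param network 1-based network index.
#' @param labels Subject group labels (character/factor).
#' @param mask Logical 3D array (required for 4D scans / 3D cluster
#'   masks).
#' @return data.frame: cluster, group, mean_r, n.
#' @export
cluster_network_correlation <- function(cluster_masks, scans,
                                        subject_timecourses, network,
                                        labels, mask = NULL) {
  labels <- as.character(labels)
  n <- length(scans)
  stopifnot(length(subject_timecourses) == n, length(labels) == n)
  cl_vecs <- lapply(cluster_masks, function(cm) {
    if (is.array(cm)) {
      if (is.null(mask)) stop("mask required for 3D cluster masks")
      if (any(cm & !mask)) stop("cluster extends outside the analysis mask")
      as.vector(cm)[as.vector(mask)]
    } else as.logical(cm)
  })
  rows <- list()
  for (ci in seq_along(cl_vecs)) {
    rs <- vapply(seq_len(n), function(i) {
      Y <- as_scan_matrix(scans[[i]], mask, NULL)
      ctc <- rowMeans(Y[, cl_vecs[[ci]], drop = FALSE])
      cor(ctc, subject_timecourses[[i]][, network])
    }, numeric(1))
    for (g in unique(labels)) {
      z <- atanh(pmin(pmax(rs[labels == g], -1 + 1e-12), 1 - 1e-12))
      rows[[length(rows) + 1]] <-
        data.frame(cluster = ci, group = g, mean_r = tanh(mean(z)),
                   n = sum(labels == g))
    }
  }
  do.call(rbind, rows)
}
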