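test_that("feature ranking follows |t| with stable tie-breaking", {
  set.seed(101)
  n <- 20
  X <- matrix(rnorm(n * 10), n, 10)
  y <- rep(c(1, -1), each = 10)
  X[, 3] <- X[, 3] + y * 2          # strongly informative
  X[, 7] <- 0                        # zero variance -> t = 0
  sel <- select_features(X, y, 5)
  expect_equal(sel[1], 3)
  expect_false(7 %in% sel)
  expect_equal(sort(select_features(X, y, 10)), 1:10)
  # exact ties broken by lower index
  Xt <- cbind(X[, 3], X[, 3], X[, 3])
  expect_equal(select_features(Xt, y, 2), c(1, 2))
  expect_error(select_features(X, y, 11), "exceeds")
})

test_that("selection concentrates on the planted region and destabilizes under the null", {
  nf <- cohort_network_features(111, effect_size = 1.6, n_responders = 12,
                                n_nonresponders = 10)
  X <- nf$families[[1]]
  yy <- ifelse(nf$y == "responder", 1, -1)
  # the informative voxels are the ~8 effect-mask voxels at this scale,
  # so the enrichment check uses a matching k
  support <- nf$effect_flat |
    (nf$cohort$ground_truth$networks$maps[1, ] >= 0.3)
  sel <- select_features(X, yy, 10)
  expect_gte(mean(support[sel]), 0.7)

  # permuted labels: selected sets are irreproducible
  set.seed(112)
  jac <- replicate(10, {
    s1 <- select_features(X, sample(yy), 100)
    s2 <- select_features(X, sample(yy), 100)
    length(intersect(s1, s2)) / length(union(s1, s2))
  })
  expect_lt(mean(jac), 0.2)
})

test_that("inner-CV tuning of the feature count is sane and deterministic", {
  set.seed(121)
  X <- matrix(rnorm(30 * 60), 30, 60)
  y <- rep(c(1, -1), 15)
  cfg <- cv_config(feature_grid = c(60), gpc = gpc_lean(), seed = 2)
  expect_equal(tune_k(X, y, cfg), 60L)
  cfg2 <- cv_config(feature_grid = c(10, 30, 60), n_inner_folds = 3,
                    gpc = gpc_lean(), seed = 2)
  k1 <- tune_k(X, y, cfg2)
  k2 <- tune_k(X, y, cfg2)
  expect_identical(k1, k2)
  expect_true(k1 %in% c(10L, 30L, 60L))
})

test_that("fold metrics satisfy their algebraic identities", {
  y <- c(1, 1, 1, -1, -1)
  pr <- c(0.9, 0.8, 0.4, 0.3, 0.6)
  m <- rsnpredict:::fold_metrics(y, pr)
  expect_equal(unname(m["balanced_accuracy"]),
               unname((m["sensitivity"] + m["specificity"]) / 2))
  expect_equal(unname(m["sensitivity"]), 2 / 3)
  expect_equal(unname(m["specificity"]), 1 / 2)
  expect_equal(unname(m["ppv"]), 2 / 3)
  expect_equal(unname(m["npv"]), 1 / 2)
  # perfectly separated probabilities give AUC 1
  expect_equal(unname(rsnpredict:::fold_metrics(y, c(.9, .8, .7, .2, .1))["auc"]), 1)
  skip_if_not_installed("pROC")
  set.seed(131)
  yy <- sample(c(1, -1), 40, replace = TRUE)
  pp <- runif(40)
  expect_equal(unname(rsnpredict:::auc_rank(yy, pp)),
               as.numeric(pROC::auc(pROC::roc(yy, pp, quiet = TRUE,
                                              direction = "<", levels = c(-1, 1)))))
})

test_that("repeated CV keeps its structural contracts", {
  set.seed(141)
  n <- 24
  X <- matrix(rnorm(n * 80), n, 80)
  X[, 1:10] <- X[, 1:10] + rep(c(1.5, -1.5), each = 12)
  y <- rep(c("responder", "non-responder"), each = 12)
  cfg <- cv_config(n_repeats = 3, n_outer_folds = 6, n_inner_folds = 3,
                   feature_grid = c(10, 40), gpc = gpc_lean(), seed = 7)
  r <- run_repeated_cv(X, y, cfg)
  # each subject predicted exactly once per repeat
  expect_true(all(colSums(!is.na(r$oof_prob)) == n))
  expect_equal(nrow(r$metrics), 3 * 6)
  expect_true(all(r$selection_counts <= r$total_runs))
  expect_equal(r$total_runs, 18)
  # stratification: fold class ratios within one subject of global
  fold <- rsnpredict:::stratified_folds(ifelse(y == "responder", 1, -1), 6,
                                        seed = 3)
  for (f in 1:6) {
    expect_equal(sum(fold == f & y == "responder"), 2)
    expect_equal(sum(fold == f & y == "non-responder"), 2)
  }
  # reproducibility: pure function of (X, y, seed)
  r2 <- run_repeated_cv(X, y, cfg)
  expect_identical(r$metrics, r2$metrics)
  expect_identical(r$oof_prob, r2$oof_prob)
  expect_gt(r$summary$mean[r$summary$metric == "balanced_accuracy"], 0.8)
  # flipping labels and probabilities swaps sensitivity and specificity
  yy <- ifelse(y == "responder", 1, -1)
  m_f <- rsnpredict:::fold_metrics(-yy, 1 - r$oof_prob[, 1])
  m_o <- rsnpredict:::fold_metrics(yy, r$oof_prob[, 1])
  expect_equal(unname(m_f["sensitivity"]), unname(m_o["specificity"]))
  expect_equal(unname(m_f["specificity"]), unname(m_o["sensitivity"]))
})

test_that("label permutation p-values are valid and Bonferroni-capped", {
  set.seed(151)
  X <- matrix(rnorm(20 * 40), 20, 40)
  X[, 1:5] <- X[, 1:5] + rep(c(2, -2), each = 10)
  y <- rep(c(1, -1), each = 10)
  cfg <- cv_config(n_repeats = 1, n_outer_folds = 5, n_inner_folds = 3,
                   feature_grid = c(10), gpc = gpc_lean(), seed = 3)
  po <- permutation_pvalue(X, y, cfg, n_perm = 99, n_tests = 49)
  expect_gte(po$p_raw, 1 / 100)
  expect_lte(po$p_corrected, 1)
  expect_equal(po$p_corrected, min(1, po$p_raw * 49))
  expect_lt(po$p_raw, 0.05) # strong signal
  # observed below the null median implies p > 0.5 by construction
  fake_null <- seq(0.4, 0.9, length.out = 99)
  p_fake <- (1 + sum(fake_null >= 0.45)) / 100
  expect_gt(p_fake, 0.5)
  expect_error(permutation_pvalue(X, y, cfg, n_perm = 9), ">= 99")
  expect_error(permutation_pvalue(X, y, cfg, n_perm = 99, n_tests = 0),
               ">= 1")
})

test_that("selection clusters are tabulated like the published cluster table", {
  grid <- c(12, 12, 8)
  mask <- array(TRUE, dim = grid)
  freq <- array(0, dim = grid)
  # two disjoint blobs of 14 and 10 voxels above the 50% threshold
  freq[2:3, 2:3, 2:4] <- 0.9          # 12 voxels
  freq[4, 2:3, 2] <- 0.9              # +2 -> 14 (26-connected)
  freq[9:10, 9:10, 3] <- 0.8          # 4
  freq[9:10, 9:10, 4] <- 0.8          # +4
  freq[9:10, 9, 5] <- 0.8             # +2 -> 10
  freq[6, 6, 6] <- 0.2                # below threshold
  counts <- as.vector(freq) * 100
  tab <- selection_clusters(counts, 100, mask, threshold = 0.5,
                            affine = default_affine())
  expect_equal(nrow(tab), 2)
  expect_equal(tab$n_voxels, c(14, 10))
  expect_equal(tab$peak_frequency, c(0.9, 0.8))
  # world coordinates follow the affine on 0-based voxel indices
  expect_equal(tab$peak_mm_x[1], tab$peak_x[1] * 4)

  expect_equal(nrow(selection_clusters(counts, 100, mask, threshold = 1.0)), 0)
})

test_that("reject-option curves exclude the uncertain band correctly", {
  y <- c(1, 1, 1, -1, -1, -1)
  P <- cbind(c(.9, .8, .52, .48, .2, .1), c(.9, .7, .6, .45, .3, .1))
  rc <- reject_curve(P, y, u_grid = c(0, 0.1, 0.25))
  expect_equal(rc$mean_excluded[rc$u == 0], 0)
  # u = 0 equals the overall out-of-fold accuracy (empty rejection region)
  overall <- mean(c(rsnpredict:::fold_metrics(y, P[, 1])["balanced_accuracy"],
                    rsnpredict:::fold_metrics(y, P[, 2])["balanced_accuracy"]))
  expect_equal(rc$balanced_accuracy[rc$u == 0], overall)
  # u = 0.25 rejects (0.375, 0.625): probabilities .4/.6 are both excluded
  rc2 <- reject_curve(matrix(c(0.4, 0.6), 2, 1), c(1, -1), u_grid = 0.25)
  expect_equal(rc2$mean_excluded, 2)
  expect_true(is.na(rc2$balanced_accuracy))
  expect_equal(rc2$n_missing_repeats, 1)
  # excluded count is nondecreasing in u
  rc3 <- reject_curve(P, y, u_grid = seq(0, 0.8, 0.1))
  expect_true(all(diff(rc3$mean_excluded) >= 0))
})

test_that("cluster-network correlations separate signal from noise clusters", {
  nf <- cohort_network_features(161, effect_size = 0, n_responders = 10,
                                n_nonresponders = 10, n_timepoints = 60)
  co <- nf$cohort
  pat <- which(co$clinical$group != "control")
  scans <- lapply(co$scans[pat], function(s) flatten(s, co$mask)$data)
  core <- co$ground_truth$networks$maps[1, ] >= 0.5
  far <- colSums(co$ground_truth$networks$maps >= 0.05) == 0
  set.seed(162)
  noise_cluster <- seq_along(far) %in% sample(which(far), 8)
  res <- cluster_network_correlation(
    list(core, noise_cluster), scans, nf$dr$timecourses, network = 1,
    labels = nf$y)
  sig <- res[res$cluster == 1, ]
  expect_true(all(sig$mean_r > 0.3))
  expect_true(all(abs(res$mean_r[res$cluster == 2]) < 0.15))
  # r of a time course with itself
  tc1 <- nf$dr$timecourses[[1]][, 1]
  expect_equal(cor(tc1, tc1), 1)
})

test_that("nested selection prevents the leakage a corrupted pipeline shows", {
  res <- vapply(1:3, function(s) {
    set.seed(s)
    n <- 24
    X <- matrix(rnorm(n * 300), n, 300)
    y <- rep(c(1, -1), each = 12)
    cfg <- cv_config(n_repeats = 3, n_inner_folds = 3,
                     feature_grid = c(20, 60), gpc = gpc_lean(), seed = s)
    clean <- run_repeated_cv(X, y, cfg)$summary$mean[1]
    sel <- select_features(X, y, 20)   # corrupt: selection sees all labels
    dirty <- run_repeated_cv(X[, sel], y,
                             cv_config(n_repeats = 3, n_inner_folds = 3,
                                       feature_grid = 20, gpc = gpc_lean(),
                                       seed = s))$summary$mean[1]
    c(clean, dirty)
  }, numeric(2))
  expect_gt(mean(res[2, ]), 0.65)
  expect_gte(mean(res[1, ]), 0.40)
  expect_lte(mean(res[1, ]), 0.60)
})
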