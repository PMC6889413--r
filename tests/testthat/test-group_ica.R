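make_ica_cohort <- function(seed, noise_sd = 1, n_controls = 8) {
  cfg <- sim_config(grid_dims = c(12, 12, 10), n_timepoints = 60,
                    n_networks = 4, n_controls = n_controls,
                    n_responders = 2, n_nonresponders = 2,
                    blob_fwhm = 2.5, noise_sd = noise_sd, seed = seed)
  simulate_cohort(cfg)
}

test_that("concatenation stacks demeaned subject blocks on a common mask", {
  co <- make_ica_cohort(41)
  cm <- concat_controls(co$scans[1:8], co$mask)
  expect_equal(nrow(cm$data), 8 * 60)
  blocks <- attr(cm, "block_rows")
  expect_length(blocks, 8)
  # per-subject voxelwise demeaning
  expect_lt(max(abs(colMeans(cm$data[blocks[[2]], ]))), 1e-10)

  expect_error(concat_controls(co$scans[1]), "at least 2")
  bad <- co$scans[1:2]
  bad[[2]] <- array(1, dim = c(5, 5, 5, 10))
  expect_error(concat_controls(bad), "mismatch")
})

test_that("spatial ICA recovers noiseless blob mixtures near-exactly", {
  co <- make_ica_cohort(42, noise_sd = 0)
  cm <- concat_controls(co$scans[1:8], co$mask, variance_normalize = FALSE)
  ic <- spatial_ica(cm, ica_config(n_components = 4, seed = 2))
  m <- match_components(ic$maps, co$ground_truth$networks$maps)
  expect_gt(min(m$abs_r), 0.99)
  expect_true(ic$converged)

  # returned maps are z-scored with positive peak and uncorrelated
  expect_lt(max(abs(rowMeans(ic$maps))), 1e-10)
  expect_equal(unname(apply(ic$maps, 1, sd)), rep(1, 4))
  for (k in 1:4)
    expect_gt(ic$maps[k, which.max(abs(ic$maps[k, ]))], 0)
  cc <- cor(t(ic$maps))
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-6)

  # determinism and rank guard
  ic2 <- spatial_ica(cm, ica_config(n_components = 4, seed = 2))
  expect_identical(ic$maps, ic2$maps)
  expect_error(spatial_ica(matrix(rnorm(3 * 50), 3, 50),
                           ica_config(n_components = 4)), "exceeds")
})

test_that("meta-ICA reproduces and validates its run protocol", {
  co <- make_ica_cohort(43)
  cm <- concat_controls(co$scans[1:8], co$mask)
  icfg <- ica_config(n_components = 4, n_meta_runs = 4, seed = 5)
  expect_error(meta_ica(cm, ica_config(n_components = 4, n_meta_runs = 1)),
               "n_meta_runs >= 2")
  m1 <- meta_ica(cm, icfg)
  m2 <- meta_ica(cm, icfg)
  expect_identical(m1$maps, m2$maps)
  expect_equal(m1$provenance, "meta")
  expect_equal(nrow(m1$run_info), 4)
  tm <- co$ground_truth$networks$maps
  expect_gt(attr(match_components(m1$maps, tm), "mean_abs_r"), 0.5)
})

test_that("component labeling follows the spectral and edge heuristics", {
  grid <- c(8, 8, 6)
  mask <- array(TRUE, dim = grid)
  V <- prod(grid)
  tr <- 1.6
  n_t <- 2000
  # component 1: white-noise time course, interior map
  # component 2: slow 0.05 Hz sinusoid, interior map
  # component 3: slow time course but all weight on the boundary shell
  interior <- array(0, dim = grid)
  interior[4:5, 4:5, 3:4] <- 5
  shell_map <- array(0, dim = grid)
  shell_map[1, 3:6, 2:5] <- 5 # small patch on the x = 0 face
  maps <- rbind(as.vector(interior), as.vector(interior), as.vector(shell_map))
  maps <- t(scale(t(maps))) * 3 # ensure |z| > 2 weight exists
  set.seed(1)
  tcs <- cbind(rnorm(n_t),
               sin(2 * pi * 0.05 * tr * seq_len(n_t)),
               sin(2 * pi * 0.05 * tr * seq_len(n_t) + 1))
  comps <- structure(list(maps = maps, timecourses = tcs, mask = mask,
                          grid_dims = grid, labels = rep("unlabeled", 3),
                          provenance = "single_run"),
                     class = "component_set")
  lab <- label_components(comps, tr_seconds = tr)
  # flat spectrum above 0.1 Hz: expected fraction (0.3125-0.1)/0.3125 = 0.68
  expect_equal(lab$label_scores$highfreq_fraction[1], 0.68, tolerance = 0.05)
  expect_equal(lab$labels, c("noise", "signal", "noise"))

  over <- label_components(comps, tr_seconds = tr,
                           overrides = list("2" = "noise"))
  expect_equal(over$labels[2], "noise")
  expect_error(label_components(comps, tr_seconds = tr,
                                overrides = list("9" = "noise")),
               "nonexistent")
})

test_that("greedy component matching prefers the strongest correlations", {
  set.seed(8)
  ref <- matrix(rnorm(3 * 200), 3, 200)
  est <- ref[c(2, 3, 1), ] + matrix(rnorm(600, sd = 0.05), 3, 200)
  est[1, ] <- -est[1, ] # sign flips must not matter
  m <- match_components(est, ref)
  expect_equal(m$est[m$ref == 2], 1)
  expect_equal(m$est[m$ref == 3], 2)
  expect_equal(m$est[m$ref == 1], 3)
  expect_gt(attr(m, "mean_abs_r"), 0.99)
})
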