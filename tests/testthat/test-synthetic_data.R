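test_that("config validation enforces the documented constraints", {
  expect_error(sim_config(grid_dims = c(5, 5, 5)), "1000")
  expect_error(sim_config(n_networks = 0), ">= 1")
  expect_error(sim_config(effect_network = 9), "networks")
  expect_error(sim_config(responder_reduction = c(0.25, 0.8)), "boundary")
  expect_error(sim_config(nonresponder_reduction = c(-0.1, 0.31)), "boundary")
})

test_that("ground-truth networks are unit-peak, separated, near-orthogonal", {
  cfg <- sim_config(n_networks = 1, seed = 3)
  one <- make_ground_truth_networks(cfg)
  expect_equal(max(one$maps), 1.0)

  cfg8 <- sim_config(seed = 7) # defaults: d = 8, 20x24x20
  nets <- make_ground_truth_networks(cfg8)
  expect_equal(nrow(nets$maps), 8)
  cc <- cor(t(nets$maps))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.2)
  dd <- as.matrix(dist(nets$centers))
  expect_gte(min(dd[upper.tri(dd)]), 2 * cfg8$blob_fwhm)

  # seeded determinism
  nets2 <- make_ground_truth_networks(sim_config(seed = 7))
  expect_identical(nets$maps, nets2$maps)

  # infeasible placement fails naming the constraint
  expect_error(make_ground_truth_networks(
    sim_config(grid_dims = c(10, 10, 10), n_networks = 8, blob_fwhm = 4)),
    "2\\*FWHM|grid too small")
})

test_that("noiseless scans are exact rank-d mixtures with planted SNR structure", {
  cfg <- small_cohort_config(11, effect_size = 0, noise_sd = 0,
                             n_responders = 2, n_nonresponders = 2,
                             n_controls = 2)
  gt <- rsnpredict:::make_ground_truth(cfg)
  scan <- simulate_subject_scan(gt, 1, cfg, seed = 1)
  Y <- flatten(scan, gt$networks$mask)$data
  # projection onto the true time courses leaves zero residual
  tc <- gt$timecourses[[1]]
  fit <- tc %*% qr.coef(qr(tc), Y)
  expect_lt(max(abs(Y - fit)), 1e-8)

  expect_error(simulate_subject_scan(gt, 1, cfg), "seed")

  # temporal SNR higher inside network cores than outside all networks
  cfgn <- small_cohort_config(12, noise_sd = 1, n_responders = 2,
                              n_nonresponders = 2, n_controls = 2)
  gtn <- rsnpredict:::make_ground_truth(cfgn)
  sc <- simulate_subject_scan(gtn, 1, cfgn, seed = 2)
  Yn <- flatten(sc, gtn$networks$mask)$data
  vvar <- apply(Yn, 2, var)
  core <- colSums(gtn$networks$maps >= 0.5) > 0
  outside <- colSums(gtn$networks$maps >= 0.05) == 0
  expect_gt(mean(vvar[core]), mean(vvar[outside]))
})

test_that("clinical table obeys the response rule and inclusion criteria", {
  co <- simulate_cohort(small_cohort_config(21))
  cl <- co$clinical
  pat <- cl$group != "control"
  expect_true(all(cl$caps_pre[pat] >= 45))
  expect_true(all(cl$caps_pre[!pat] < 15))
  red <- (cl$caps_pre[pat] - cl$caps_post[pat]) / cl$caps_pre[pat]
  expect_true(all((red >= 0.30) == (cl$group[pat] == "responder")))
  expect_equal(label_response(cl$caps_pre[pat], cl$caps_post[pat]),
               cl$group[pat])
  expect_true(all(cl$age >= 18 & cl$age <= 60))

  # full determinism of the cohort in both clinical and imaging data
  co2 <- simulate_cohort(small_cohort_config(21))
  expect_identical(co$clinical, co2$clinical)
  expect_identical(co$scans[[3]], co2$scans[[3]])
  expect_identical(co$struct_maps[[1]], co2$struct_maps[[1]])
})

test_that("planted stage-2 effect grows monotonically with effect size", {
  mean_diff <- function(effect) {
    d <- vapply(1:10, function(s) {
      nf <- cohort_network_features(400 + s, effect_size = effect,
                                    n_responders = 6, n_nonresponders = 6,
                                    n_timepoints = 30)
      b <- nf$dr$betas[, 1, nf$effect_flat]
      nonresp <- nf$y == "non-responder"
      mean(b[nonresp, ]) - mean(b[!nonresp, ])
    }, numeric(1))
    mean(d)
  }
  diffs <- vapply(c(0, 0.4, 0.8, 1.6), mean_diff, numeric(1))
  expect_true(all(diff(diffs) > 0))
  expect_lt(abs(diffs[1]), abs(diffs[4]))
})

test_that("cohorts round-trip to disk in plain interchange formats", {
  co <- simulate_cohort(small_cohort_config(31, n_responders = 2,
                                            n_nonresponders = 2,
                                            n_timepoints = 10))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "clinical.tsv")))
  expect_true(file.exists(file.path(dir, "effect_mask.nii.gz")))
  v <- read_volume(file.path(dir, "sub-001_bold.nii.gz"))
  expect_equal(dim(v$data), c(co$config$grid_dims, co$config$n_timepoints))
  expect_equal(v$data, co$scans[[1]], tolerance = 1e-5)
  cl <- read.delim(file.path(dir, "clinical.tsv"))
  expect_equal(nrow(cl), length(co$scans))
})
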