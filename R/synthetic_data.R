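#' Simulation configuration for a synthetic rs-fMRI cohort
#'
#' Defines the study conditions the generator emulates: a cohort of combat
#' controls plus trauma-focused-therapy patients (responders and
#' non-responders by the >= 30 percent CAPS-reduction rule), each subject
#' carrying a preprocessed-style 4D scan built as a linear mixture of
#' spatial networks and band-limited time courses plus Gaussian noise, a
#' smooth structural (gray-matter-like) map, and a clinical table. A group
#' effect can be planted as a multiplicative amplitude change of one
#' network inside a sub-region for non-responders.
#'
#' @param grid_dims Voxels per axis (default 20 x 24 x 20).
#' @param n_timepoints Timepoints per scan (default 100).
#' @param n_networks Number of true networks d (default 8).
#' @param n_controls,n_responders,n_nonresponders Group sizes
#'   (defaults 28, 24, 20).
#' @param effect_network 1-based index of the network carrying the planted
#'   effect.
#' @param effect_size Multiplier added to the effect-network amplitude in
#'   the effect region for non-responders (default 0.8; 0 = null cohort).
#' @param noise_sd Scan noise SD relative to unit signal (default 1.0).
#' @param tr_seconds Sampling interval (default 1.6 s).
#' @param blob_fwhm Network blob FWHM in voxels (default 4).
#' @param lowpass_hz Time-course low-pass cutoff (default 0.1 Hz).
#' @param voxel_size mm per voxel for the affine (default 4 x 4 x 3.6).
#' @param responder_reduction,nonresponder_reduction Uniform ranges for the
#'   fractional CAPS reduction in each patient group. Must stay clear of
#'   the 0.30 response boundary (with margin for integer rounding).
#' @param struct_effect_size Group effect planted in the structural maps
#'   (default 0: null, mirroring a negative gray-matter finding).
#' @param seed Integer seed; the whole cohort is a pure function of the
#'   config.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(grid_dims = c(20L, 24L, 20L),
                       n_timepoints = 100L,
                       n_networks = 8L,
                       n_controls = 28L,
                       n_responders = 24L,
                       n_nonresponders = 20L,
                       effect_network = 1L,
                       effect_size = 0.8,
                       noise_sd = 1.0,
                       tr_seconds = 1.6,
                       blob_fwhm = 4,
                       lowpass_hz = 0.1,
                       voxel_size = c(4, 4, 3.6),
                       responder_reduction = c(0.35, 0.85),
                       nonresponder_reduction = c(-0.10, 0.25),
                       struct_effect_size = 0,
                       seed = 1L) {
  cfg <- list(grid_dims = as.integer(grid_dims),
              n_timepoints = as.integer(n_timepoints),
              n_networks = as.integer(n_networks),
              n_controls = as.integer(n_controls),
              n_responders = as.integer(n_responders),
              n_nonresponders = as.integer(n_nonresponders),
              effect_network = as.integer(effect_network),
              effect_size = effect_size, noise_sd = noise_sd,
              tr_seconds = tr_seconds, blob_fwhm = blob_fwhm,
              lowpass_hz = lowpass_hz, voxel_size = voxel_size,
              responder_reduction = responder_reduction,
              nonresponder_reduction = nonresponder_reduction,
              struct_effect_size = struct_effect_size,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$grid_dims) == 3, all(cfg$grid_dims >= 1))
  if (prod(cfg$grid_dims) < 1000)
    stop("grid volume must be >= 1000 voxels so clusters are resolvable")
  counts <- c(cfg$n_timepoints, cfg$n_networks, cfg$n_controls,
              cfg$n_responders, cfg$n_nonresponders)
  if (any(counts < 1)) stop("all counts must be >= 1")
  if (cfg$effect_network < 1 || cfg$effect_network > cfg$n_networks)
    stop("effect_network must index one of the ", cfg$n_networks, " networks")
  if (cfg$noise_sd < 0 || cfg$tr_seconds <= 0 || cfg$blob_fwhm <= 0)
    stop("noise_sd must be >= 0 and tr_seconds, blob_fwhm > 0")
  # rounding of integer CAPS scores can move the realized reduction by
  # up to 0.5/45; require the ranges to clear the 0.30 rule by that margin
  eps <- 0.5 / 45
  if (cfg$responder_reduction[1] < 0.30 + eps)
    stop("responder_reduction range crosses the 0.30 response boundary")
  if (cfg$nonresponder_reduction[2] > 0.30 - eps)
    stop("nonresponder_reduction range crosses the 0.30 response boundary")
  invisible(cfg)
}

subject_groups <- function(cfg) {
  factor(rep(c("control", "responder", "non-responder"),
             c(cfg$n_controls, cfg$n_responders, cfg$n_nonresponders)),
         levels = c("control", "responder", "non-responder"))
}

#' Ground-truth spatial networks
#'
#' Places `n_networks` isotropic Gaussian blobs (unit peak) at seeded
#' centers that are pairwise separated by at least twice the blob FWHM and
#' at least one FWHM from the grid boundary.
#'
#' @param config A [sim_config()].
#' @return A `component_set` with `maps` (d x voxels over the full-grid
#'   mask), `mask`, `grid_dims`, `affine` and `labels`.
#' @export
make_ground_truth_networks <- function(config) {
  validate_sim_config(config)
  d <- config$n_networks
  grid <- config$grid_dims
  fwhm <- config$blob_fwhm
  margin <- ceiling(fwhm)
  if (any(grid - 2 * margin < 1))
    stop("grid too small to place ", d, " blobs: need at least ",
         2 * margin + 1, " voxels per axis for FWHM ", fwhm)
  set.seed(derive_seed(config$seed, 1L))
  min_sep <- 2 * fwhm
  # seeded farthest-point selection from a uniform candidate pool:
  # deterministic given the seed and far more reliable than rejection
  # sampling when the separation constraint is tight
  n_cand <- max(500L, 50L * d)
  cand <- cbind(margin + runif(n_cand) * (grid[1] - 2 * margin),
                margin + runif(n_cand) * (grid[2] - 2 * margin),
                margin + runif(n_cand) * (grid[3] - 2 * margin))
  centers <- matrix(NA_real_, nrow = d, ncol = 3)
  centers[1, ] <- cand[1, ]
  mind <- sqrt(rowSums(sweep(cand, 2, centers[1, ])^2))
  for (k in seq_len(d)[-1]) {
    pick <- which.max(mind)
    centers[k, ] <- cand[pick, ]
    mind <- pmin(mind, sqrt(rowSums(sweep(cand, 2, centers[k, ])^2)))
  }
  # refinement sweeps: re-place each center at the candidate farthest
  # from the remaining ones (pushes the greedy start towards maximin)
  if (d > 1) {
    for (sweep_i in 1:3) {
      for (k in seq_len(d)) {
        others <- centers[-k, , drop = FALSE]
        md <- rep(Inf, nrow(cand))
        for (o in seq_len(nrow(others)))
          md <- pmin(md, sqrt(rowSums(sweep(cand, 2, others[o, ])^2)))
        centers[k, ] <- cand[which.max(md), ]
      }
    }
  }
  if (d > 1) {
    dd <- as.matrix(stats::dist(centers))
    diag(dd) <- Inf
    if (min(dd) < min_sep)
      stop("grid too small to place ", d,
           " blob centers pairwise separated by 2*FWHM = ", min_sep,
           " voxels; enlarge the grid or reduce blob_fwhm/n_networks")
  }
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  co <- expand.grid(x = seq_len(grid[1]), y = seq_len(grid[2]),
                    z = seq_len(grid[3]))
  maps <- matrix(0, nrow = d, ncol = prod(grid))
  for (k in seq_len(d)) {
    d2 <- (co$x - centers[k, 1])^2 + (co$y - centers[k, 2])^2 +
      (co$z - centers[k, 3])^2
    maps[k, ] <- exp(-d2 / (2 * sigma^2))
    # exact unit peak at the nearest voxel to the center
    maps[k, ] <- maps[k, ] / max(maps[k, ])
  }
  mask <- array(TRUE, dim = grid)
  structure(list(maps = maps, mask = mask, grid_dims = grid,
                 affine = default_affine(config$voxel_size),
                 timecourses = NULL, centers = centers,
                 labels = rep("signal", d), provenance = "ground_truth"),
            class = "component_set")
}

# Band-limited standardized noise: white Gaussian noise low-pass filtered
# in the frequency domain at `cutoff` Hz, then z-scored.
lowpass_timecourse <- function(n, tr, cutoff) {
  x <- rnorm(n)
  xf <- fft(x)
  freq <- (seq_len(n) - 1) / (n * tr)
  freq <- pmin(freq, 1 / tr - freq) # two-sided spectrum
  xf[freq > cutoff] <- 0
  y <- Re(fft(xf, inverse = TRUE)) / n
  (y - mean(y)) / sd(y)
}

# Full latent state of a cohort: maps, per-subject time courses and
# loadings, labels, and the planted-effect region.
make_ground_truth <- function(config) {
  networks <- make_ground_truth_networks(config)
  d <- config$n_networks
  groups <- subject_groups(config)
  n_total <- length(groups)
  set.seed(derive_seed(config$seed, 2L))
  loadings <- matrix(pmax(rnorm(n_total * d, mean = 1, sd = 0.15), 0.3),
                     nrow = n_total, ncol = d)
  timecourses <- lapply(seq_len(n_total), function(i)
    vapply(seq_len(d), function(k)
      lowpass_timecourse(config$n_timepoints, config$tr_seconds,
                         config$lowpass_hz),
      numeric(config$n_timepoints)))
  effect_mask_flat <- networks$maps[config$effect_network, ] >= 0.5
  list(networks = networks, labels = groups, loadings = loadings,
       timecourses = timecourses,
       effect_mask = array(effect_mask_flat, dim = config$grid_dims),
       config = config)
}

#' Simulate one subject's 4D scan
#'
#' `scan(v, t) = sum_k loading_k * tc_k(t) * map_k(v) + noise`. For
#' non-responders the effect-network contribution inside the effect region
#' is multiplied by `1 + effect_size`.
#'
#' @param ground_truth Output of the internal ground-truth builder (as
#'   stored in a simulated cohort).
#' @param subject_index 1-based subject index.
#' @param config The [sim_config()] used to build `ground_truth`.
#' @param seed Explicit integer seed for the noise draw (required: no
#'   hidden global randomness).
#' @return 4D array (x, y, z, t).
#' @export
simulate_subject_scan <- function(ground_truth, subject_index, config, seed) {
  if (missing(seed)) stop("seed is required (no hidden global randomness)")
  i <- subject_index
  if (i < 1 || i > length(ground_truth$labels))
    stop("subject_index out of range")
  maps <- ground_truth$networks$maps
  if (ground_truth$labels[i] == "non-responder" && config$effect_size != 0) {
    em <- as.vector(ground_truth$effect_mask)
    maps[config$effect_network, em] <-
      maps[config$effect_network, em] * (1 + config$effect_size)
  }
  tc <- ground_truth$timecourses[[i]]            # T x d
  signal <- tc %*% (ground_truth$loadings[i, ] * maps)
  if (config$noise_sd > 0) {
    set.seed(seed)
    signal <- signal + rnorm(length(signal), sd = config$noise_sd)
  }
  array(t(signal), dim = c(config$grid_dims, config$n_timepoints))
}

# Smooth random field on the grid: white noise convolved with a separable
# Gaussian kernel along each axis.
smooth_field <- function(grid, sigma = 2) {
  v <- array(rnorm(prod(grid)), dim = grid)
  half <- max(1L, ceiling(3 * sigma))
  kern <- dnorm(seq(-half, half), sd = sigma)
  kern <- kern / sum(kern)
  for (ax in 1:3) {
    v <- apply(v, setdiff(1:3, ax), function(x) {
      n <- length(x)
      xp <- c(rep(x[1], half), x, rep(x[n], half))
      stats::convolve(xp, rev(kern), type = "filter")
    })
    v <- aperm(v, order(c(ax, setdiff(1:3, ax))))
  }
  v / sd(v)
}

#' Simulate a full cohort
#'
#' Generates scans, structural maps, a clinical table and the ground truth
#' for a controls + responders + non-responders cohort. Clinical scores are
#' drawn consistently with the response rule: patient baseline CAPS is
#' Normal(70, 13) truncated at >= 45, responders reduce it by
#' Uniform(0.35, 0.85), non-responders by Uniform(-0.10, 0.25); controls
#' score below 15. Ages are Normal(36, 9) clipped to 18-60 and TIV is
#' Normal(1540, 140) ml. Structural maps are smooth random fields with an
#' optional planted group effect (default none).
#'
#' @param config A [sim_config()].
#' @return A `sim_cohort`: list with `scans` (list of 4D arrays, patients
#'   and controls), `struct_maps` (list of 3D arrays), `clinical`
#'   (data.frame), `ground_truth`, `mask`, `affine`, `config`.
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  gt <- make_ground_truth(config)
  groups <- gt$labels
  n_total <- length(groups)
  is_pat <- groups != "control"

  set.seed(derive_seed(config$seed, 3L))
  caps_pre <- integer(n_total)
  caps_pre[!is_pat] <- round(runif(sum(!is_pat), 0, 14))
  npat <- sum(is_pat)
  draw <- rnorm(npat * 20, 70, 13)
  draw <- draw[draw >= 45]
  if (length(draw) < npat) stop("truncated CAPS draw failed; retry with another seed")
  caps_pre[is_pat] <- round(draw[seq_len(npat)])
  red <- numeric(n_total)
  r_i <- groups == "responder"
  n_i <- groups == "non-responder"
  red[r_i] <- runif(sum(r_i), config$responder_reduction[1],
                    config$responder_reduction[2])
  red[n_i] <- runif(sum(n_i), config$nonresponder_reduction[1],
                    config$nonresponder_reduction[2])
  caps_post <- ifelse(is_pat, round(caps_pre * (1 - red)), NA_integer_)
  age <- pmin(pmax(rnorm(n_total, 36, 9), 18), 60)
  tiv <- rnorm(n_total, 1540, 140)
  handed <- sample(c("right", "left", "ambidexter"), n_total, replace = TRUE,
                   prob = c(0.8, 0.1, 0.1))
  clinical <- data.frame(
    subject_id = sprintf("sub-%03d", seq_len(n_total)),
    group = as.character(groups),
    age = age,
    caps_pre = caps_pre,
    caps_post = caps_post,
    tiv = tiv,
    handedness = handed,
    med_sri = rbinom(n_total, 1, 0.25),
    med_benzo = rbinom(n_total, 1, 0.2),
    comorbid_mood = rbinom(n_total, 1, 0.4),
    stringsAsFactors = FALSE)

  scans <- lapply(seq_len(n_total), function(i)
    simulate_subject_scan(gt, i, config, seed = derive_seed(config$seed, 4L, i)))

  set.seed(derive_seed(config$seed, 5L))
  struct_maps <- lapply(seq_len(n_total), function(i) {
    f <- 700 + 50 * smooth_field(config$grid_dims, sigma = 2)
    if (config$struct_effect_size != 0 && groups[i] == "non-responder")
      f <- f + config$struct_effect_size * 50 * gt$effect_mask
    f
  })

  structure(list(scans = scans, struct_maps = struct_maps,
                 clinical = clinical, ground_truth = gt,
                 mask = gt$networks$mask,
                 affine = default_affine(config$voxel_size),
                 config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("sim_cohort:", length(x$scans), "subjects (",
      x$config$n_controls, "controls /", x$config$n_responders,
      "responders /", x$config$n_nonresponders, "non-responders ), grid",
      paste(x$config$grid_dims, collapse = "x"), ", T =",
      x$config$n_timepoints, "\n")
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Scans and structural maps as NIfTI-1 (`.nii.gz`), the clinical table as
#' TSV, the effect mask as uint8 NIfTI, and the generation metadata as
#' JSON.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  aff <- cohort$affine
  for (i in seq_along(cohort$scans)) {
    id <- cohort$clinical$subject_id[i]
    write_volume(cohort$scans[[i]], aff, file.path(dir, paste0(id, "_bold.nii.gz")))
    write_volume(cohort$struct_maps[[i]], aff, file.path(dir, paste0(id, "_gm.nii.gz")))
  }
  write_volume(array(as.numeric(cohort$ground_truth$effect_mask),
                     dim = cohort$config$grid_dims),
               aff, file.path(dir, "effect_mask.nii.gz"))
  write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- cohort$config
  class(meta) <- NULL
  jsonlite::write_json(meta, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
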