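#' ICA configuration
#'
#' @param n_components Number of spatial components d.
#' @param n_meta_runs Number of ICA runs feeding the meta decomposition
#'   (default 25).
#' @param nonlinearity Contrast nonlinearity, `"tanh"` or `"cube"`.
#' @param max_iter Maximum fixed-point iterations.
#' @param tolerance Convergence tolerance on the rotation update.
#' @param seed Integer seed.
#' @return `ica_config` object.
#' @export
ica_config <- function(n_components = 8L, n_meta_runs = 25L,
                       nonlinearity = c("tanh", "cube"),
                       max_iter = 300L, tolerance = 1e-5, seed = 1L) {
  nonlinearity <- match.arg(nonlinearity)
  stopifnot(n_components >= 1, n_meta_runs >= 1, max_iter >= 1,
            tolerance > 0)
  structure(list(n_components = as.integer(n_components),
                 n_meta_runs = as.integer(n_meta_runs),
                 nonlinearity = nonlinearity,
                 max_iter = as.integer(max_iter), tolerance = tolerance,
                 seed = as.integer(seed)),
            class = "ica_config")
}

#' Temporally concatenate control scans
#'
#' Flattens each control scan over the common mask, demeans and
#' variance-normalizes every voxel's time series within subject, and
#' stacks subjects along the time axis (the standard group-ICA input).
#'
#' @param scans List of 4D arrays (>= 2 subjects).
#' @param mask Logical 3D array; default: intersection mask via
#'   [compute_mask()].
#' @param variance_normalize Scale each voxel's time series by an
#'   estimate of its *noise* standard deviation within subject (default).
#'   The estimate is the successive-difference estimator
#'   `sd(diff(ts))/sqrt(2)`, which isolates the white measurement noise
#'   from the band-limited network signal; normalizing by total variance
#'   instead would flatten the spatial amplitude structure ICA relies on.
#'   Disable for strictly noiseless rank-d data (exact-recovery oracles).
#' @return A `masked_matrix` with `sum(T_i)` rows; attribute
#'   `block_rows` records each subject's row indices.
#' @export
concat_controls <- function(scans, mask = NULL, variance_normalize = TRUE) {
  if (!is.list(scans) || length(scans) < 2)
    stop("need at least 2 control scans (meta-ICA resampling is undefined for 1)")
  if (is.null(mask)) mask <- compute_mask(scans)
  blocks <- lapply(scans, function(s) {
    fm <- flatten(s, mask)
    x <- fm$data
    mu <- colMeans(x)
    x <- sweep(x, 2, mu)
    if (variance_normalize) {
      dn <- apply(x, 2, function(ts) sd(diff(ts))) / sqrt(2)
      dn[dn == 0] <- 1
      x <- sweep(x, 2, dn, "/")
    }
    x
  })
  out <- flatten(scans[[1]], mask)
  out$data <- do.call(rbind, blocks)
  out$row_meaning <- "time"
  nt <- vapply(blocks, nrow, integer(1))
  ends <- cumsum(nt)
  attr(out, "block_rows") <- mapply(function(a, b) seq(a, b),
                                    ends - nt + 1, ends, SIMPLIFY = FALSE)
  out
}

# PCA-whitening of the spatial view: rows of the returned matrix are d
# uncorrelated unit-variance (over voxels) projections. Centering is per
# row (over voxels) — the spatial-ICA convention where voxels are the
# samples; column demeaning would annihilate any direction shared across
# rows (fatal for a stacked-maps input).
whiten_spatial <- function(X, d) {
  Xc <- X - rowMeans(X)
  V <- ncol(Xc)
  C <- tcrossprod(Xc) / V             # rows x rows covariance
  ev <- eigen(C, symmetric = TRUE)
  if (d > sum(ev$values > 1e-12 * ev$values[1]))
    stop("requested ", d, " components but the data have lower rank")
  lam <- ev$values[seq_len(d)]
  E <- ev$vectors[, seq_len(d), drop = FALSE]
  Z <- diag(1 / sqrt(lam), d) %*% t(E) %*% Xc
  list(Z = Z, Xc = Xc)
}

# symmetric decorrelation W <- (W W')^{-1/2} W
sym_decorrelate <- function(W) {
  s <- eigen(tcrossprod(W), symmetric = TRUE)
  s$vectors %*% diag(1 / sqrt(pmax(s$values, 1e-12)), nrow(W)) %*%
    t(s$vectors) %*% W
}

#' Spatial ICA by fixed-point iteration
#'
#' PCA-whitens the (time x voxel) matrix to `n_components` dimensions and
#' runs a symmetric fixed-point iteration maximizing the non-Gaussianity
#' of the spatial maps. Maps are returned z-scored over the mask with the
#' sign convention that the voxel of maximum absolute weight is positive;
#' associated time courses are the least-squares mixing columns.
#'
#' @param x A `masked_matrix` (or plain rows x voxels matrix).
#' @param config An [ica_config()].
#' @param seed Seed for the random orthogonal initialization (defaults to
#'   `config$seed`).
#' @return A `component_set` with `maps` (d x voxels, z-scored),
#'   `timecourses` (rows x d), `converged`, `n_iter`,
#'   `provenance = "single_run"`.
#' @export
spatial_ica <- function(x, config, seed = config$seed) {
  mm <- NULL
  if (inherits(x, "masked_matrix")) {
    mm <- x
    x <- x$data
  }
  d <- config$n_components
  if (nrow(x) < d)
    stop("n_components (", d, ") exceeds the number of rows (", nrow(x), ")")
  w <- whiten_spatial(x, d)
  Z <- w$Z
  V <- ncol(Z)
  set.seed(seed)
  W <- sym_decorrelate(matrix(rnorm(d * d), d, d))
  converged <- FALSE
  it <- 0L
  for (it in seq_len(config$max_iter)) {
    WX <- W %*% Z
    if (config$nonlinearity == "tanh") {
      G <- tanh(WX)
      gp <- rowMeans(1 - G^2)
    } else {
      G <- WX^3
      gp <- rowMeans(3 * WX^2)
    }
    W_new <- G %*% t(Z) / V - gp * W
    W_new <- sym_decorrelate(W_new)
    delta <- max(abs(1 - abs(rowSums(W_new * W))))
    W <- W_new
    if (delta < config$tolerance) {
      converged <- TRUE
      break
    }
  }
  S <- W %*% Z
  # z-score over the mask and fix signs
  S <- (S - rowMeans(S)) / apply(S, 1, sd)
  for (k in seq_len(d)) {
    v <- S[k, which.max(abs(S[k, ]))]
    if (v < 0) S[k, ] <- -S[k, ]
  }
  # mixing time courses: least squares of the data on the maps
  A <- w$Xc %*% t(S) %*% solve(tcrossprod(S))
  out <- list(maps = S, timecourses = A,
              labels = rep("unlabeled", d),
              converged = converged, n_iter = it,
              provenance = "single_run", seed = seed)
  if (!is.null(mm)) {
    out$mask <- mm$mask
    out$grid_dims <- mm$grid_dims
    out$affine <- mm$affine
  }
  class(out) <- "component_set"
  if (!converged)
    warning("spatial ICA did not converge in ", config$max_iter,
            " iterations (delta tolerance ", config$tolerance, ")")
  out
}

#' Meta-ICA: reproducible group components
#'
#' Runs [spatial_ica()] `n_meta_runs` times from distinct random
#' initializations (optionally also on with-replacement resamples of the
#' subject blocks), stacks all resulting z-scored maps into a
#' (runs*d) x voxels matrix, and decomposes that stack with one final
#' spatial ICA of d components. Re-decomposition of pooled run maps is
#' the standard construction for extracting components that reproduce
#' across runs; non-convergent runs are excluded from the stack.
#'
#' @inheritParams spatial_ica
#' @param subject_bootstrap Also resample subject blocks with replacement
#'   per run (requires the `block_rows` attribute set by
#'   [concat_controls()]). Default off: bootstrap runs see less unique
#'   data, which costs recovery accuracy unless single runs are unstable.
#' @return A `component_set` with `provenance = "meta"`; `run_info` lists
#'   per-run seeds and convergence.
#' @export
meta_ica <- function(x, config, subject_bootstrap = FALSE) {
  if (config$n_meta_runs < 2)
    stop("meta-ICA needs n_meta_runs >= 2")
  mm <- if (inherits(x, "masked_matrix")) x else NULL
  blocks <- attr(x, "block_rows")
  if (subject_bootstrap && is.null(blocks)) {
    warning("no block_rows attribute: subject bootstrap disabled, ",
            "runs differ by initialization only")
    subject_bootstrap <- FALSE
  }
  xd <- if (is.null(mm)) x else mm$data
  runs <- vector("list", config$n_meta_runs)
  seeds <- vapply(seq_len(config$n_meta_runs),
                  function(r) derive_seed(config$seed, 10L, r), integer(1))
  for (r in seq_len(config$n_meta_runs)) {
    xr <- x
    if (subject_bootstrap) {
      set.seed(derive_seed(config$seed, 12L, r))
      pick <- sample(length(blocks), replace = TRUE)
      xr <- xd[unlist(blocks[pick]), , drop = FALSE]
    }
    runs[[r]] <- withCallingHandlers(
      spatial_ica(xr, config, seed = seeds[r]),
      warning = function(w) invokeRestart("muffleWarning"))
  }
  ok <- vapply(runs, function(r) isTRUE(r$converged), logical(1))
  if (sum(ok) < length(runs) / 2)
    stop("more than half of the ", length(runs), " ICA runs failed to converge")
  stack <- do.call(rbind, lapply(runs[ok], function(r) r$maps))
  final <- spatial_ica(stack, config, seed = derive_seed(config$seed, 11L))
  # time courses of the meta maps on the original data
  Xc <- xd - rowMeans(xd)
  A <- Xc %*% t(final$maps) %*% solve(tcrossprod(final$maps))
  final$timecourses <- A
  final$provenance <- "meta"
  final$run_info <- data.frame(run = seq_along(runs), seed = seeds,
                               converged = ok)
  if (!is.null(mm)) {
    final$mask <- mm$mask
    final$grid_dims <- mm$grid_dims
    final$affine <- mm$affine
  }
  final
}

# boundary shell of a mask: in-mask voxels with a 6-neighbour outside
mask_shell <- function(mask) {
  grid <- dim(mask)
  padded <- array(FALSE, dim = grid + 2)
  padded[2:(grid[1] + 1), 2:(grid[2] + 1), 2:(grid[3] + 1)] <- mask
  interior <- padded[2:(grid[1] + 1), 2:(grid[2] + 1), 2:(grid[3] + 1)]
  for (sh in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))) {
    nb <- padded[(2:(grid[1] + 1)) + sh[1], (2:(grid[2] + 1)) + sh[2],
                 (2:(grid[3] + 1)) + sh[3]]
    interior <- interior & nb
  }
  mask & !interior
}

# fraction of time-course spectral power above `cutoff` Hz (DC excluded)
highfreq_fraction <- function(tc, tr, cutoff = 0.1) {
  n <- length(tc)
  p <- Mod(fft(tc - mean(tc)))^2
  k <- seq_len(floor(n / 2))
  freq <- k / (n * tr)
  sum(p[k + 1][freq > cutoff]) / sum(p[k + 1])
}

#' Label components as signal or noise
#'
#' Automatic heuristics mark a component as noise when (a) the fraction of
#' its time-course spectral power above 0.1 Hz exceeds `hf_threshold`, or
#' (b) the fraction of suprathreshold map weight (|z| > 2) lying on the
#' mask boundary shell exceeds `edge_threshold`. Manual overrides are
#' applied last and recorded, keeping the semi-automatic procedure
#' auditable.
#'
#' @param components A `component_set` carrying `timecourses`.
#' @param tr_seconds Sampling interval of the time courses.
#' @param hf_threshold,edge_threshold Heuristic cutoffs (defaults 0.5).
#' @param hf_cutoff_hz Spectral split point (default 0.1 Hz).
#' @param overrides Optional named list/vector mapping component index to
#'   `"signal"` or `"noise"`.
#' @return The `component_set` with `labels`, `label_scores` and
#'   `label_overrides` filled in.
#' @export
label_components <- function(components, tr_seconds,
                             hf_threshold = 0.5, edge_threshold = 0.5,
                             hf_cutoff_hz = 0.1, overrides = NULL) {
  if (is.null(components$timecourses))
    stop("components carry no time courses; run spatial_ica/meta_ica first")
  d <- nrow(components$maps)
  hf <- vapply(seq_len(d), function(k)
    highfreq_fraction(components$timecourses[, k], tr_seconds, hf_cutoff_hz),
    numeric(1))
  if (!is.null(components$mask)) {
    shell <- as.vector(mask_shell(components$mask))[as.vector(components$mask)]
  } else {
    shell <- rep(FALSE, ncol(components$maps))
  }
  edge <- vapply(seq_len(d), function(k) {
    w <- abs(components$maps[k, ])
    supra <- w > 2
    if (!any(supra)) return(0)
    sum(w[supra & shell]) / sum(w[supra])
  }, numeric(1))
  labels <- ifelse(hf > hf_threshold | edge > edge_threshold,
                   "noise", "signal")
  if (!is.null(overrides)) {
    idx <- as.integer(names(overrides))
    if (any(is.na(idx)) || any(idx < 1 | idx > d))
      stop("override references a nonexistent component")
    bad <- !unlist(overrides) %in% c("signal", "noise")
    if (any(bad)) stop("override labels must be 'signal' or 'noise'")
    labels[idx] <- unlist(overrides)
  }
  components$labels <- labels
  components$label_scores <- data.frame(component = seq_len(d),
                                        highfreq_fraction = hf,
                                        edge_fraction = edge,
                                        label = labels)
  components$label_overrides <- overrides
  components
}

#' @export
print.component_set <- function(x, ...) {
  cat("component_set (", x$provenance, "):", nrow(x$maps), "maps x",
      ncol(x$maps), "voxels;",
      sum(x$labels == "signal"), "signal /",
      sum(x$labels == "noise"), "noise /",
      sum(x$labels == "unlabeled"), "unlabeled\n")
  invisible(x)
}

#' Greedy matching of estimated to reference component maps
#'
#' Pairs each reference map with an estimated map by repeatedly taking the
#' largest absolute spatial correlation (ties: larger |r| first, then
#' lower component index).
#'
#' @param est_maps,ref_maps d x voxels matrices.
#' @return data.frame with `ref`, `est`, `abs_r`; attribute `mean_abs_r`.
#' @export
match_components <- function(est_maps, ref_maps) {
  R <- abs(cor(t(ref_maps), t(est_maps)))
  nr <- nrow(R)
  res <- data.frame(ref = integer(0), est = integer(0), abs_r = numeric(0))
  for (step in seq_len(min(dim(R)))) {
    ij <- which(R == max(R), arr.ind = TRUE)[1, ]
    res <- rbind(res, data.frame(ref = ij[1], est = ij[2],
                                 abs_r = R[ij[1], ij[2]]))
    R[ij[1], ] <- -1
    R[, ij[2]] <- -1
  }
  res <- res[order(res$ref), ]
  rownames(res) <- NULL
  attr(res, "mean_abs_r") <- mean(res$abs_r)
  res
}
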