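#' Dual regression stage 1: subject time courses
#'
#' Ordinary least squares of each timepoint's voxel vector on the d group
#' maps. The scan is voxelwise demeaned and the spatial design carries an
#' explicit intercept, so coefficients are fluctuation amplitudes.
#'
#' @param scan 4D array or rows x voxels matrix (timepoints x in-mask
#'   voxels).
#' @param group_maps d x voxels matrix (e.g. `component_set$maps`).
#' @param mask Logical 3D array, required when `scan` is 4D.
#' @return T x d matrix of time courses.
#' @export
stage1_timecourses <- function(scan, group_maps, mask = NULL) {
  Y <- as_scan_matrix(scan, mask, ncol(group_maps))
  Y <- sweep(Y, 2, colMeans(Y))
  G <- cbind(1, t(group_maps))              # voxels x (1+d)
  qrG <- qr(G)
  if (qrG$rank < ncol(G)) {
    dg <- sqrt(colSums(G^2))
    dg[dg == 0] <- 1
    cc <- suppressWarnings(abs(cor(G / rep(dg, each = nrow(G)))))
    diag(cc) <- 0
    cc[is.na(cc)] <- 1 # zero-variance components are degenerate collinear
    stop("group map matrix is rank deficient (collinear or zero components; ",
         "worst pair |r| = ", round(max(cc, na.rm = TRUE), 4), ")")
  }
  tc <- t(qr.coef(qrG, t(Y)))               # T x (1+d)
  tc[, -1, drop = FALSE]
}

#' Dual regression stage 2: subject spatial maps
#'
#' Per-voxel OLS of the voxel time series on all d stage-1 time courses
#' jointly. With `variance_normalize` (default) each time course is scaled
#' to unit variance first so betas reflect connectivity amplitude.
#'
#' @param scan As in [stage1_timecourses()].
#' @param timecourses T x d matrix from stage 1.
#' @param variance_normalize Scale time courses to unit variance first.
#' @param mask Logical 3D array, required when `scan` is 4D.
#' @return d x voxels matrix of regression coefficients.
#' @export
stage2_subject_maps <- function(scan, timecourses, variance_normalize = TRUE,
                                mask = NULL) {
  Y <- as_scan_matrix(scan, mask, NULL)
  if (nrow(Y) != nrow(timecourses))
    stop("scan has ", nrow(Y), " timepoints but timecourses have ",
         nrow(timecourses))
  Y <- sweep(Y, 2, colMeans(Y))
  tc <- sweep(timecourses, 2, colMeans(timecourses))
  if (variance_normalize) {
    s <- apply(tc, 2, sd)
    if (any(s == 0)) stop("zero-variance time course: component ",
                          paste(which(s == 0), collapse = ", "))
    tc <- sweep(tc, 2, s, "/")
  }
  qr.coef(qr(tc), Y)                        # d x voxels (no intercept: demeaned)
}

as_scan_matrix <- function(scan, mask, expected_cols) {
  if (is.array(scan) && length(dim(scan)) == 4) {
    if (is.null(mask)) stop("mask is required for a 4D scan")
    Y <- flatten(scan, mask)$data
  } else if (is.matrix(scan)) {
    Y <- scan
  } else stop("scan must be a 4D array or a timepoints x voxels matrix")
  if (!is.null(expected_cols) && ncol(Y) != expected_cols)
    stop("scan has ", ncol(Y), " voxels but group maps have ", expected_cols)
  Y
}

#' Run dual regression over a cohort
#'
#' Applies stages 1 and 2 to every subject and assembles the per-subject,
#' per-network spatial coefficient maps that feed all downstream
#' inference.
#'
#' @param scans List of 4D arrays (or T x voxels matrices), one per
#'   subject, in cohort manifest order.
#' @param components A `component_set` (or d x voxels matrix).
#' @param mask Logical 3D array; defaults to the component set's mask.
#' @param variance_normalize Passed to [stage2_subject_maps()].
#' @param subject_ids Optional character vector for error messages and
#'   downstream tables.
#' @return A `subject_network_maps` object: `betas` (subjects x d x
#'   voxels), `timecourses` (list of T x d), `r2` (per-subject fit),
#'   `mask`, `grid_dims`, `affine`.
#' @export
run_dual_regression <- function(scans, components, mask = NULL,
                                variance_normalize = TRUE,
                                subject_ids = NULL) {
  if (length(scans) < 2) stop("need at least 2 subjects")
  maps <- if (inherits(components, "component_set")) components$maps else components
  if (is.null(mask) && inherits(components, "component_set"))
    mask <- components$mask
  n <- length(scans)
  d <- nrow(maps)
  if (is.null(subject_ids)) subject_ids <- sprintf("sub-%03d", seq_len(n))
  first <- TRUE
  betas <- NULL
  tcs <- vector("list", n)
  r2 <- numeric(n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      tc <- stage1_timecourses(scans[[i]], maps, mask)
      b <- stage2_subject_maps(scans[[i]], tc, variance_normalize, mask)
      Y <- as_scan_matrix(scans[[i]], mask, NULL)
      Y <- sweep(Y, 2, colMeans(Y))
      tcn <- sweep(tc, 2, colMeans(tc))
      if (variance_normalize) tcn <- sweep(tcn, 2, apply(tcn, 2, sd), "/")
      fit <- tcn %*% b
      list(tc = tc, b = b,
           r2 = 1 - sum((Y - fit)^2) / sum(Y^2))
    }, error = function(e)
      stop("dual regression failed for subject ", subject_ids[i], ": ",
           conditionMessage(e), call. = FALSE))
    if (first) {
      betas <- array(NA_real_, dim = c(n, d, ncol(res$b)))
      first <- FALSE
    }
    betas[i, , ] <- res$b
    tcs[[i]] <- res$tc
    r2[i] <- res$r2
  }
  structure(list(betas = betas, timecourses = tcs, r2 = r2,
                 subject_ids = subject_ids,
                 variance_normalized = variance_normalize,
                 mask = mask,
                 grid_dims = if (!is.null(mask)) dim(mask) else NULL,
                 affine = if (inherits(components, "component_set"))
                   components$affine else NULL),
            class = "subject_network_maps")
}

#' @export
print.subject_network_maps <- function(x, ...) {
  cat("subject_network_maps:", dim(x$betas)[1], "subjects x",
      dim(x$betas)[2], "networks x", dim(x$betas)[3], "voxels; median R2 =",
      round(stats::median(x$r2), 3), "\n")
  invisible(x)
}
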