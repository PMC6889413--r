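#' TFCE parameters
#'
#' Extent exponent E = 0.5, height exponent H = 2 and ~100 integration
#' steps are the method's recommended defaults for volumetric data;
#' `connectivity` chooses the 6/18/26-neighbourhood (default 26).
#'
#' @param E,H Extent and height exponents.
#' @param dh Integration step; `NULL` means `max(|stat|)/n_steps` per map.
#' @param n_steps Number of integration steps when `dh` is `NULL`.
#' @param connectivity 6, 18 or 26.
#' @return `tfce_params` object.
#' @export
tfce_params <- function(E = 0.5, H = 2, dh = NULL, n_steps = 100L,
                        connectivity = 26L) {
  stopifnot(E > 0, H > 0, is.null(dh) || dh > 0, n_steps >= 1,
            connectivity %in% c(6L, 18L, 26L))
  structure(list(E = E, H = H, dh = dh, n_steps = as.integer(n_steps),
                 connectivity = as.integer(connectivity)),
            class = "tfce_params")
}

#' Build a GLM design for the responder vs non-responder contrast
#'
#' Columns: intercept, group indicator (non-responder = 1), then
#' mean-centered covariates. The returned contrast selects the group
#' column.
#'
#' @param group Character/factor with values `"responder"` /
#'   `"non-responder"`.
#' @param covariates Optional data.frame/matrix of numeric covariates
#'   (e.g. age, TIV).
#' @return List with `design` (n x p matrix) and `contrast` (length p).
#' @export
glm_design <- function(group, covariates = NULL) {
  g <- as.character(group)
  if (!all(g %in% c("responder", "non-responder")))
    stop("group must contain only responder/non-responder")
  X <- cbind(intercept = 1, group = as.numeric(g == "non-responder"))
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    cv <- sweep(cv, 2, colMeans(cv))
    colnames(cv) <- colnames(covariates)
    X <- cbind(X, cv)
  }
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  contrast <- as.numeric(colnames(X) == "group")
  list(design = X, contrast = contrast)
}

#' Voxelwise GLM t-statistic map
#'
#' Per-voxel OLS t statistic for a single contrast, df = n - rank(design).
#' Voxels with zero residual variance get t = 0.
#'
#' @param Y n x voxels matrix (rows match design rows).
#' @param design n x p design matrix of full column rank.
#' @param contrast Length-p contrast vector.
#' @return Numeric vector of t values (one per voxel); attribute `df`.
#' @export
glm_tstat_map <- function(Y, design, contrast) {
  X <- as.matrix(design)
  if (nrow(Y) != nrow(X)) stop("Y rows must match design rows")
  r <- qr(X)$rank
  if (r < ncol(X)) stop("design matrix is rank deficient")
  df <- nrow(X) - r
  if (df <= 0) stop("no residual degrees of freedom")
  XtXinv <- chol2inv(chol(crossprod(X)))
  beta <- XtXinv %*% crossprod(X, Y)
  res <- Y - X %*% beta
  s2 <- colSums(res^2) / df
  # voxels fitted exactly (up to floating point) have no residual
  # information: their t is defined as 0
  s2[s2 <= 1e-24 * pmax(colMeans(Y^2), .Machine$double.xmin)] <- 0
  cc <- drop(crossprod(contrast, XtXinv %*% contrast))
  num <- drop(crossprod(contrast, beta))
  se <- sqrt(cc * s2)
  tv <- ifelse(se > 0, num / se, 0)
  attr(tv, "df") <- df
  tv
}

#' Threshold-free cluster enhancement
#'
#' For each voxel, sums `extent(h)^E * h^H * dh` over thresholds
#' `h = dh, 2dh, ...` where `extent(h)` is the size of the connected
#' suprathreshold component containing the voxel at height h. Only the
#' positive tail is enhanced; see [tfce_two_tailed()] for the two-tailed
#' rule.
#'
#' @param stat_map Numeric vector (in-mask values) or 3D array.
#' @param mask Logical 3D array.
#' @param params [tfce_params()].
#' @return Vector of enhanced values for in-mask voxels.
#' @export
tfce <- function(stat_map, mask, params = tfce_params()) {
  if (!any(mask)) stop("empty mask")
  full <- if (is.array(stat_map) && length(dim(stat_map)) == 3) {
    stat_map * mask
  } else {
    unflatten(as.numeric(stat_map), mask)
  }
  out <- tfce_cpp(as.numeric(full), dim(mask), params$E, params$H,
                  ifelse(is.null(params$dh), -1, params$dh),
                  params$n_steps, params$connectivity)
  out[as.vector(mask)]
}

#' Two-tailed TFCE
#'
#' Enhances the positive and the negated map separately and takes the
#' voxelwise maximum — the two-tailed rule applied identically to observed
#' and permuted data, so no post-hoc doubling of p values is needed.
#'
#' @inheritParams tfce
#' @return Vector of enhanced values for in-mask voxels.
#' @export
tfce_two_tailed <- function(stat_map, mask, params = tfce_params()) {
  pos <- tfce(stat_map, mask, params)
  neg <- tfce(-if (is.array(stat_map)) stat_map else as.numeric(stat_map),
              mask, params)
  pmax(pos, neg)
}

#' Permutation-based FWE-corrected inference pooled across networks
#'
#' Voxelwise group comparison with covariates for every family (network)
#' of maps, TFCE enhancement, and family-wise error control by the
#' permutation distribution of the maximum enhanced statistic over all
#' voxels of all families jointly. Covariates are respected by
#' Freedman-Lane residual permutation: the reduced (nuisance-only) model
#' is fitted, its residuals are permuted, the nuisance fit is added back
#' and the full model is refitted.
#'
#' @param maps_by_family List of n x voxels matrices (one per network; a
#'   single-element list for e.g. a gray-matter analysis).
#' @param design n x p design matrix (see [glm_design()]).
#' @param contrast Length-p contrast vector.
#' @param mask Logical 3D array shared by all families.
#' @param params [tfce_params()].
#' @param n_perm Number of random permutations (>= 99); the observed data
#'   count as one additional member of the null, so the minimum attainable
#'   p is `1/(n_perm+1)`.
#' @param seed Integer seed (required).
#' @param method `"freedman_lane"` (default) or `"labels"` (simple
#'   permutation of design rows).
#' @return `fwe_perm_result`: per-family observed enhanced maps and
#'   t-maps, `null_max` (length n_perm), per-family voxelwise FWE p maps,
#'   `min_p` per family, df, seed.
#' @export
permutation_fwe <- function(maps_by_family, design, contrast, mask,
                            params = tfce_params(), n_perm = 499L,
                            seed, method = c("freedman_lane", "labels")) {
  method <- match.arg(method)
  if (missing(seed)) stop("seed is required")
  if (n_perm < 99) stop("n_perm must be >= 99")
  if (!is.list(maps_by_family)) maps_by_family <- list(maps_by_family)
  X <- as.matrix(design)
  n <- nrow(X)
  if (n <= ncol(X)) stop("too few subjects for the design")
  for (f in maps_by_family)
    if (nrow(f) != n) stop("family rows must match design rows")
  contrast <- as.numeric(contrast)
  nuis <- which(contrast == 0)
  Z <- X[, nuis, drop = FALSE]
  Hz <- Z %*% chol2inv(chol(crossprod(Z))) %*% t(Z)
  Rz <- diag(n) - Hz

  enhance_all <- function(Ylist) {
    lapply(Ylist, function(Y) {
      tv <- glm_tstat_map(Y, X, contrast)
      tfce_two_tailed(as.numeric(tv), mask, params)
    })
  }

  obs_t <- lapply(maps_by_family, function(Y) glm_tstat_map(Y, X, contrast))
  obs_enh <- enhance_all(maps_by_family)

  red <- lapply(maps_by_family, function(Y)
    list(fit = Hz %*% Y, res = Rz %*% Y))
  set.seed(seed)
  null_max <- numeric(n_perm)
  for (j in seq_len(n_perm)) {
    perm <- sample.int(n)
    Yp <- if (method == "freedman_lane") {
      lapply(red, function(r) r$fit + r$res[perm, , drop = FALSE])
    } else {
      lapply(maps_by_family, function(Y) Y[perm, , drop = FALSE])
    }
    enh <- enhance_all(Yp)
    null_max[j] <- max(vapply(enh, max, numeric(1)))
  }
  p_maps <- lapply(obs_enh, function(e)
    vapply(e, function(v) (1 + sum(null_max >= v)) / (n_perm + 1), numeric(1)))
  structure(list(tstat = obs_t, enhanced = obs_enh, p_fwe = p_maps,
                 null_max = null_max,
                 min_p = vapply(p_maps, min, numeric(1)),
                 df = attr(obs_t[[1]], "df"),
                 n_perm = n_perm, seed = seed, method = method,
                 params = params, mask = mask),
            class = "fwe_perm_result")
}

#' @export
print.fwe_perm_result <- function(x, ...) {
  cat("fwe_perm_result:", length(x$enhanced), "families,", x$n_perm,
      "permutations (", x$method, ")\n")
  cat("  min FWE p per family:",
      paste(signif(x$min_p, 3), collapse = ", "), "\n")
  invisible(x)
}
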