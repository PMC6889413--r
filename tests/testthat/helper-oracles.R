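# Shared fixtures and independent oracles, built in code at test time.

# Lean GPC grid used where many fits are needed; the scientific content
# of those tests does not depend on the grid resolution.
gpc_lean <- function() {
  gpc_config(sigma_f_grid = 10^seq(-1, 1, length.out = 3),
             sigma_b_grid = 10^seq(-1, 1, length.out = 3))
}

# Small desk-scale cohort settings used throughout the suite.
small_cohort_config <- function(seed, effect_size = 0, n_responders = 12,
                                n_nonresponders = 10, n_controls = 2,
                                grid_dims = c(10, 10, 10),
                                n_timepoints = 40, n_networks = 4,
                                noise_sd = 1) {
  sim_config(grid_dims = grid_dims, n_timepoints = n_timepoints,
             n_networks = n_networks, n_controls = n_controls,
             n_responders = n_responders, n_nonresponders = n_nonresponders,
             blob_fwhm = 2, effect_size = effect_size, noise_sd = noise_sd,
             seed = seed)
}

# Simulate a cohort and dual-regress the patients against the z-scored
# ground-truth networks, returning per-network feature matrices.
cohort_network_features <- function(seed, effect_size = 0, ...) {
  cfg <- small_cohort_config(seed, effect_size = effect_size, ...)
  co <- simulate_cohort(cfg)
  zm <- t(scale(t(co$ground_truth$networks$maps)))
  pat <- which(co$clinical$group != "control")
  dr <- run_dual_regression(co$scans[pat], zm, co$mask,
                            subject_ids = co$clinical$subject_id[pat])
  list(cohort = co, dr = dr,
       families = lapply(seq_len(cfg$n_networks), function(k) dr$betas[, k, ]),
       y = co$clinical$group[pat],
       age = co$clinical$age[pat],
       mask = co$mask,
       effect_flat = as.vector(co$ground_truth$effect_mask))
}

# Brute-force TFCE: naive per-threshold connected-component labelling,
# summed over the explicit threshold set h = dh, 2dh, ..., nsteps*dh.
# Independent of the incremental-merge implementation under test (shares
# only the component labeller, which is itself checked against an R
# flood fill).
tfce_brute <- function(stat, mask, E = 0.5, H = 2, nsteps = 100, conn = 26,
                       dh = NULL) {
  st <- stat * mask
  mx <- max(st)
  out <- array(0, dim = dim(mask))
  if (mx <= 0) return(out[as.vector(mask)])
  if (is.null(dh)) dh <- mx / nsteps
  K <- floor(mx / dh + 1e-9)
  for (k in seq_len(K)) {
    h <- k * dh
    # the tiny slack keeps a voxel exactly at a threshold (e.g. the max
    # at h = nsteps*dh) suprathreshold despite floating-point rounding
    labs <- array(rsnpredict:::label_components_cpp(as.vector(st >= h - 1e-12),
                                                    dim(mask), conn),
                  dim = dim(mask))
    sz <- tabulate(labs[labs > 0])
    sel <- labs > 0
    out[sel] <- out[sel] + sz[labs[sel]]^E * h^H * dh
  }
  out[as.vector(mask)]
}

# Pure-R flood fill (6/18/26), the oracle for the C++ labeller.
label_brute <- function(bin, conn = 26) {
  dims <- dim(bin)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  s <- rowSums(abs(offs))
  offs <- offs[s > 0 & s <= switch(as.character(conn), "6" = 1, "18" = 2, "26" = 3), ,
               drop = FALSE]
  lab <- array(0L, dims)
  nxt <- 0L
  for (v in which(bin)) {
    if (lab[v] > 0) next
    nxt <- nxt + 1L
    queue <- v
    lab[v] <- nxt
    while (length(queue)) {
      u <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ijk <- arrayInd(u, dims)
      for (q in seq_len(nrow(offs))) {
        w <- ijk + offs[q, ]
        if (any(w < 1) || any(w > dims)) next
        wi <- w[1] + dims[1] * ((w[2] - 1) + dims[2] * (w[3] - 1))
        if (bin[wi] && lab[wi] == 0) {
          lab[wi] <- nxt
          queue <- c(queue, wi)
        }
      }
    }
  }
  lab
}

# Dense-quadrature oracle for the GPC predictive: integrates the exact
# posterior over the whitened latent space (trapezoid weights implicit in
# the uniform grid). Shares nothing with the Laplace path under test.
gpc_quadrature_predict <- function(Xs, y, Xns, sf, sb, npts = 31) {
  p <- ncol(Xs)
  n <- nrow(Xs)
  K <- sf^2 * tcrossprod(Xs) / p + sb^2 + diag(1e-8, n)
  Lk <- t(chol(K))
  Ki <- chol2inv(chol(K))
  ks <- sf^2 * tcrossprod(Xns, Xs) / p + sb^2
  kss <- sf^2 * rowSums(Xns^2) / p + sb^2
  U <- as.matrix(expand.grid(rep(list(seq(-6, 6, length.out = npts)), n)))
  Fm <- U %*% t(Lk)
  lp <- -0.5 * rowSums(U^2)
  for (i in seq_len(n)) lp <- lp + pnorm(y[i] * Fm[, i], log.p = TRUE)
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  A <- ks %*% Ki
  mu <- A %*% t(Fm)
  s2 <- pmax(kss - rowSums(A * ks), 0)
  drop(pnorm(mu / sqrt(1 + s2)) %*% w)
}
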