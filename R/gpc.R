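#' GPC configuration
#'
#' Linear kernel `k(x, x') = sigma_f^2 (x . x')/p + sigma_b^2` with
#' hyperparameters selected by maximizing the Laplace approximate log
#' marginal likelihood over a fixed log-spaced grid — a robust choice at
#' the tens-of-subjects scale this classifier targets. An RBF kernel is
#' available behind the same interface.
#'
#' @param kernel `"linear"` (default) or `"rbf"`.
#' @param sigma_f_grid,sigma_b_grid Candidate signal / bias standard
#'   deviations (default 5 log-spaced points in `[0.1, 10]`).
#' @param rbf_lengthscale Lengthscale for the RBF kernel (on standardized
#'   features, scaled by `sqrt(p)`).
#' @param tol Newton convergence tolerance on the Laplace objective.
#' @param max_iter Maximum Newton iterations.
#' @return `gpc_config` object.
#' @export
gpc_config <- function(kernel = c("linear", "rbf"),
                       sigma_f_grid = 10^seq(-1, 1, length.out = 5),
                       sigma_b_grid = 10^seq(-1, 1, length.out = 5),
                       rbf_lengthscale = 1,
                       tol = 1e-6, max_iter = 100L) {
  kernel <- match.arg(kernel)
  stopifnot(all(sigma_f_grid > 0), all(sigma_b_grid > 0), tol > 0,
            max_iter >= 1)
  structure(list(kernel = kernel, sigma_f_grid = sigma_f_grid,
                 sigma_b_grid = sigma_b_grid,
                 rbf_lengthscale = rbf_lengthscale,
                 tol = tol, max_iter = as.integer(max_iter)),
            class = "gpc_config")
}

base_kernel <- function(X1, X2, config) {
  p <- ncol(X1)
  if (config$kernel == "linear") {
    tcrossprod(X1, X2) / p
  } else {
    d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
    exp(-pmax(d2, 0) / (2 * config$rbf_lengthscale^2 * p))
  }
}

#' Fit a binary Gaussian process classifier
#'
#' Probit-likelihood GP classification with a Laplace approximation to the
#' latent posterior (Newton iteration to the mode) — fitting is
#' deterministic. Features are standardized internally using training
#' statistics only; constant features are centered to zero and contribute
#' nothing.
#'
#' @param X n x p numeric feature matrix.
#' @param y Labels in `{-1, +1}` (numeric), or a 2-level factor whose
#'   *second* level is coded +1.
#' @param config A [gpc_config()].
#' @return A `gpc_model` with the selected hyperparameters, latent mode,
#'   likelihood gradient and curvature at the mode, standardization
#'   statistics, and the evidence grid.
#' @export
fit_gpc <- function(X, y, config = gpc_config()) {
  X <- as.matrix(X)
  if (is.factor(y)) y <- ifelse(y == levels(y)[2], 1, -1)
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) stop("y must be coded -1/+1")
  if (length(unique(y)) < 2) stop("both classes must be present in y")
  if (any(!is.finite(X))) stop("non-finite feature values")
  if (nrow(X) != length(y)) stop("X rows must match length(y)")
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  K0 <- base_kernel(Xs, Xs, config)
  fit <- gpc_grid_cpp(K0, y, config$sigma_f_grid^2, config$sigma_b_grid^2,
                      config$tol, config$max_iter)
  if (!fit$converged)
    warning("GPC Laplace Newton iteration did not converge at the selected ",
            "hyperparameters")
  structure(list(sigma_f = sqrt(fit$sf2), sigma_b = sqrt(fit$sb2),
                 f_hat = drop(fit$f_hat), grad = drop(fit$grad),
                 W = drop(fit$W),
                 log_marginal = fit$log_marginal,
                 log_marginal_grid = fit$log_marginal_grid,
                 converged = fit$converged,
                 X_train = Xs, y = y, mu = mu, sd = sdv,
                 config = config),
            class = "gpc_model")
}

#' Predictive class probabilities from a fitted GPC
#'
#' Probability of the +1 class for new feature rows, via the
#' probit-Gaussian convolution of the approximate latent predictive
#' distribution. Values are strictly inside (0, 1).
#'
#' @param model A [fit_gpc()] result.
#' @param X_new m x p matrix on the original feature scale (standardized
#'   internally with the training statistics).
#' @return Numeric vector of length m.
#' @export
predict_proba <- function(model, X_new) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(model$mu))
    stop("feature count mismatch: model has ", length(model$mu),
         ", X_new has ", ncol(X_new))
  Xn <- sweep(sweep(X_new, 2, model$mu), 2, model$sd, "/")
  cfg <- model$config
  sf2 <- model$sigma_f^2
  sb2 <- model$sigma_b^2
  Ks <- sf2 * base_kernel(Xn, model$X_train, cfg) + sb2
  kss <- if (cfg$kernel == "linear") {
    sf2 * rowSums(Xn^2) / ncol(Xn) + sb2
  } else {
    rep(sf2 + sb2, nrow(Xn))
  }
  n <- length(model$y)
  sW <- sqrt(model$W)
  B <- diag(n) + (sW %o% sW) * (sf2 * base_kernel(model$X_train,
                                                  model$X_train, cfg) + sb2)
  L <- t(chol(B))                        # lower
  fs <- drop(Ks %*% model$grad)
  v <- forwardsolve(L, sW * t(Ks))
  vs <- pmax(kss - colSums(v^2), 0)
  pnorm(fs / sqrt(1 + vs))
}

#' @export
print.gpc_model <- function(x, ...) {
  cat("gpc_model:", length(x$y), "training points,", length(x$mu),
      "features; kernel", x$config$kernel,
      sprintf("(sigma_f = %.3g, sigma_b = %.3g), log evidence %.3f\n",
              x$sigma_f, x$sigma_b, x$log_marginal))
  invisible(x)
}
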