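#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// log of the standard normal CDF, stable in the far left tail
static inline double log_ndtr(double z) {
  if (z > -37.0) return std::log(0.5 * std::erfc(-z * M_SQRT1_2));
  double z2 = z * z;
  return -0.5 * z2 - 0.918938533204672742 - std::log(-z) +
         std::log1p(-1.0 / z2 + 3.0 / (z2 * z2));
}

// hazard phi(z)/Phi(z)
static inline double norm_hazard(double z) {
  double logphi = -0.5 * z * z - 0.918938533204672742;
  return std::exp(logphi - log_ndtr(z));
}

// derivatives of the probit log likelihood log Phi(y*f)
static void probit_derivs(const arma::vec& f, const arma::vec& y,
                          arma::vec& grad, arma::vec& W, double& ll) {
  const arma::uword n = f.n_elem;
  ll = 0.0;
  for (arma::uword i = 0; i < n; ++i) {
    double z = y(i) * f(i);
    double h = norm_hazard(z);
    grad(i) = y(i) * h;
    W(i) = h * (h + z);           // -d2/df2 log Phi(yf), >= 0
    if (W(i) < 0.0) W(i) = 0.0;   // numeric guard
    ll += log_ndtr(z);
  }
}

// Laplace approximation for probit-likelihood GP binary classification
// (Newton iteration to the posterior mode; Rasmussen-Williams style).
static bool laplace_mode(const arma::mat& K, const arma::vec& y,
                         double tol, int maxit,
                         arma::vec& f, arma::vec& grad, arma::vec& W,
                         double& logZ) {
  const arma::uword n = y.n_elem;
  f.zeros(n);
  grad.set_size(n);
  W.set_size(n);
  arma::vec a(n, arma::fill::zeros);
  double ll = 0.0, obj = -arma::datum::inf;
  bool conv = false;
  arma::mat I = arma::eye(n, n);
  for (int it = 0; it < maxit; ++it) {
    probit_derivs(f, y, grad, W, ll);
    arma::vec sW = arma::sqrt(W);
    arma::mat B = I + (sW * sW.t()) % K;
    arma::mat L = arma::chol(B, "lower");
    arma::vec b = W % f + grad;
    arma::vec c = arma::solve(arma::trimatl(L), sW % (K * b));
    a = b - sW % arma::solve(arma::trimatu(L.t()), c);
    f = K * a;
    // objective at the new f
    double ll_new = 0.0;
    for (arma::uword i = 0; i < n; ++i) ll_new += log_ndtr(y(i) * f(i));
    double obj_new = -0.5 * arma::dot(a, f) + ll_new;
    if (std::abs(obj_new - obj) < tol) {
      obj = obj_new;
      conv = true;
      break;
    }
    obj = obj_new;
  }
  // final curvature at the mode for the evidence
  probit_derivs(f, y, grad, W, ll);
  arma::vec sW = arma::sqrt(W);
  arma::mat B = I + (sW * sW.t()) % K;
  arma::mat L = arma::chol(B, "lower");
  logZ = -0.5 * arma::dot(a, f) + ll - arma::accu(arma::log(L.diag()));
  return conv;
}

// Fit over a grid of (sigma_f^2, sigma_b^2) on a shared base kernel K0
// (K = sf2*K0 + sb2). Returns the model at the evidence-maximising pair;
// ties keep the earlier grid entry (sb2 varying fastest).
// [[Rcpp::export]]
List gpc_grid_cpp(const arma::mat& K0, const arma::vec& y,
                  const arma::vec& sf2_grid, const arma::vec& sb2_grid,
                  double tol, int maxit) {
  const arma::uword nf = sf2_grid.n_elem, nb = sb2_grid.n_elem;
  arma::mat logZ_grid(nf, nb);
  logZ_grid.fill(-arma::datum::inf);
  double best = -arma::datum::inf;
  arma::uword bi = 0, bj = 0;
  arma::vec best_f, best_grad, best_W;
  bool best_conv = false;
  arma::vec f, grad, W;
  for (arma::uword i = 0; i < nf; ++i) {
    for (arma::uword j = 0; j < nb; ++j) {
      arma::mat K = sf2_grid(i) * K0 + sb2_grid(j);
      double lz;
      bool conv = laplace_mode(K, y, tol, maxit, f, grad, W, lz);
      logZ_grid(i, j) = lz;
      if (lz > best) {
        best = lz;
        bi = i; bj = j;
        best_f = f; best_grad = grad; best_W = W;
        best_conv = conv;
      }
    }
  }
  return List::create(
    _["sf2"] = sf2_grid(bi), _["sb2"] = sb2_grid(bj),
    _["f_hat"] = best_f, _["grad"] = best_grad, _["W"] = best_W,
    _["log_marginal"] = best, _["log_marginal_grid"] = logZ_grid,
    _["converged"] = best_conv);
}

// Single-kernel fit (used by tests and by models with fixed hyperparameters).
// [[Rcpp::export]]
List gpc_laplace_cpp(const arma::mat& K, const arma::vec& y,
                     double tol, int maxit) {
  arma::vec f, grad, W;
  double lz;
  bool conv = laplace_mode(K, y, tol, maxit, f, grad, W, lz);
  return List::create(_["f_hat"] = f, _["grad"] = grad, _["W"] = W,
                      _["log_marginal"] = lz, _["converged"] = conv);
}
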