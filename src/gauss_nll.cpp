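// Batched multivariate-Gaussian negative log-likelihood for the
// time-varying density network. Each row of (mu, l, d) parameterises one
// covariance Sigma = L L' + diag(exp(d) + eps), with l packed row-wise over
// the lower triangle of L (i >= j). k is small (<= 8) so per-row dense
// factorisations are cheap.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void unpack_L(const arma::rowvec &l, arma::mat &L, int k) {
  L.zeros(k, k);
  int idx = 0;
  for (int i = 0; i < k; ++i)
    for (int j = 0; j <= i; ++j)
      L(i, j) = l(idx++);
}

// Per-row NLL: 0.5 * (k log 2pi + log|Sigma| + r' Sigma^-1 r), r = x - mu.
// [[Rcpp::export]]
arma::vec gauss_nll_batch(const arma::mat &mu, const arma::mat &l,
                          const arma::mat &d, const arma::mat &x,
                          double eps) {
  const int n = mu.n_rows, k = mu.n_cols;
  arma::vec out(n);
  arma::mat L(k, k), Sigma(k, k), C(k, k);
  const double c0 = k * std::log(2.0 * M_PI);
  for (int r = 0; r < n; ++r) {
    unpack_L(l.row(r), L, k);
    Sigma = L * L.t();
    Sigma.diag() += arma::exp(d.row(r).t()) + eps;
    if (!arma::chol(C, Sigma, "lower"))
      stop("covariance not positive definite at row %d", r + 1);
    arma::vec res = x.row(r).t() - mu.row(r).t();
    arma::vec w = arma::solve(arma::trimatl(C), res);
    double logdet = 2.0 * arma::accu(arma::log(C.diag()));
    out(r) = 0.5 * (c0 + logdet + arma::dot(w, w));
  }
  return out;
}

// Mean NLL over the batch plus gradients w.r.t. mu, l, d (also averaged).
// [[Rcpp::export]]
List gauss_nll_grad(const arma::mat &mu, const arma::mat &l,
                    const arma::mat &d, const arma::mat &x, double eps) {
  const int n = mu.n_rows, k = mu.n_cols, q = l.n_cols;
  arma::mat dmu(n, k), dl(n, q), dd(n, k);
  arma::mat L(k, k), Sigma(k, k), C(k, k), Sinv(k, k), G(k, k), dL(k, k);
  const double c0 = k * std::log(2.0 * M_PI);
  double total = 0.0;
  for (int r = 0; r < n; ++r) {
    unpack_L(l.row(r), L, k);
    arma::vec ed = arma::exp(d.row(r).t());
    Sigma = L * L.t();
    Sigma.diag() += ed + eps;
    if (!arma::chol(C, Sigma, "lower"))
      stop("covariance not positive definite at row %d", r + 1);
    arma::mat Ci = arma::inv(arma::trimatl(C));
    Sinv = Ci.t() * Ci;
    arma::vec res = x.row(r).t() - mu.row(r).t();
    arma::vec alpha = Sinv * res;
    double logdet = 2.0 * arma::accu(arma::log(C.diag()));
    total += 0.5 * (c0 + logdet + arma::dot(res, alpha));
    // dNLL/dSigma = 0.5 (Sinv - alpha alpha')
    G = 0.5 * (Sinv - alpha * alpha.t());
    dmu.row(r) = (-alpha).t();
    dL = 2.0 * G * L; // Sigma symmetric in L L'
    int idx = 0;
    for (int i = 0; i < k; ++i)
      for (int j = 0; j <= i; ++j)
        dl(r, idx++) = dL(i, j);
    for (int i = 0; i < k; ++i)
      dd(r, i) = G(i, i) * ed(i);
  }
  double inv_n = 1.0 / n;
  return List::create(_["nll"] = total * inv_n, _["dmu"] = dmu * inv_n,
                      _["dl"] = dl * inv_n, _["dd"] = dd * inv_n);
}
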