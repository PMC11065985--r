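#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// EM for Gaussian mixtures under six covariance parameterizations, named by
// the E/V convention: 1 EII (spherical, equal), 2 VII (spherical, varying),
// 3 EEI (diagonal, equal), 4 VVI (diagonal, varying), 5 EEE (full, shared),
// 6 VVV (full, varying).
//
// resp: n x k initial responsibilities (from k-means++-style seeding in R).
// Returns weights, means, covariances, log-likelihood, iterations, and
// whether a ridge had to be applied to keep covariances positive definite.
// [[Rcpp::export]]
List cpp_gmm_em(const arma::mat& X, arma::mat resp, int model, int max_iter,
                double tol, double ridge_frac) {
  const int n = X.n_rows, d = X.n_cols;
  const int k = resp.n_cols;
  arma::vec w(k);
  arma::mat mu(k, d);
  arma::cube sig(d, d, k);
  double ll = -arma::datum::inf;
  bool ridged = false;
  int it = 0;
  const double ln2pi = std::log(2.0 * arma::datum::pi);
  // data scale for ridge regularization and degeneracy detection
  arma::rowvec gmean = arma::mean(X, 0);
  arma::mat Xg = X.each_row() - gmean;
  double data_var = arma::trace(Xg.t() * Xg) / ((double)n * d);
  if (data_var <= 0) data_var = 1.0;

  for (it = 1; it <= max_iter; it++) {
    // ---- M step ----
    arma::rowvec Nk = arma::sum(resp, 0);
    Nk = arma::clamp(Nk, 1e-300, arma::datum::inf);
    w = Nk.t() / (double)n;
    for (int j = 0; j < k; j++)
      mu.row(j) = (resp.col(j).t() * X) / Nk(j);
    arma::cube S(d, d, k);
    for (int j = 0; j < k; j++) {
      arma::mat Xc = X.each_row() - mu.row(j);
      arma::mat W = Xc.each_col() % resp.col(j);
      S.slice(j) = (W.t() * Xc) / Nk(j);
    }
    arma::mat pooled(d, d, arma::fill::zeros);
    for (int j = 0; j < k; j++) pooled += (Nk(j) / (double)n) * S.slice(j);
    switch (model) {
      case 1: {  // EII
        double s2 = arma::trace(pooled) / d;
        for (int j = 0; j < k; j++) sig.slice(j) = s2 * arma::eye(d, d);
        break;
      }
      case 2: {  // VII
        for (int j = 0; j < k; j++)
          sig.slice(j) = (arma::trace(S.slice(j)) / d) * arma::eye(d, d);
        break;
      }
      case 3: {  // EEI
        arma::vec dg = pooled.diag();
        for (int j = 0; j < k; j++) sig.slice(j) = arma::diagmat(dg);
        break;
      }
      case 4: {  // VVI
        for (int j = 0; j < k; j++)
          sig.slice(j) = arma::diagmat(S.slice(j).diag());
        break;
      }
      case 5: {  // EEE
        for (int j = 0; j < k; j++) sig.slice(j) = pooled;
        break;
      }
      default: {  // VVV
        for (int j = 0; j < k; j++) sig.slice(j) = S.slice(j);
      }
    }
    // ridge degenerate covariances (relative to the data scale)
    for (int j = 0; j < k; j++) {
      arma::mat C = sig.slice(j);
      arma::mat R;
      if (!arma::chol(R, C) || C.diag().min() < 1e-10 * data_var) {
        sig.slice(j) = C + (ridge_frac * data_var) * arma::eye(d, d);
        ridged = true;
      }
    }

    // ---- E step + log-likelihood ----
    arma::mat logp(n, k);
    for (int j = 0; j < k; j++) {
      arma::mat R = arma::chol(sig.slice(j));
      double logdet = 2.0 * arma::sum(arma::log(R.diag()));
      arma::mat Xc = X.each_row() - mu.row(j);
      // Mahalanobis via triangular solve
      arma::mat Z = arma::solve(arma::trimatl(R.t()), Xc.t());
      arma::rowvec q = arma::sum(Z % Z, 0);
      logp.col(j) = (-0.5 * (d * ln2pi + logdet) + std::log(w(j))) -
                    0.5 * q.t();
    }
    arma::vec mx = arma::max(logp, 1);
    arma::vec lse = mx + arma::log(arma::sum(arma::exp(logp.each_col() - mx), 1));
    double ll_new = arma::sum(lse);
    resp = arma::exp(logp.each_col() - lse);
    double rel = std::abs(ll_new - ll) / (std::abs(ll_new) + 1e-300);
    ll = ll_new;
    if (it > 1 && rel < tol) break;
  }
  // a component supported by fewer than d + 1 observations marks the
  // solution as a likelihood spike, not a genuine cluster
  double n_min = arma::min(arma::sum(resp, 0));
  return List::create(_["weights"] = w, _["means"] = mu, _["cov"] = sig,
                      _["loglik"] = ll, _["iter"] = it,
                      _["ridged"] = ridged, _["n_min"] = n_min);
}
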