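// Truncated Dirichlet-process Gaussian mixture fitted by mean-field
// variational inference (stick-breaking representation, full covariances,
// Gaussian-Wishart component priors).  The update scheme is the standard
// variational Bayes recursion; priors follow the common defaults
// (weight concentration gamma0, mean precision beta0, df nu0 = d,
// covariance prior Psi0 = empirical covariance of the data).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static double digamma_(double x) { return R::digamma(x); }

// [[Rcpp::export(name = ".cpp_dpgmm")]]
List cpp_dpgmm(const arma::mat& X,       // n x d data
               arma::mat resp,           // n x K initial responsibilities
               double gamma0,            // stick concentration prior
               double beta0,             // mean precision prior
               const arma::rowvec& m0,   // mean prior (1 x d)
               double nu0,               // Wishart degrees of freedom prior
               const arma::mat& Psi0,    // d x d covariance prior (scale)
               int max_iter, double tol) {
  const arma::uword n = X.n_rows, d = X.n_cols;
  const arma::uword K = resp.n_cols;
  const double ln2pi = std::log(2.0 * M_PI);

  arma::vec Nk(K), beta(K), nu(K), a(K), b(K);
  arma::mat means(K, d);
  arma::cube Psi(d, d, K);
  arma::vec Elogdet(K), Elogpi(K);
  arma::mat logprob(n, K);
  arma::uvec empty(K, arma::fill::zeros);
  arma::vec prior_col;
  bool prior_col_ready = false;
  double prev_crit = -arma::datum::inf;
  int iter = 0;
  bool converged = false;
  double crit = prev_crit;

  for (iter = 1; iter <= max_iter; ++iter) {
    // ---- M-step: update variational posteriors from responsibilities
    Nk = arma::sum(resp, 0).t();                    // K
    // stick-breaking Beta posteriors: a_k = 1 + N_k, b_k = gamma0 + sum_{j>k} N_j
    double tail = 0.0;
    for (arma::uword k = K; k-- > 0; ) {
      a(k) = 1.0 + Nk(k);
      b(k) = gamma0 + tail;
      tail += Nk(k);
    }
    double acc = 0.0;                                // sum_{j<k} E[log(1-v_j)]
    for (arma::uword k = 0; k < K; ++k) {
      double dab = digamma_(a(k) + b(k));
      Elogpi(k) = digamma_(a(k)) - dab + acc;
      acc += digamma_(b(k)) - dab;
    }
    for (arma::uword k = 0; k < K; ++k) {
      double nk = Nk(k);
      if (nk < 1e-9) {           // effectively empty: posterior equals prior
        empty(k) = 1;
        beta(k) = beta0; nu(k) = nu0;
        means.row(k) = m0;
        Psi.slice(k) = Psi0;
        continue;
      }
      empty(k) = 0;
      beta(k) = beta0 + nk;
      nu(k) = nu0 + nk;
      arma::rowvec xbar = resp.col(k).t() * X / nk;
      means.row(k) = (beta0 * m0 + nk * xbar) / beta(k);
      // scatter around xbar, weighted by resp
      arma::mat Y = (X.each_row() - xbar).eval().each_col()
        % arma::sqrt(resp.col(k));
      arma::rowvec dm = xbar - m0;
      Psi.slice(k) = Psi0 + Y.t() * Y + (beta0 * nk / beta(k)) * (dm.t() * dm);
    }

    // ---- E-step: expected log joint per point and component.
    // Empty components all sit exactly at the prior, so their (identical)
    // column is computed once and shifted by the stick term.
    for (arma::uword k = 0; k < K; ++k) {
      if (empty(k) && prior_col_ready) {
        logprob.col(k) = Elogpi(k) + prior_col;
        continue;
      }
      arma::mat L;
      bool ok = arma::chol(L, Psi.slice(k), "lower");
      if (!ok) {
        arma::mat J = Psi.slice(k) + 1e-8 * arma::trace(Psi.slice(k)) / d *
          arma::eye(d, d);
        arma::chol(L, J, "lower");
      }
      double logdetPsi = 2.0 * arma::accu(arma::log(L.diag()));
      double eld = d * std::log(2.0) - logdetPsi;
      for (arma::uword i = 0; i < d; ++i)
        eld += digamma_(0.5 * (nu(k) - (double)i));
      Elogdet(k) = eld;
      arma::mat Xc = (X.each_row() - means.row(k)).t();   // d x n
      arma::mat Z = arma::solve(arma::trimatl(L), Xc);    // d x n
      arma::rowvec quad = arma::sum(arma::square(Z), 0);  // n
      arma::vec col = 0.5 * eld - 0.5 * d * ln2pi
        - 0.5 * (d / beta(k) + nu(k) * quad.t());
      logprob.col(k) = Elogpi(k) + col;
      if (empty(k)) { prior_col = col; prior_col_ready = true; }
    }
    arma::vec mx = arma::max(logprob, 1);
    arma::mat shifted = arma::exp(logprob.each_col() - mx);
    arma::vec norm = arma::sum(shifted, 1);
    resp = shifted.each_col() / norm;
    crit = arma::mean(arma::log(norm) + mx);   // mean log-normaliser
    if (iter > 1 && std::fabs(crit - prev_crit) < tol) { converged = true; break; }
    prev_crit = crit;
  }

  // expected mixing weights from the stick means, renormalised
  arma::vec Ev = a / (a + b);
  arma::vec wts(K);
  double rem = 1.0;
  for (arma::uword k = 0; k < K; ++k) { wts(k) = Ev(k) * rem; rem *= (1.0 - Ev(k)); }
  wts /= arma::accu(wts);

  arma::uvec labels = arma::index_max(resp, 1) + 1;
  return List::create(_["weights"] = wts, _["labels"] = labels,
                      _["means"] = means, _["n_iter"] = std::min(iter, max_iter),
                      _["converged"] = converged, _["criterion"] = crit);
}
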