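#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sigmoidal activation of the third-order neuron, odd-symmetric with a dead
// point at x = 0.  b is the half-response input; with the half-response rule
// b = log(1/99)/alpha + 0.75 the output reaches 0.99*A0 at x = 0.75.
//
// All forms are written in terms of the logistic s = 1/(1+exp(-z)) so they
// stay finite for large |z| (exp(-z) may overflow to Inf; 1/Inf == 0).

static inline double logistic(double z) { return 1.0 / (1.0 + std::exp(-z)); }

static inline double act_sigmoid(double x, double alpha, double b, double A0) {
  if (x > 0.0)  return  A0 * logistic(alpha * (x - b));
  if (x < 0.0)  return -A0 * logistic(alpha * (-x - b));
  return 0.0;
}

// dF/dx: both branches reduce to A0*alpha*s*(1-s), always >= 0.
static inline double act_fx(double x, double alpha, double b, double A0) {
  if (x == 0.0) return 0.0;
  double s = logistic(alpha * (std::fabs(x) - b));
  return A0 * alpha * s * (1.0 - s);
}

// dF/dalpha holding b fixed (the printed derivative).  chain_b adds the
// dependence of b on alpha through the half-response rule,
// db/dalpha = log(99)/alpha^2, via dF/db = -sign(x) * A0*alpha*s*(1-s).
static inline double act_falpha(double x, double alpha, double b, double A0,
                                bool chain_b) {
  if (x == 0.0) return 0.0;
  double u = std::fabs(x) - b;
  double s = logistic(alpha * u);
  double core = A0 * s * (1.0 - s);
  double g = (x > 0.0 ? 1.0 : -1.0) * u * core;
  if (chain_b) {
    double dbda = std::log(99.0) / (alpha * alpha);
    g += (x > 0.0 ? -1.0 : 1.0) * alpha * core * dbda;
  }
  return g;
}

static inline double half_response(double alpha) {
  return std::log(1.0 / 99.0) / alpha + 0.75;
}

// [[Rcpp::export(name = ".cpp_sigmoid")]]
NumericVector cpp_sigmoid(NumericVector x, double alpha, double A0) {
  double b = half_response(alpha);
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = act_sigmoid(x[i], alpha, b, A0);
  return out;
}

// Weighted cost G = sum_m c_m (F(x_m) - yhat_m)^2 over one tuning curve.
// r: 3 x N matrix of transmedullary responses (v_i * E_i) at the curve's
// wavelengths, rows in (S, M, L) order; w length 3 in the same order.
// [[Rcpp::export(name = ".cpp_cost")]]
double cpp_cost(NumericMatrix r, NumericVector yhat, NumericVector cw,
                NumericVector w, double alpha, double A0) {
  double b = half_response(alpha);
  int N = r.ncol();
  double G = 0.0;
  for (int m = 0; m < N; ++m) {
    double x = w[0] * r(0, m) + w[1] * r(1, m) + w[2] * r(2, m);
    double e = act_sigmoid(x, alpha, b, A0) - yhat[m];
    G += cw[m] * e * e;
  }
  return G;
}

// Analytic gradients of the weighted cost w.r.t. (w1, w2, w3, alpha).
// [[Rcpp::export(name = ".cpp_gradients")]]
NumericVector cpp_gradients(NumericMatrix r, NumericVector yhat,
                            NumericVector cw, NumericVector w, double alpha,
                            double A0, bool chain_b) {
  double b = half_response(alpha);
  int N = r.ncol();
  NumericVector g(4);
  for (int m = 0; m < N; ++m) {
    double x = w[0] * r(0, m) + w[1] * r(1, m) + w[2] * r(2, m);
    double e = act_sigmoid(x, alpha, b, A0) - yhat[m];
    double fx = act_fx(x, alpha, b, A0);
    double fa = act_falpha(x, alpha, b, A0, chain_b);
    double common = 2.0 * cw[m] * e;
    g[0] += common * r(0, m) * fx;
    g[1] += common * r(1, m) * fx;
    g[2] += common * r(2, m) * fx;
    g[3] += common * fa;
  }
  return g;
}

// Plain gradient descent on (W, alpha) with best-iterate tracking.
// Termination: max_iter; ||W^{t+1}-W^t|| < eps; or a cost plateau
// (relative change < plateau_tol over plateau_window iterations).
// alpha is clamped to [alpha_min, inf).
// [[Rcpp::export(name = ".cpp_descent")]]
List cpp_descent(NumericMatrix r, NumericVector yhat, NumericVector cw,
                 NumericVector w0, double alpha0, double A0, double eta_w,
                 double eta_alpha, int max_iter, double eps, bool chain_b,
                 double plateau_tol, int plateau_window, double alpha_min,
                 int trace_every) {
  NumericVector w = clone(w0);
  double alpha = alpha0;
  double best_cost = cpp_cost(r, yhat, cw, w, alpha, A0);
  NumericVector best_w = clone(w);
  double best_alpha = alpha;
  double window_ref = best_cost;
  std::vector<double> trace;
  trace.push_back(best_cost);
  int iter = 0;
  std::string stop_reason = "max_iter";
  bool diverged = false;

  for (iter = 1; iter <= max_iter; ++iter) {
    NumericVector g = cpp_gradients(r, yhat, cw, w, alpha, A0, chain_b);
    double dnorm2 = 0.0;
    for (int i = 0; i < 3; ++i) {
      double step = eta_w * g[i];
      w[i] -= step;
      dnorm2 += step * step;
    }
    alpha -= eta_alpha * g[3];
    if (alpha < alpha_min) alpha = alpha_min;

    double cost = cpp_cost(r, yhat, cw, w, alpha, A0);
    if (!std::isfinite(cost)) { diverged = true; stop_reason = "diverged"; break; }
    if (cost < best_cost) {
      best_cost = cost;
      best_w = clone(w);
      best_alpha = alpha;
    }
    if (trace_every > 0 && iter % trace_every == 0) trace.push_back(cost);
    if (std::sqrt(dnorm2) < eps) { stop_reason = "eps"; break; }
    if (plateau_window > 0 && iter % plateau_window == 0) {
      double denom = std::fabs(window_ref) + 1e-300;
      if (std::fabs(window_ref - best_cost) / denom < plateau_tol) {
        stop_reason = "plateau";
        break;
      }
      window_ref = best_cost;
    }
  }
  if (iter > max_iter) iter = max_iter;

  return List::create(_["w"] = best_w, _["alpha"] = best_alpha,
                      _["cost"] = best_cost, _["n_iter"] = iter,
                      _["stop_reason"] = stop_reason,
                      _["diverged"] = diverged,
                      _["trace"] = NumericVector(trace.begin(), trace.end()));
}
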