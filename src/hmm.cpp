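#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gaussian emission density with a hard floor so that log() stays finite on
// noiseless test traces where the variance collapses to the configured floor.
static inline double gauss_dens(double x, double mean, double var) {
  double d = x - mean;
  double b = std::exp(-0.5 * d * d / var) / std::sqrt(2.0 * M_PI * var);
  return (b < 1e-300) ? 1e-300 : b;
}

// Baum-Welch EM for a K-state Gaussian-emission HMM on a single trace.
// Returns the parameters that produced the last evaluated log-likelihood,
// the full log-likelihood trace (one value per E-step) and convergence info.
// Convergence: relative log-likelihood change < tol, or maxit iterations.
// [[Rcpp::export]]
List hmm_em_cpp(NumericVector x, NumericVector mean0, NumericVector var0,
                NumericMatrix trans0, NumericVector init0,
                int maxit, double tol, double var_floor, bool fix_var) {
  const int T = x.size(), K = mean0.size();
  NumericVector mean = clone(mean0), var = clone(var0), init = clone(init0);
  NumericMatrix trans = clone(trans0);
  std::vector<double> ll_trace;
  ll_trace.reserve(64);

  NumericMatrix b(T, K), alpha(T, K), beta(T, K), gamma(T, K);
  NumericVector c(T);
  bool converged = false;
  double ll = R_NegInf, ll_old = R_NegInf;
  int iter = 0;

  // parameters as of the last E-step; updated just before each E-step
  NumericVector mean_at_ll(K), var_at_ll(K), init_at_ll(K);
  NumericMatrix trans_at_ll(K, K);

  for (iter = 1; iter <= maxit; ++iter) {
    // snapshot parameters entering this E-step
    for (int k = 0; k < K; ++k) {
      mean_at_ll[k] = mean[k];
      var_at_ll[k] = var[k];
      init_at_ll[k] = init[k];
      for (int j = 0; j < K; ++j) trans_at_ll(j, k) = trans(j, k);
    }

    // ---- E-step: scaled forward-backward ----
    for (int t = 0; t < T; ++t)
      for (int k = 0; k < K; ++k) b(t, k) = gauss_dens(x[t], mean[k], var[k]);

    double s = 0.0;
    for (int k = 0; k < K; ++k) { alpha(0, k) = init[k] * b(0, k); s += alpha(0, k); }
    if (s <= 0) s = 1e-300;
    c[0] = s; ll = std::log(s);
    for (int k = 0; k < K; ++k) alpha(0, k) /= s;
    for (int t = 1; t < T; ++t) {
      s = 0.0;
      for (int k = 0; k < K; ++k) {
        double a = 0.0;
        for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * trans(j, k);
        a *= b(t, k);
        alpha(t, k) = a; s += a;
      }
      if (s <= 0) s = 1e-300;
      c[t] = s; ll += std::log(s);
      for (int k = 0; k < K; ++k) alpha(t, k) /= s;
    }

    for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
    for (int t = T - 2; t >= 0; --t)
      for (int j = 0; j < K; ++j) {
        double bs = 0.0;
        for (int k = 0; k < K; ++k) bs += trans(j, k) * b(t + 1, k) * beta(t + 1, k);
        beta(t, j) = bs / c[t + 1];
      }

    for (int t = 0; t < T; ++t) {
      double g = 0.0;
      for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); g += gamma(t, k); }
      if (g <= 0) g = 1e-300;
      for (int k = 0; k < K; ++k) gamma(t, k) /= g;
    }

    ll_trace.push_back(ll);
    if (iter > 1) {
      double rel = std::fabs(ll - ll_old) / (std::fabs(ll_old) + 1e-12);
      if (rel < tol) { converged = true; break; }
    }
    ll_old = ll;

    // expected transition counts
    NumericMatrix xi(K, K);
    for (int t = 0; t < T - 1; ++t) {
      double z = 0.0;
      for (int j = 0; j < K; ++j)
        for (int k = 0; k < K; ++k)
          z += alpha(t, j) * trans(j, k) * b(t + 1, k) * beta(t + 1, k);
      if (z <= 0) z = 1e-300;
      for (int j = 0; j < K; ++j)
        for (int k = 0; k < K; ++k)
          xi(j, k) += alpha(t, j) * trans(j, k) * b(t + 1, k) * beta(t + 1, k) / z;
    }

    // ---- M-step ----
    for (int k = 0; k < K; ++k) init[k] = gamma(0, k);
    for (int j = 0; j < K; ++j) {
      double rs = 0.0;
      for (int k = 0; k < K; ++k) rs += xi(j, k);
      if (rs > 1e-12) {
        for (int k = 0; k < K; ++k) trans(j, k) = xi(j, k) / rs;
      } else {
        for (int k = 0; k < K; ++k) trans(j, k) = 1.0 / K;
      }
    }
    for (int k = 0; k < K; ++k) {
      double wsum = 0.0, msum = 0.0;
      for (int t = 0; t < T; ++t) { wsum += gamma(t, k); msum += gamma(t, k) * x[t]; }
      if (wsum > 1e-12) {
        double m = msum / wsum;
        mean[k] = m;
        if (!fix_var) {
          double vsum = 0.0;
          for (int t = 0; t < T; ++t) {
            double d = x[t] - m;
            vsum += gamma(t, k) * d * d;
          }
          var[k] = std::max(vsum / wsum, var_floor);
        }
      } else if (!fix_var) {
        var[k] = var_floor;  // starved state: keep its mean, floor its variance
      }
    }
  }
  if (iter > maxit) iter = maxit;

  return List::create(
    _["means"] = mean_at_ll, _["variances"] = var_at_ll,
    _["transition_matrix"] = trans_at_ll, _["initial_probs"] = init_at_ll,
    _["log_likelihood"] = ll, _["loglik_trace"] = NumericVector(ll_trace.begin(), ll_trace.end()),
    _["converged"] = converged, _["n_iterations"] = iter);
}

// Viterbi decoding in log space; ties broken toward the lower state index
// (strict '>' comparisons keep the first maximiser). Returns 1-based states.
// [[Rcpp::export]]
IntegerVector hmm_viterbi_cpp(NumericVector x, NumericVector mean, NumericVector var,
                              NumericMatrix trans, NumericVector init) {
  const int T = x.size(), K = mean.size();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  NumericMatrix ltr(K, K);
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k)
      ltr(j, k) = (trans(j, k) > 0) ? std::log(trans(j, k)) : -1e300;

  for (int k = 0; k < K; ++k) {
    double li = (init[k] > 0) ? std::log(init[k]) : -1e300;
    delta(0, k) = li + std::log(gauss_dens(x[0], mean[k], var[k]));
  }
  for (int t = 1; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      double best = delta(t - 1, 0) + ltr(0, k);
      int arg = 0;
      for (int j = 1; j < K; ++j) {
        double v = delta(t - 1, j) + ltr(j, k);
        if (v > best) { best = v; arg = j; }
      }
      delta(t, k) = best + std::log(gauss_dens(x[t], mean[k], var[k]));
      psi(t, k) = arg;
    }

  IntegerVector path(T);
  int arg = 0;
  double best = delta(T - 1, 0);
  for (int k = 1; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg + 1;
  for (int t = T - 2; t >= 0; --t) {
    arg = psi(t + 1, arg);
    path[t] = arg + 1;
  }
  return path;
}
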