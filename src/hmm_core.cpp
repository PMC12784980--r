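#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double logsumexp3(double a, double b, double c) {
  double m = a > b ? a : b;
  if (c > m) m = c;
  if (m == R_NegInf) return R_NegInf;
  return m + std::log(std::exp(a - m) + std::exp(b - m) + std::exp(c - m));
}

// Log-space forward-backward for one observation sequence of a 3-state HMM.
// log_emis: n x 3 log emission probabilities, log_pi: length-3 log initial
// distribution, log_A: 3x3 log transition matrix (rows = from).
// Returns per-bin posteriors (gamma), summed pairwise transition posteriors
// (xi_sum, for the Baum-Welch M-step) and the sequence log-likelihood.
// [[Rcpp::export]]
List forward_backward_cpp(NumericMatrix log_emis, NumericVector log_pi,
                          NumericMatrix log_A) {
  const int n = log_emis.nrow();
  if (n == 0) stop("empty observation sequence");
  NumericMatrix la(n, 3), lb(n, 3), gamma(n, 3);

  for (int s = 0; s < 3; ++s) la(0, s) = log_pi[s] + log_emis(0, s);
  if (logsumexp3(la(0, 0), la(0, 1), la(0, 2)) == R_NegInf)
    stop("model cannot emit data at bin 1");
  for (int t = 1; t < n; ++t) {
    for (int s = 0; s < 3; ++s) {
      double v = logsumexp3(la(t - 1, 0) + log_A(0, s),
                            la(t - 1, 1) + log_A(1, s),
                            la(t - 1, 2) + log_A(2, s));
      la(t, s) = v + log_emis(t, s);
    }
    if (logsumexp3(la(t, 0), la(t, 1), la(t, 2)) == R_NegInf)
      stop("model cannot emit data at bin " + std::to_string(t + 1));
  }
  const double ll = logsumexp3(la(n - 1, 0), la(n - 1, 1), la(n - 1, 2));

  for (int s = 0; s < 3; ++s) lb(n - 1, s) = 0.0;
  for (int t = n - 2; t >= 0; --t)
    for (int s = 0; s < 3; ++s)
      lb(t, s) = logsumexp3(log_A(s, 0) + log_emis(t + 1, 0) + lb(t + 1, 0),
                            log_A(s, 1) + log_emis(t + 1, 1) + lb(t + 1, 1),
                            log_A(s, 2) + log_emis(t + 1, 2) + lb(t + 1, 2));

  for (int t = 0; t < n; ++t) {
    double g0 = la(t, 0) + lb(t, 0) - ll;
    double g1 = la(t, 1) + lb(t, 1) - ll;
    double g2 = la(t, 2) + lb(t, 2) - ll;
    double e0 = g0 == R_NegInf ? 0.0 : std::exp(g0);
    double e1 = g1 == R_NegInf ? 0.0 : std::exp(g1);
    double e2 = g2 == R_NegInf ? 0.0 : std::exp(g2);
    double z = e0 + e1 + e2;
    gamma(t, 0) = e0 / z;
    gamma(t, 1) = e1 / z;
    gamma(t, 2) = e2 / z;
  }

  NumericMatrix xi(3, 3);
  for (int t = 0; t < n - 1; ++t)
    for (int i = 0; i < 3; ++i) {
      if (la(t, i) == R_NegInf) continue;
      for (int j = 0; j < 3; ++j) {
        double v = la(t, i) + log_A(i, j) + log_emis(t + 1, j) +
                   lb(t + 1, j) - ll;
        if (v != R_NegInf) xi(i, j) += std::exp(v);
      }
    }

  return List::create(_["gamma"] = gamma, _["xi_sum"] = xi,
                      _["loglik"] = ll);
}
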