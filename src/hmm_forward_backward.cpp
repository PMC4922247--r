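#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Scaled forward-backward recursions for a 2-state HMM.
//
// dens: T x 2 matrix of per-observation emission densities (not logged);
// trans: 2 x 2 row-stochastic transition matrix; delta: initial distribution.
// seg_start: 1-based indices where independent chain segments begin (the
// chain is re-initialized from delta at each segment start; segments arise
// from gaps in the fix series).
//
// Returns log-likelihood, posterior state probabilities (T x 2), the matrix
// of expected transition counts summed over time (2 x 2), and the summed
// posterior at segment starts (for the initial-distribution M-step).
// [[Rcpp::export]]
List forward_backward_cpp(NumericMatrix dens, NumericMatrix trans,
                          NumericVector delta, IntegerVector seg_start) {
  const int T = dens.nrow();
  const int S = seg_start.size();
  NumericMatrix alpha(T, 2), beta(T, 2), post(T, 2);
  NumericVector cvec(T);
  NumericMatrix xi(2, 2);
  NumericVector first(2);
  double loglik = 0.0;
  const double tiny = 1e-300;

  // segment boundaries: seg i covers [seg_start[i]-1, seg_end)
  for (int s = 0; s < S; ++s) {
    int a = seg_start[s] - 1;
    int b = (s + 1 < S) ? (seg_start[s + 1] - 1) : T;

    // forward with scaling
    double a0 = delta[0] * dens(a, 0), a1 = delta[1] * dens(a, 1);
    double c = a0 + a1;
    if (c < tiny) c = tiny;
    alpha(a, 0) = a0 / c; alpha(a, 1) = a1 / c;
    cvec[a] = c;
    loglik += std::log(c);
    for (int t = a + 1; t < b; ++t) {
      double p0 = (alpha(t - 1, 0) * trans(0, 0) + alpha(t - 1, 1) * trans(1, 0)) * dens(t, 0);
      double p1 = (alpha(t - 1, 0) * trans(0, 1) + alpha(t - 1, 1) * trans(1, 1)) * dens(t, 1);
      c = p0 + p1;
      if (c < tiny) c = tiny;
      alpha(t, 0) = p0 / c; alpha(t, 1) = p1 / c;
      cvec[t] = c;
      loglik += std::log(c);
    }

    // backward, scaled by the same constants
    beta(b - 1, 0) = 1.0; beta(b - 1, 1) = 1.0;
    for (int t = b - 2; t >= a; --t) {
      double b0 = (trans(0, 0) * dens(t + 1, 0) * beta(t + 1, 0) +
                   trans(0, 1) * dens(t + 1, 1) * beta(t + 1, 1)) / cvec[t + 1];
      double b1 = (trans(1, 0) * dens(t + 1, 0) * beta(t + 1, 0) +
                   trans(1, 1) * dens(t + 1, 1) * beta(t + 1, 1)) / cvec[t + 1];
      beta(t, 0) = b0; beta(t, 1) = b1;
    }

    for (int t = a; t < b; ++t) {
      double g0 = alpha(t, 0) * beta(t, 0);
      double g1 = alpha(t, 1) * beta(t, 1);
      double z = g0 + g1;
      if (z < tiny) z = tiny;
      post(t, 0) = g0 / z; post(t, 1) = g1 / z;
    }
    first[0] += post(a, 0);
    first[1] += post(a, 1);

    for (int t = a; t < b - 1; ++t) {
      for (int i = 0; i < 2; ++i) {
        for (int j = 0; j < 2; ++j) {
          xi(i, j) += alpha(t, i) * trans(i, j) * dens(t + 1, j) *
            beta(t + 1, j) / cvec[t + 1];
        }
      }
    }
  }

  return List::create(_["loglik"] = loglik,
                      _["posterior"] = post,
                      _["xi"] = xi,
                      _["first"] = first);
}
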