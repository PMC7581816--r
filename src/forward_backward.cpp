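#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

// Scaled forward-backward for a categorical-emission HMM.
// y is 0-based; A rows are source states; E rows are hidden states.
// Returns the per-step posterior gamma, the sequence log-likelihood and the
// summed expected transition counts xi (the Baum-Welch E-step quantities).
// [[Rcpp::export(name = ".fb_cpp")]]
List fb_cpp(NumericVector pi, NumericMatrix A, NumericMatrix E,
            IntegerVector y) {
  const int N = A.nrow();
  const int T = y.size();
  NumericMatrix alpha(T, N), beta(T, N), gamma(T, N), xi(N, N);
  NumericVector c(T);

  double s = 0.0;
  for (int j = 0; j < N; ++j) {
    alpha(0, j) = pi[j] * E(j, y[0]);
    s += alpha(0, j);
  }
  if (s <= 0.0) s = DBL_MIN;
  c[0] = s;
  for (int j = 0; j < N; ++j) alpha(0, j) /= s;

  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int j = 0; j < N; ++j) {
      double a = 0.0;
      for (int i = 0; i < N; ++i) a += alpha(t - 1, i) * A(i, j);
      a *= E(j, y[t]);
      alpha(t, j) = a;
      s += a;
    }
    if (s <= 0.0) s = DBL_MIN;
    c[t] = s;
    for (int j = 0; j < N; ++j) alpha(t, j) /= s;
  }

  for (int j = 0; j < N; ++j) beta(T - 1, j) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < N; ++i) {
      double b = 0.0;
      for (int j = 0; j < N; ++j)
        b += A(i, j) * E(j, y[t + 1]) * beta(t + 1, j);
      beta(t, i) = b / c[t + 1];
    }
  }

  double ll = 0.0;
  for (int t = 0; t < T; ++t) {
    double rs = 0.0;
    for (int j = 0; j < N; ++j) {
      gamma(t, j) = alpha(t, j) * beta(t, j);
      rs += gamma(t, j);
    }
    for (int j = 0; j < N; ++j) gamma(t, j) /= rs;
    ll += std::log(c[t]);
  }

  for (int t = 0; t < T - 1; ++t)
    for (int i = 0; i < N; ++i)
      for (int j = 0; j < N; ++j)
        xi(i, j) += alpha(t, i) * A(i, j) * E(j, y[t + 1]) *
                    beta(t + 1, j) / c[t + 1];

  return List::create(_["gamma"] = gamma, _["loglik"] = ll,
                      _["xi_sum"] = xi);
}
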