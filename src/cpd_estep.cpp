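#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// E-step of rigid coherent point drift with a uniform outlier component.
// TY: transformed moving cloud (M x d); X: fixed cloud (N x d);
// sigma: current Gaussian width; outlier_const: the additive uniform term
// in each column denominator. Returns the sufficient statistics the
// M-step needs: P1 (row sums of P), Pt1 (column sums), PX (P %*% X) and
// the negative log-likelihood term sum(log(denom)).
// [[Rcpp::export(name = ".cpd_estep")]]
List cpd_estep(NumericMatrix TY, NumericMatrix X, double sigma,
               double outlier_const) {
  const int M = TY.nrow(), N = X.nrow(), d = TY.ncol();
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  std::vector<double> K(static_cast<size_t>(M) * N);
  NumericVector P1(M), Pt1(N);
  NumericMatrix PX(M, d);
  double loglik = 0.0;

  for (int n = 0; n < N; ++n) {
    double denom = outlier_const + 1e-300;
    size_t base = static_cast<size_t>(n) * M;
    for (int m = 0; m < M; ++m) {
      double d2 = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = TY(m, k) - X(n, k);
        d2 += diff * diff;
      }
      double e = d2 * inv2s2;
      // exp underflows to subnormals for distant pairs, which is both
      // negligible and very slow on common hardware; cut off explicitly
      double kv = (e > 40.0) ? 0.0 : std::exp(-e);
      K[base + m] = kv;
      denom += kv;
    }
    loglik += std::log(denom);
    double pt1 = 0.0;
    for (int m = 0; m < M; ++m) {
      double p = K[base + m] / denom;
      pt1 += p;
      P1[m] += p;
      for (int k = 0; k < d; ++k) PX(m, k) += p * X(n, k);
    }
    Pt1[n] = pt1;
  }
  return List::create(_["P1"] = P1, _["Pt1"] = Pt1, _["PX"] = PX,
                      _["neg_loglik"] = -loglik);
}
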