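#include <Rcpp.h>
using namespace Rcpp;

// Log density of a Gaussian kernel density estimate evaluated at query
// points, with a floor applied on the density scale. Densities here live on
// the log-ISI axis, so magnitudes are O(1) and a direct sum of exponentials
// is numerically safe; queries far outside the support underflow to 0 and
// are caught by the floor.
// [[Rcpp::export]]
NumericVector kde_logdens_cpp(NumericVector q, NumericVector centers,
                              double h, double floor_eps) {
  const int nq = q.size(), nc = centers.size();
  NumericVector out(nq);
  const double c0 = -0.5 * std::log(2.0 * M_PI) - std::log(h) -
    std::log(static_cast<double>(nc));
  const double lf = std::log(floor_eps);
  for (int i = 0; i < nq; ++i) {
    const double qi = q[i];
    double s = 0.0;
    for (int j = 0; j < nc; ++j) {
      const double z = (qi - centers[j]) / h;
      s += std::exp(-0.5 * z * z);
    }
    const double ld = (s > 0.0) ? c0 + std::log(s) : R_NegInf;
    out[i] = (ld < lf) ? lf : ld;
  }
  return out;
}

// Leave-fold-out cross-validated mean log-likelihood for one bandwidth.
// fold is 1-based fold membership per point.
// [[Rcpp::export]]
double kde_cv_loglik_cpp(NumericVector x, IntegerVector fold, int nfold,
                         double h, double floor_eps) {
  const int n = x.size();
  const double lf = std::log(floor_eps);
  const double lc = -0.5 * std::log(2.0 * M_PI) - std::log(h);
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (fold[j] == fold[i]) continue;
      const double z = (x[i] - x[j]) / h;
      s += std::exp(-0.5 * z * z);
      ++m;
    }
    double ld;
    if (m == 0 || s <= 0.0) ld = lf;
    else {
      ld = lc + std::log(s) - std::log(static_cast<double>(m));
      if (ld < lf) ld = lf;
    }
    total += ld;
  }
  return total / n;
}
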