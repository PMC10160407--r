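#include <Rcpp.h>
using namespace Rcpp;

// Hermite-function basis matrix H_0..H_max_order evaluated at x by the
// normalized three-term recurrence (see hermite_basis() in R/hermite.R).
// Columns are filled in order so all memory access is sequential.
// [[Rcpp::export]]
NumericMatrix hermite_basis_cpp(NumericVector x, int max_order) {
  const int n = x.size();
  NumericMatrix H(n, max_order + 1);
  const double c0 = std::pow(M_PI, -0.25);
  double *h = REAL(H);
  const double *xs = REAL(x);
  for (int i = 0; i < n; i++) h[i] = c0 * std::exp(-xs[i] * xs[i] / 2);
  if (max_order >= 1) {
    const double s2 = std::sqrt(2.0);
    for (int i = 0; i < n; i++) h[n + i] = s2 * xs[i] * h[i];
    for (int k = 1; k < max_order; k++) {
      const double a = std::sqrt(2.0 / (k + 1));
      const double b = std::sqrt((double)k / (k + 1));
      const double *pk = h + (size_t)n * k, *pm1 = pk - n;
      double *pp = h + (size_t)n * (k + 1);
      for (int i = 0; i < n; i++) pp[i] = xs[i] * a * pk[i] - b * pm1[i];
    }
  }
  return H;
}

// Sample Hermite coefficient estimates (1/N) sum_j H_i(x_j) for
// i = 0..max_order, without materializing the basis matrix.
// [[Rcpp::export]]
NumericVector hermite_coef_means_cpp(NumericVector x, int max_order) {
  const int n = x.size();
  NumericVector out(max_order + 1);
  const double c0 = std::pow(M_PI, -0.25);
  const double *xs = REAL(x);
  std::vector<double> hm1(n), hk(n);
  double acc = 0;
  for (int i = 0; i < n; i++) {
    hm1[i] = c0 * std::exp(-xs[i] * xs[i] / 2);
    acc += hm1[i];
  }
  out[0] = acc / n;
  if (max_order >= 1) {
    const double s2 = std::sqrt(2.0);
    acc = 0;
    for (int i = 0; i < n; i++) {
      hk[i] = s2 * xs[i] * hm1[i];
      acc += hk[i];
    }
    out[1] = acc / n;
    for (int k = 1; k < max_order; k++) {
      const double a = std::sqrt(2.0 / (k + 1));
      const double b = std::sqrt((double)k / (k + 1));
      acc = 0;
      for (int i = 0; i < n; i++) {
        double hp = xs[i] * a * hk[i] - b * hm1[i];
        hm1[i] = hk[i];
        hk[i] = hp;
        acc += hp;
      }
      out[k + 1] = acc / n;
    }
  }
  return out;
}
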