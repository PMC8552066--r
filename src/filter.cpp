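// Direct-form II transposed IIR filtering (single channel), with optional
// initial conditions.  The Butterworth design lives in R/bsp.R.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".iir_filter")]]
NumericVector iir_filter(NumericVector b, NumericVector a, NumericVector x,
                         NumericVector zi) {
  const int nb = b.size(), na = a.size(), n = x.size();
  const int nz = std::max(na, nb) - 1;
  std::vector<double> z(nz, 0.0);
  for (int i = 0; i < std::min((int)zi.size(), nz); ++i) z[i] = zi[i];
  std::vector<double> bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  const double a0 = aa[0];
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = (bb[0] * xi + z[0]) / a0;
    for (int k = 0; k < nz - 1; ++k)
      z[k] = bb[k + 1] * xi + z[k + 1] - aa[k + 1] * yi;
    if (nz > 0) z[nz - 1] = bb[nz] * xi - aa[nz] * yi;
    y[i] = yi;
  }
  return y;
}
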