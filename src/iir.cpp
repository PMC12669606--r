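#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter, a[0] assumed 1.
// zi: initial filter state (length max(len(a),len(b)) - 1), may be empty.
// [[Rcpp::export(name = ".df2t_filter")]]
NumericVector df2t_filter(NumericVector x, NumericVector b, NumericVector a,
                          NumericVector zi) {
  const int n = x.size();
  const int nb = b.size(), na = a.size();
  const int nz = std::max(na, nb) - 1;
  std::vector<double> z(nz, 0.0);
  for (int i = 0; i < std::min((int)zi.size(), nz); ++i) z[i] = zi[i];
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + (nz > 0 ? z[0] : 0.0);
    for (int j = 0; j < nz - 1; ++j) {
      z[j] = z[j + 1] + (j + 1 < nb ? b[j + 1] * xi : 0.0) -
             (j + 1 < na ? a[j + 1] * yi : 0.0);
    }
    if (nz > 0) {
      z[nz - 1] = (nz < nb ? b[nz] * xi : 0.0) - (nz < na ? a[nz] * yi : 0.0);
    }
    y[i] = yi;
  }
  return y;
}
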