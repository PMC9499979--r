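#include <Rcpp.h>
using namespace Rcpp;

// Direct-form-II-transposed IIR filter, a[0] assumed 1 (coefficients are
// normalised on the R side). Hot loop for the click detector's band
// filtering of multi-hour recordings.
// [[Rcpp::export(name = ".iir_filter_cpp")]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a,
                             NumericVector x) {
  int nb = b.size(), na = a.size(), n = x.size();
  int nw = std::max(nb, na);
  std::vector<double> w(nw, 0.0);
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = b[0] * xi + w[0];
    for (int k = 1; k < nw; ++k) {
      double bk = (k < nb) ? b[k] : 0.0;
      double ak = (k < na) ? a[k] : 0.0;
      w[k - 1] = bk * xi - ak * yi + ((k < nw - 1) ? w[k] : 0.0);
    }
    y[i] = yi;
  }
  return y;
}
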