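#include <Rcpp.h>
using namespace Rcpp;

// Causal IIR filter, direct form II transposed, with carried state.
// b, a are transfer-function coefficients (a[0] must be 1 after
// normalisation); zi has length max(len(a), len(b)) - 1 and is updated in
// place semantics via the returned list, so chunked application reproduces
// whole-signal output exactly.
// [[Rcpp::export]]
List iir_df2t(NumericVector b, NumericVector a, NumericVector x,
              NumericVector zi) {
  int nb = b.size(), na = a.size();
  int nfilt = std::max(nb, na);
  std::vector<double> bb(nfilt, 0.0), aa(nfilt, 0.0);
  double a0 = a[0];
  if (a0 == 0.0) stop("a[0] must be non-zero");
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a0;
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a0;
  int nz = nfilt - 1;
  if (zi.size() != nz) stop("zi must have length %d", nz);
  std::vector<double> z(zi.begin(), zi.end());
  int n = x.size();
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + (nz > 0 ? z[0] : 0.0);
    for (int k = 0; k < nz - 1; ++k) {
      z[k] = bb[k + 1] * xi + z[k + 1] - aa[k + 1] * yi;
    }
    if (nz > 0) z[nz - 1] = bb[nfilt - 1] * xi - aa[nfilt - 1] * yi;
    y[i] = yi;
  }
  return List::create(_["y"] = y, _["zf"] = NumericVector(z.begin(), z.end()));
}
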