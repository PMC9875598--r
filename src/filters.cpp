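#include <Rcpp.h>
using namespace Rcpp;

// Direct-form-II-transposed biquad (second-order IIR) filter.
// b, a are length-3 coefficient vectors with a[0] == 1.
// [[Rcpp::export(name = ".biquad_filter")]]
NumericVector biquad_filter(NumericVector x, NumericVector b, NumericVector a,
                            Nullable<NumericVector> zi = R_NilValue) {
  if (b.size() != 3 || a.size() != 3)
    stop("biquad_filter expects length-3 coefficient vectors");
  const double b0 = b[0], b1 = b[1], b2 = b[2];
  const double a1 = a[1], a2 = a[2];
  const R_xlen_t n = x.size();
  NumericVector y(n);
  double z1 = 0.0, z2 = 0.0;
  if (zi.isNotNull()) {
    NumericVector z(zi);
    if (z.size() != 2) stop("zi must have length 2");
    z1 = z[0]; z2 = z[1];
  }
  for (R_xlen_t i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b0 * xi + z1;
    z1 = b1 * xi - a1 * yi + z2;
    z2 = b2 * xi - a2 * yi;
    y[i] = yi;
  }
  return y;
}

// steady-state filter state for a unit-amplitude constant input
// (the lfilter_zi construction), so transients at the record edges vanish
static void biquad_zi(const double* b, const double* a, double* zi) {
  const double h1 = (b[0] + b[1] + b[2]) / (1.0 + a[1] + a[2]);
  zi[1] = b[2] - a[2] * h1;
  zi[0] = b[1] - a[1] * h1 + zi[1];
}

static void biquad_inplace(std::vector<double>& x, const double* b,
                           const double* a, bool reverse) {
  const double b0 = b[0], b1 = b[1], b2 = b[2];
  const double a1 = a[1], a2 = a[2];
  const R_xlen_t n = (R_xlen_t)x.size();
  if (n == 0) return;
  double zi[2];
  biquad_zi(b, a, zi);
  double z1 = zi[0] * (reverse ? x[n - 1] : x[0]);
  double z2 = zi[1] * (reverse ? x[n - 1] : x[0]);
  if (!reverse) {
    for (R_xlen_t i = 0; i < n; ++i) {
      const double xi = x[i];
      const double yi = b0 * xi + z1;
      z1 = b1 * xi - a1 * yi + z2;
      z2 = b2 * xi - a2 * yi;
      x[i] = yi;
    }
  } else {
    for (R_xlen_t i = n - 1; i >= 0; --i) {
      const double xi = x[i];
      const double yi = b0 * xi + z1;
      z1 = b1 * xi - a1 * yi + z2;
      z2 = b2 * xi - a2 * yi;
      x[i] = yi;
    }
  }
}

// Zero-phase biquad cascade applied to every column of a matrix: each of
// the filters in blist/alist (parallel lists of length-3 vectors) is run
// forward-backward with odd-reflection padding of `pad` samples.
// [[Rcpp::export(name = ".filtfilt_mat")]]
NumericMatrix filtfilt_mat(NumericMatrix X, List blist, List alist, int pad) {
  const int n = X.nrow(), m = X.ncol(), nf = blist.size();
  if (pad >= n) pad = n - 1;
  if (pad < 0) pad = 0;
  std::vector<std::vector<double> > bcoef(nf), acoef(nf);
  for (int f = 0; f < nf; ++f) {
    bcoef[f] = Rcpp::as<std::vector<double> >(blist[f]);
    acoef[f] = Rcpp::as<std::vector<double> >(alist[f]);
    if (bcoef[f].size() != 3 || acoef[f].size() != 3)
      stop("coefficient vectors must have length 3");
  }
  NumericMatrix Y(n, m);
  std::vector<double> w(n + 2 * pad);
  for (int j = 0; j < m; ++j) {
    for (int f = 0; f < nf; ++f) {
      const double* src = (f == 0) ? &X(0, j) : &Y(0, j);
      // odd reflection about the end points
      for (int i = 0; i < pad; ++i) w[i] = 2.0 * src[0] - src[pad - i];
      for (int i = 0; i < n; ++i) w[pad + i] = src[i];
      for (int i = 0; i < pad; ++i)
        w[pad + n + i] = 2.0 * src[n - 1] - src[n - 2 - i];
      biquad_inplace(w, bcoef[f].data(), acoef[f].data(), false);
      biquad_inplace(w, bcoef[f].data(), acoef[f].data(), true);
      for (int i = 0; i < n; ++i) Y(i, j) = w[pad + i];
    }
  }
  return Y;
}
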