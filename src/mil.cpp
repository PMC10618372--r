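#include <Rcpp.h>
using namespace Rcpp;

// Propagate the alternating-interval likelihood through a dwell sequence.
// For each dwell of class c with duration t the state row-vector is
// advanced by exp(eQ_cc (t - td)) expressed spectrally as
// V diag(exp(lambda (t - td))) Vi, followed (except after the final
// dwell) by the class-switch operator folded into M2 = Vi * Q_cc' for the
// transition into the opposite class. Real spectra are required (checked
// on the R side). Rescaling after every dwell guards against underflow.
//
// For class k (0 closed, 1 open): Vk (nk x nk), lamk (nk),
// M2k (nk x n_other) = Vi_k * Q_{k,other}, Sk (nk) = row sums of Vi_k
// (for the survival term after the last dwell).
// [[Rcpp::export(name = ".mil_propagate")]]
double mil_propagate(NumericVector t, IntegerVector cls, double td,
                     NumericVector v0,
                     NumericMatrix V0m, NumericVector lam0, NumericMatrix M20,
                     NumericMatrix V1m, NumericVector lam1, NumericMatrix M21,
                     NumericMatrix Vi0, NumericMatrix Vi1) {
  const int n = t.size();
  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> tmp(16), w(16);
  double logscale = 0.0;
  for (int k = 0; k < n; ++k) {
    const bool open = cls[k] == 1;
    NumericMatrix& V = open ? V1m : V0m;
    NumericVector& lam = open ? lam1 : lam0;
    NumericMatrix& M2 = open ? M21 : M20;
    NumericMatrix& Vi = open ? Vi1 : Vi0;
    const int na = V.nrow();
    const double dt = t[k] - td;
    // tmp = (v * V) .* exp(lam * dt)
    for (int j = 0; j < na; ++j) {
      double acc = 0.0;
      for (int i = 0; i < na; ++i) acc += v[i] * V(i, j);
      tmp[j] = acc * std::exp(lam[j] * dt);
    }
    if (k < n - 1) {
      const int nb = M2.ncol();
      for (int j = 0; j < nb; ++j) {
        double acc = 0.0;
        for (int i = 0; i < na; ++i) acc += tmp[i] * M2(i, j);
        w[j] = acc;
      }
      double s = 0.0;
      for (int j = 0; j < nb; ++j) s += std::fabs(w[j]);
      if (!(s > 0.0) || !std::isfinite(s)) return R_NegInf;
      for (int j = 0; j < nb; ++j) v[j] = w[j] / s;
      logscale += std::log(s);
      v.resize(nb);
    } else {
      // survival: v exp(eQ dt) 1 = tmp * (Vi %*% 1)
      double s = 0.0;
      for (int j = 0; j < na; ++j) {
        double acc = 0.0;
        for (int c = 0; c < na; ++c) acc += Vi(j, c);
        s += tmp[j] * acc;
      }
      if (!(s > 0.0) || !std::isfinite(s)) return R_NegInf;
      logscale += std::log(s);
    }
  }
  return logscale;
}
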