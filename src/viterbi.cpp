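#include <Rcpp.h>
using namespace Rcpp;

// Most-likely two-level state path under Gaussian emissions: the
// assignment step of segmental k-means idealization. Levels/SDs per class
// (0 = closed, 1 = open), log transition probabilities from a 2x2 matrix.
// [[Rcpp::export(name = ".viterbi2")]]
IntegerVector viterbi2(NumericVector x, NumericVector mu, NumericVector sd,
                       NumericMatrix ltrans, NumericVector lprior) {
  const R_xlen_t n = x.size();
  IntegerVector path(n);
  if (n == 0) return path;
  std::vector<unsigned char> bp(2 * (size_t)n);
  const double c0 = -0.5 * std::log(2.0 * M_PI) - std::log(sd[0]);
  const double c1 = -0.5 * std::log(2.0 * M_PI) - std::log(sd[1]);
  const double is0 = 0.5 / (sd[0] * sd[0]);
  const double is1 = 0.5 / (sd[1] * sd[1]);
  double d0 = x[0] - mu[0], d1 = x[0] - mu[1];
  double v0 = lprior[0] + c0 - d0 * d0 * is0;
  double v1 = lprior[1] + c1 - d1 * d1 * is1;
  for (R_xlen_t t = 1; t < n; ++t) {
    d0 = x[t] - mu[0];
    d1 = x[t] - mu[1];
    const double e0 = c0 - d0 * d0 * is0;
    const double e1 = c1 - d1 * d1 * is1;
    const double a00 = v0 + ltrans(0, 0), a10 = v1 + ltrans(1, 0);
    const double a01 = v0 + ltrans(0, 1), a11 = v1 + ltrans(1, 1);
    unsigned char b0 = a00 >= a10 ? 0 : 1;
    unsigned char b1 = a01 >= a11 ? 0 : 1;
    const double n0 = (b0 ? a10 : a00) + e0;
    const double n1 = (b1 ? a11 : a01) + e1;
    bp[2 * (size_t)t] = b0;
    bp[2 * (size_t)t + 1] = b1;
    v0 = n0;
    v1 = n1;
  }
  int s = v1 > v0 ? 1 : 0;
  path[n - 1] = s;
  for (R_xlen_t t = n - 1; t > 0; --t) {
    s = bp[2 * (size_t)t + s];
    path[t - 1] = s;
  }
  return path;
}
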