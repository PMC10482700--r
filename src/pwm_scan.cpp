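#include <Rcpp.h>
using namespace Rcpp;

// Best-hit log-odds scan of one integer-coded sequence (A=0,C=1,G=2,T=3,
// N=4) against a list of 4 x L log-odds matrices (both strands supplied by
// the caller). N positions contribute 0 (odds ratio 1). Returns the maximum
// window sum over all matrices and offsets; the caller applies the floor.
// [[Rcpp::export]]
double scan_best_hit_cpp(IntegerVector seq, List lo_mats) {
  const int n = seq.size();
  double best = R_NegInf;
  for (int m = 0; m < lo_mats.size(); ++m) {
    NumericMatrix lo = lo_mats[m];
    const int L = lo.ncol();
    if (L > n) continue;
    for (int off = 0; off + L <= n; ++off) {
      double s = 0.0;
      for (int j = 0; j < L; ++j) {
        const int b = seq[off + j];
        if (b < 4) s += lo(b, j);
      }
      if (s > best) best = s;
    }
  }
  return best == R_NegInf ? 0.0 : best;
}
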