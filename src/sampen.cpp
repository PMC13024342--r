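#include <Rcpp.h>
using namespace Rcpp;

// Sample entropy pair counts: B = template pairs of length m within
// Chebyshev tolerance r (strict <), A = the same pairs extended to length
// m + 1.  Templates are the N - m windows x[i..i+m-1]; self-matches are
// excluded and each unordered pair is counted once.  Counting A over the
// same i, j < N - m index range keeps the ratio A/B conditional, the
// standard SampEn construction.
// [[Rcpp::export(name = ".sampen_counts")]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  int n = x.size();
  int nt = n - m;  // number of (m+1)-extendable templates
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dk = std::abs(x[i + k] - x[j + k]);
        if (dk > d) d = dk;
      }
      if (d < r) {
        B += 1.0;
        double dm = std::abs(x[i + m] - x[j + m]);
        if (dm > d) d = dm;
        if (d < r) A += 1.0;
      }
    }
  }
  return NumericVector::create(A, B);
}
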