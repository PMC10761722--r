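#include <Rcpp.h>
using namespace Rcpp;

// Template-match pair counts for sample entropy (Richman & Moorman
// convention): templates i = 0..N-m-1 so every length-m template also has
// a length-(m+1) extension; pairs i < j; Chebyshev distance strictly below
// r counts as a match. Returns (B, A) = (m-matches, (m+1)-matches).
// [[Rcpp::export(name = ".sampen_counts")]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;  // usable templates
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool match_m = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) >= r) { match_m = false; break; }
      }
      if (!match_m) continue;
      B += 1.0;
      if (std::fabs(x[i + m] - x[j + m]) < r) A += 1.0;
    }
  }
  return NumericVector::create(B, A);
}
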