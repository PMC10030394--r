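#include <Rcpp.h>
#include <cmath>

// Sample entropy by exhaustive template-pair counting.
//
// U^k counts unordered pairs (i, j), i != j, of length-k subseries whose
// Chebyshev distance is <= r (closed tolerance, self-matches excluded).
// Both U^m and U^{m+1} run over template start indices 0 .. N-m-1 so the
// normalisation (identical in numerator and denominator) cancels in the
// ratio. Returns -log(A/B); +Inf when A == 0; NaN when B == 0.

static double sampen_trace(const double* x, int n, int m, double r) {
  const int nt = n - m;  // number of (m+1)-extendable templates
  if (nt < 2) return NA_REAL;
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::abs(x[i + k] - x[j + k]) > r) { match = false; break; }
      }
      if (!match) continue;
      B += 1.0;
      if (std::abs(x[i + m] - x[j + m]) <= r) A += 1.0;
    }
  }
  if (B == 0.0) return R_NaN;
  if (A == 0.0) return R_PosInf;
  return -std::log(A / B);
}

// [[Rcpp::export]]
Rcpp::NumericVector sampen_cpp(Rcpp::NumericMatrix x, int m,
                               Rcpp::NumericVector r) {
  const int n = x.nrow(), p = x.ncol();
  if (r.size() != p) Rcpp::stop("length(r) must equal ncol(x)");
  Rcpp::NumericVector out(p);
  for (int j = 0; j < p; ++j) {
    out[j] = sampen_trace(&x(0, j), n, m, r[j]);
  }
  return out;
}
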