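#include <Rcpp.h>
using namespace Rcpp;

// Chebyshev distance between templates starting at i and j (0-based),
// with early exit once the running max exceeds r.
static inline bool within_r(const NumericVector &x, int i, int j, int m, double r) {
  for (int k = 0; k < m; ++k) {
    double d = std::fabs(x[i + k] - x[j + k]);
    if (d > r) return false;
  }
  return true;
}

// Unordered template pairs i < j over i, j in {0, ..., N - m - 1}: both
// counts range over templates that have an (m+1)-th extension, which keeps
// count_m1 <= count_m structurally true. Counts held in doubles: pair counts
// exceed 2^31 well before memory does.
// [[Rcpp::export]]
List count_matches_cpp(NumericVector x, int m, double r) {
  const int N = x.size();
  const int nt = N - m;
  double cm = 0.0, cm1 = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      if (within_r(x, i, j, m, r)) {
        cm += 1.0;
        if (std::fabs(x[i + m] - x[j + m]) <= r) cm1 += 1.0;
      }
    }
  }
  return List::create(_["count_m"] = cm, _["count_m1"] = cm1,
                      _["n_templates"] = nt);
}

// Pincus's phi_m(r): average over templates of the log of the fraction of
// templates (self included) within tolerance; templates range over
// {0, ..., N - m}.
// [[Rcpp::export]]
double apen_phi_cpp(NumericVector x, int m, double r) {
  const int N = x.size();
  const int nt = N - m + 1;
  double phi = 0.0;
  for (int i = 0; i < nt; ++i) {
    int c = 0;
    for (int j = 0; j < nt; ++j) {
      if (within_r(x, i, j, m, r)) ++c;
    }
    phi += std::log(static_cast<double>(c) / nt);
  }
  return phi / nt;
}
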