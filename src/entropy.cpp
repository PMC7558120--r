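#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Template-match counts shared by approximate and sample entropy.
//
// Templates of length m are compared under the Chebyshev (max-abs)
// distance with tolerance r. Returns, for a series of length N:
//   cm  : per-template match counts at length m, including self-matches,
//         over the N - m + 1 templates (approximate-entropy convention);
//   cm1 : the same at length m + 1 over the N - m templates;
//   B   : number of distinct template pairs (i < j, both <= N - m)
//         matching at length m, excluding self-matches
//         (sample-entropy convention);
//   A   : the same pairs extended to length m + 1.
// [[Rcpp::export]]
List entropy_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nm = n - m;          // templates for SampEn / ApEn phi_{m+1}
  const int nm1 = n - m + 1;     // templates for ApEn phi_m
  if (nm < 1) stop("series too short for embedding length m");

  const double* v = REAL(x);
  std::vector<int> cm(nm1, 1);   // self-match included
  std::vector<int> cm1(nm, 1);
  double B = 0.0, A = 0.0;

  for (int i = 0; i < nm1; ++i) {
    const double* vi = v + i;
    for (int j = i + 1; j < nm1; ++j) {
      const double* vj = v + j;
      bool match = true;
      double dmax = 0.0;
      for (int k = 0; k < m; ++k) {
        double d = std::fabs(vi[k] - vj[k]);
        if (d > r) { match = false; break; }
        if (d > dmax) dmax = d;
      }
      if (!match) continue;
      ++cm[i];
      ++cm[j];
      if (j < nm) {               // i < j < nm: both templates extendable
        B += 1.0;
        double d = std::fabs(vi[m] - vj[m]);
        if (d <= r && dmax <= r) {
          A += 1.0;
          ++cm1[i];
          ++cm1[j];
        }
      }
    }
  }
  return List::create(_["cm"] = IntegerVector(cm.begin(), cm.end()),
                      _["cm1"] = IntegerVector(cm1.begin(), cm1.end()),
                      _["B"] = B, _["A"] = A);
}
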