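#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>
using namespace Rcpp;

// Template-match counting for sample entropy.
//
// Templates are the N - m vectors z_i^m = (x_i, ..., x_{i+m-1}) for
// i = 1..N-m, i.e. only those m-templates that can be extended to length
// m + 1, so that A/B is a genuine conditional probability. Matching uses
// the Chebyshev (max-component) distance with a strict "< r" comparison;
// ordered pairs with i != j are counted and self-matches are excluded.
//
// Candidate pairs are enumerated by sorting template start points on their
// first component and scanning only pairs whose first components lie within
// r of each other; the remaining components are then checked directly. This
// prunes the O(N^2) pair set without changing which pairs are counted, so
// the counts equal an exhaustive scan's exactly.
//
// Counts are returned as doubles: at N = 15,000 the ordered-pair counts
// exceed 2^31.
// [[Rcpp::export(name = ".sampen_counts")]]
List sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  if (m < 1) stop("m must be >= 1");
  if (n < m + 2) stop("series too short for m = %d (need at least m + 2 points)", m);
  if (!(r > 0)) stop("tolerance r must be positive");
  const int nt = n - m;  // number of templates extendable to m + 1
  const double *xp = REAL(x);
  std::vector<int> idx(nt);
  std::iota(idx.begin(), idx.end(), 0);
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return xp[a] < xp[b]; });
  std::vector<double> v(nt);  // sorted first components, contiguous scan
  for (int a = 0; a < nt; ++a) v[a] = xp[idx[a]];
  double A = 0.0, B = 0.0;
  if (m == 2) {  // dominant case: tight two-component scan
    for (int a = 1; a < nt; ++a) {
      const int i = idx[a];
      const double xi = v[a];
      const double xi1 = xp[i + 1], xi2 = xp[i + 2];
      for (int b = a - 1; b >= 0; --b) {
        if (xi - v[b] >= r) break;  // sorted: no closer first components left
        const int j = idx[b];
        if (std::fabs(xi1 - xp[j + 1]) < r) {
          B += 2.0;  // ordered pairs: (i, j) and (j, i)
          if (std::fabs(xi2 - xp[j + 2]) < r) A += 2.0;
        }
      }
    }
  } else {
    for (int a = 1; a < nt; ++a) {
      const int i = idx[a];
      const double xi = v[a];
      for (int b = a - 1; b >= 0; --b) {
        if (xi - v[b] >= r) break;
        const int j = idx[b];
        bool match = true;
        for (int k = 1; k < m; ++k) {
          if (std::fabs(xp[i + k] - xp[j + k]) >= r) { match = false; break; }
        }
        if (match) {
          B += 2.0;
          if (std::fabs(xp[i + m] - xp[j + m]) < r) A += 2.0;
        }
      }
    }
  }
  return List::create(_["A"] = A, _["B"] = B, _["n_templates"] = (double)nt);
}
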