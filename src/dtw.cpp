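#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Accumulated-cost dynamic time warping on scalar series.
//
// Local cost is the absolute difference of samples; allowed steps are
// (i+1,j), (i,j+1) and (i+1,j+1); the accumulated distance is the sum of
// local costs over every path pair (each cell counted once), i.e. the
// default behaviour of the MATLAB dtw() routine.  Tie-breaking between
// equal-cost predecessors is deterministic: diagonal first, then
// query-advance, then template-advance, which keeps warping paths short.

static inline double local_cost(double a, double b) { return std::fabs(a - b); }

// [[Rcpp::export]]
List dtw_align_cpp(NumericVector query, NumericVector tmpl) {
  const int n = query.size(), m = tmpl.size();
  if (n == 0 || m == 0) stop("both sequences must be non-empty");

  NumericMatrix D(n, m);
  // predecessor code: -1 origin, 0 diagonal, 1 query-advance, 2 template-advance
  IntegerMatrix from(n, m);

  D(0, 0) = local_cost(query[0], tmpl[0]);
  from(0, 0) = -1;
  for (int j = 1; j < m; ++j) {
    D(0, j) = D(0, j - 1) + local_cost(query[0], tmpl[j]);
    from(0, j) = 2;
  }
  for (int i = 1; i < n; ++i) {
    D(i, 0) = D(i - 1, 0) + local_cost(query[i], tmpl[0]);
    from(i, 0) = 1;
  }
  for (int i = 1; i < n; ++i) {
    for (int j = 1; j < m; ++j) {
      double best = D(i - 1, j - 1);
      int f = 0;
      if (D(i - 1, j) < best) { best = D(i - 1, j); f = 1; }
      if (D(i, j - 1) < best) { best = D(i, j - 1); f = 2; }
      D(i, j) = local_cost(query[i], tmpl[j]) + best;
      from(i, j) = f;
    }
  }

  std::vector<int> pi, pj;
  pi.reserve(n + m);
  pj.reserve(n + m);
  int i = n - 1, j = m - 1;
  for (;;) {
    pi.push_back(i + 1);  // 1-based for R
    pj.push_back(j + 1);
    int f = from(i, j);
    if (f < 0) break;
    if (f == 0) { --i; --j; }
    else if (f == 1) { --i; }
    else { --j; }
  }
  std::reverse(pi.begin(), pi.end());
  std::reverse(pj.begin(), pj.end());

  return List::create(_["index_query"] = wrap(pi),
                      _["index_template"] = wrap(pj),
                      _["distance"] = D(n - 1, m - 1));
}

// Distance only, O(min(n,m)) memory.
// [[Rcpp::export]]
double dtw_distance_cpp(NumericVector a, NumericVector b) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("both sequences must be non-empty");
  std::vector<double> prev(m), cur(m);
  prev[0] = local_cost(a[0], b[0]);
  for (int j = 1; j < m; ++j) prev[j] = prev[j - 1] + local_cost(a[0], b[j]);
  for (int i = 1; i < n; ++i) {
    cur[0] = prev[0] + local_cost(a[i], b[0]);
    for (int j = 1; j < m; ++j) {
      double best = std::min(prev[j - 1], std::min(prev[j], cur[j - 1]));
      cur[j] = local_cost(a[i], b[j]) + best;
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}

// Symmetric pairwise DTW distance matrix for a list of numeric vectors.
// [[Rcpp::export]]
NumericMatrix dtw_pairwise_cpp(List seqs) {
  const int k = seqs.size();
  NumericMatrix out(k, k);
  for (int i = 0; i < k; ++i) {
    NumericVector a = seqs[i];
    for (int j = i + 1; j < k; ++j) {
      NumericVector b = seqs[j];
      double d = dtw_distance_cpp(a, b);
      out(i, j) = d;
      out(j, i) = d;
    }
  }
  return out;
}
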