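#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Optimal least-squares segmentation by dynamic programming.
//
// For every k in 1..k_max, computes the global minimum over all partitions of
// x into k contiguous blocks of the within-block sum of squared deviations
// from the block mean. Block SSE is evaluated in O(1) from prefix sums of x
// and x^2; total cost O(k_max * n^2). Ties at a DP state keep the earliest
// feasible split point.
//
// Returns:
//   cost:  numeric k_max vector, cost[k-1] = optimal SSE with k segments
//   back:  integer k_max x n matrix; back(k-1, i-1) is the 1-based index of
//          the last element of the previous segment in the optimal k-split of
//          x[1..i] (0 when k == 1)
// [[Rcpp::export]]
List dp_segment_core(NumericVector x, int k_max) {
  const int n = x.size();
  if (n < 1) stop("empty input");
  if (k_max < 1 || k_max > n) stop("k_max must be in 1..n");

  std::vector<double> S(n + 1, 0.0), S2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    S[i + 1] = S[i] + x[i];
    S2[i + 1] = S2[i] + x[i] * x[i];
  }
  // SSE of x[a..b], 1-based inclusive; clamped at 0 against rounding.
  auto sse = [&](int a, int b) -> double {
    const double s = S[b] - S[a - 1];
    const double v = S2[b] - S2[a - 1] - s * s / (b - a + 1);
    return v > 0.0 ? v : 0.0;
  };

  // Rolling cost rows (prev = k-1 segments, cur = k segments), indexed by the
  // 1-based end position i; contiguous access keeps the inner loop in cache.
  std::vector<double> prev(n + 1), cur(n + 1);
  IntegerMatrix B(k_max, n);
  NumericVector cost(k_max);
  for (int i = 1; i <= n; ++i) {
    prev[i] = sse(1, i);
    B(0, i - 1) = 0;
  }
  cost[0] = prev[n];
  const double* Sp = S.data();
  const double* S2p = S2.data();
  for (int k = 2; k <= k_max; ++k) {
    for (int i = 1; i < k; ++i) { cur[i] = R_PosInf; B(k - 1, i - 1) = NA_INTEGER; }
    for (int i = k; i <= n; ++i) {
      const double Si = Sp[i], S2i = S2p[i];
      double best = R_PosInf;
      int bestj = -1;
      for (int j = k - 1; j <= i - 1; ++j) {
        const double s = Si - Sp[j];
        double v = S2i - S2p[j] - s * s / (i - j);
        if (v < 0.0) v = 0.0;
        const double c = prev[j] + v;
        if (c < best) { best = c; bestj = j; }
      }
      cur[i] = best;
      B(k - 1, i - 1) = bestj;
    }
    cost[k - 1] = cur[n];
    std::swap(prev, cur);
  }
  return List::create(_["cost"] = cost, _["back"] = B);
}

// Backtrack the optimal k-segmentation: returns 1-based inclusive segment
// boundaries as an integer matrix with columns (first, last).
// [[Rcpp::export]]
IntegerMatrix dp_backtrack(IntegerMatrix back, int k, int n) {
  IntegerMatrix seg(k, 2);
  int i = n;
  for (int kk = k; kk >= 1; --kk) {
    int j = back(kk - 1, i - 1);
    seg(kk - 1, 0) = j + 1;
    seg(kk - 1, 1) = i;
    i = j;
  }
  return seg;
}
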