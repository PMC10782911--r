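#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <numeric>
#include <vector>
using namespace Rcpp;

// Count tied pairs sum t*(t-1)/2 over runs of equal values in a sorted vector.
static double tied_pairs(const std::vector<double>& v) {
  double t = 0;
  size_t i = 0;
  while (i < v.size()) {
    size_t j = i;
    while (j < v.size() && v[j] == v[i]) ++j;
    double c = (double)(j - i);
    t += c * (c - 1) / 2;
    i = j;
  }
  return t;
}

// Bottom-up merge sort counting the number of discordant swaps (inversions).
static double merge_inversions(std::vector<double>& a, std::vector<double>& buf) {
  size_t n = a.size();
  double inv = 0;
  for (size_t width = 1; width < n; width *= 2) {
    for (size_t lo = 0; lo < n; lo += 2 * width) {
      size_t mid = std::min(lo + width, n), end = std::min(lo + 2 * width, n);
      if (mid >= end) continue;
      size_t l = lo, r = mid, k = lo;
      while (l < mid && r < end) {
        if (a[l] <= a[r]) buf[k++] = a[l++];
        else { inv += (double)(mid - l); buf[k++] = a[r++]; }
      }
      while (l < mid) buf[k++] = a[l++];
      while (r < end) buf[k++] = a[r++];
      std::copy(buf.begin() + lo, buf.begin() + end, a.begin() + lo);
    }
  }
  return inv;
}

// Kendall tau-b of x against every column of Y via Knight's O(n log n)
// algorithm (sort by x, then count exchanges needed to sort y), with the
// standard tie corrections: tau_b = (P - Q) / sqrt((n0 - n1)(n0 - n2)).
// [[Rcpp::export(name = ".kendall_tau")]]
NumericVector kendall_tau(NumericVector x, NumericMatrix Y) {
  const int n = x.size();
  if (Y.nrow() != n) stop("x and Y must have the same number of observations.");
  const int G = Y.ncol();
  NumericVector tau(G);

  // order by x once (stable); record boundaries of tied-x groups
  std::vector<int> ord(n);
  std::iota(ord.begin(), ord.end(), 0);
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return x[a] < x[b]; });
  std::vector<size_t> grp_start;
  grp_start.push_back(0);
  for (int i = 1; i < n; ++i)
    if (x[ord[i]] != x[ord[i - 1]]) grp_start.push_back(i);
  grp_start.push_back(n);

  double n0 = (double)n * (n - 1) / 2;
  double xtie = 0;
  for (size_t g = 0; g + 1 < grp_start.size(); ++g) {
    double c = (double)(grp_start[g + 1] - grp_start[g]);
    xtie += c * (c - 1) / 2;
  }

  std::vector<double> y(n), ysort(n), buf(n);
  for (int j = 0; j < G; ++j) {
    for (int i = 0; i < n; ++i) y[i] = Y(ord[i], j);
    // sort y within tied-x groups so within-group pairs are not counted as swaps
    double xytie = 0;
    for (size_t g = 0; g + 1 < grp_start.size(); ++g) {
      std::sort(y.begin() + grp_start[g], y.begin() + grp_start[g + 1]);
      size_t i = grp_start[g];
      while (i < grp_start[g + 1]) {
        size_t jj = i;
        while (jj < grp_start[g + 1] && y[jj] == y[i]) ++jj;
        double c = (double)(jj - i);
        xytie += c * (c - 1) / 2;
        i = jj;
      }
    }
    ysort = y;
    std::sort(ysort.begin(), ysort.end());
    double ytie = tied_pairs(ysort);
    double dis = merge_inversions(y, buf);
    double num = n0 - xtie - ytie + xytie - 2 * dis;
    double den = std::sqrt((n0 - xtie) * (n0 - ytie));
    tau[j] = den > 0 ? num / den : NA_REAL;
  }
  return tau;
}
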