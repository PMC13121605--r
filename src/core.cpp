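#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// 1-D squared distance transform (Felzenszwalb & Huttenlocher), exact.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -1e30;
  z[1] = 1e30;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = 1e30;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < (double)q) k++;
    double dq = (double)q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact squared Euclidean distance to the nearest true pixel.
// mask: logical matrix; returns numeric matrix of squared distances
// (integer-valued); all entries INF-coded as R_PosInf when mask is empty.
// [[Rcpp::export]]
NumericMatrix edt_sq_cpp(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double BIG = 1e30;
  NumericMatrix out(nr, nc);
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  // pass 1: columns
  for (int j = 0; j < nc; j++) {
    for (int i = 0; i < nr; i++) f[i] = mask(i, j) ? 0.0 : BIG;
    dt1d(f, d, nr);
    for (int i = 0; i < nr; i++) out(i, j) = d[i];
  }
  // pass 2: rows
  for (int i = 0; i < nr; i++) {
    for (int j = 0; j < nc; j++) f[j] = out(i, j);
    dt1d(f, d, nc);
    for (int j = 0; j < nc; j++) out(i, j) = (d[j] >= BIG) ? R_PosInf : d[j];
  }
  return out;
}

// 8-connectivity component labeling by flood fill; labels 1..n, 0 = background.
// [[Rcpp::export]]
IntegerMatrix label_cc8_cpp(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int j0 = 0; j0 < nc; j0++) {
    for (int i0 = 0; i0 < nr; i0++) {
      if (!mask(i0, j0) || lab(i0, j0)) continue;
      next++;
      stack.push_back(i0 + j0 * nr);
      lab(i0, j0) = next;
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int i = p % nr, j = p / nr;
        for (int dj = -1; dj <= 1; dj++) {
          for (int di = -1; di <= 1; di++) {
            if (!di && !dj) continue;
            int ii = i + di, jj = j + dj;
            if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
            if (mask(ii, jj) && !lab(ii, jj)) {
              lab(ii, jj) = next;
              stack.push_back(ii + jj * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Brute-force k nearest neighbors (Euclidean), ties broken by row index.
// Returns 1-based n x k index matrix; self excluded.
// [[Rcpp::export]]
IntegerMatrix knn_index_cpp(const NumericMatrix& x, const int k) {
  const int n = x.nrow(), p = x.ncol();
  IntegerMatrix idx(n, k);
  std::vector<std::pair<double, int> > cand(n);
  for (int i = 0; i < n; i++) {
    for (int j = 0; j < n; j++) {
      double d2 = 0.0;
      for (int c = 0; c < p; c++) {
        double dd = x(i, c) - x(j, c);
        d2 += dd * dd;
      }
      cand[j] = std::make_pair(d2, j);
    }
    cand[i].first = R_PosInf;  // exclude self
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
    for (int m = 0; m < k; m++) idx(i, m) = cand[m].second + 1;
  }
  return idx;
}
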