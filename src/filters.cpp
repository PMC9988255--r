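#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Whole-sample symmetric reflection (mirror about the edge pixel, the
// edge itself is not duplicated): for n = 5, indices map as
// -2 -1 0 1 2 3 4 5 6  ->  2 1 0 1 2 3 4 3 2.
static inline int reflect_index(int i, int n) {
  if (n == 1) return 0;
  const int p = 2 * (n - 1);
  int m = i % p;
  if (m < 0) m += p;
  return (m >= n) ? (p - m) : m;
}

// [[Rcpp::export]]
NumericMatrix median_disk_cpp(const NumericMatrix& x, int radius) {
  const int nr = x.nrow(), nc = x.ncol();
  // disk neighborhood offsets (dx^2 + dy^2 <= r^2)
  std::vector<int> dr, dc;
  for (int a = -radius; a <= radius; ++a)
    for (int b = -radius; b <= radius; ++b)
      if (a * a + b * b <= radius * radius) { dr.push_back(a); dc.push_back(b); }
  const int k = (int) dr.size();
  NumericMatrix out(nr, nc);
  std::vector<double> buf(k);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      for (int t = 0; t < k; ++t) {
        const int ri = reflect_index(i + dr[t], nr);
        const int cj = reflect_index(j + dc[t], nc);
        buf[t] = x(ri, cj);
      }
      std::nth_element(buf.begin(), buf.begin() + k / 2, buf.end());
      out(i, j) = buf[k / 2];
    }
  }
  return out;
}

// Separable convolution with a symmetric 1-D kernel (length 2h+1),
// mirrored borders on both axes.
// [[Rcpp::export]]
NumericMatrix sep_conv_cpp(const NumericMatrix& x, const NumericVector& kernel) {
  const int nr = x.nrow(), nc = x.ncol();
  const int k = kernel.size();
  const int h = (k - 1) / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // rows (vertical pass)
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int t = -h; t <= h; ++t)
        s += kernel[t + h] * x(reflect_index(i + t, nr), j);
      tmp(i, j) = s;
    }
  // columns (horizontal pass)
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int t = -h; t <= h; ++t)
        s += kernel[t + h] * tmp(i, reflect_index(j + t, nc));
      out(i, j) = s;
    }
  return out;
}
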