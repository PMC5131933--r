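#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// wrapped difference into (-pi, pi] for inputs already in (-pi, pi]
static inline double wdiff(double a, double b) {
  double d = a - b;
  if (d > M_PI) d -= 2.0 * M_PI;
  else if (d <= -M_PI) d += 2.0 * M_PI;
  return d;
}

// winding numbers of all pixels at the given border margin: sum of wrapped
// differences along the closed 8-neighbor loop (start east, traversed in
// the sense of increasing atan2(row - r0, col - c0)), divided by 2 pi.
// [[Rcpp::export]]
IntegerMatrix winding_field_cpp(NumericMatrix ph, int margin) {
  const int H = ph.nrow(), W = ph.ncol(), m = margin;
  const int dr[9] = {0, 1, 1, 1, 0, -1, -1, -1, 0};
  const int dc[9] = {1, 1, 0, -1, -1, -1, 0, 1, 1};
  IntegerMatrix w(H - 2 * m, W - 2 * m);
  for (int c = m; c < W - m; ++c) {
    for (int r = m; r < H - m; ++r) {
      double tot = 0.0;
      double prev = ph(r + dr[0], c + dc[0]);
      for (int k = 1; k < 9; ++k) {
        double cur = ph(r + dr[k], c + dc[k]);
        tot += wdiff(cur, prev);
        prev = cur;
      }
      w(r - m, c - m) = (int)std::lround(tot / (2.0 * M_PI));
    }
  }
  return w;
}

// 1-based linear indices of pixels whose raw phase difference
// next - prev falls below the threshold M
// [[Rcpp::export]]
IntegerVector lc_hits_cpp(NumericMatrix prev, NumericMatrix nxt, double M) {
  const R_xlen_t n = prev.size();
  std::vector<int> hits;
  const double* a = prev.begin();
  const double* b = nxt.begin();
  for (R_xlen_t i = 0; i < n; ++i)
    if (b[i] - a[i] < M) hits.push_back((int)(i + 1));
  return wrap(hits);
}
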