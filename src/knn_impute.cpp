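#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// KNN imputation.
// For each row with missing cells: distance to every other row is the mean
// squared difference over mutually observed columns (undefined -> +Inf).
// For each missing cell, donors are the k nearest rows that observe that
// column; ties broken toward the lower row index (strict '<' during
// insertion keeps the earlier candidate).  Observed cells are untouched.
//
// Data are copied into a row-major buffer (missing encoded as a sentinel
// checked by value, avoiding ISNAN in the hot loop) so the donor scan is
// cache-friendly: the dominant cost is n_incomplete * n * p.
// donors: 0-based indices of candidate donor rows (typically all rows).
// [[Rcpp::export]]
NumericMatrix knn_impute_cpp(NumericMatrix x, int k, IntegerVector donors) {
  const int n = x.nrow(), p = x.ncol();
  const int nd = donors.size();
  NumericMatrix out = clone(x);

  // row-major copy with observation mask
  std::vector<double> v((size_t)n * p);
  std::vector<unsigned char> ob((size_t)n * p);
  std::vector<double> colMean(p, 0.0);
  std::vector<int> colCnt(p, 0);
  for (int j = 0; j < p; ++j) {
    const double *col = &x(0, j);
    for (int i = 0; i < n; ++i) {
      double val = col[i];
      bool o = !ISNAN(val);
      v[(size_t)i * p + j] = o ? val : 0.0;
      ob[(size_t)i * p + j] = o;
      if (o) { colMean[j] += val; ++colCnt[j]; }
    }
  }
  for (int j = 0; j < p; ++j)
    colMean[j] = colCnt[j] > 0 ? colMean[j] / colCnt[j] : 0.0;

  std::vector<int> todo;
  for (int i = 0; i < n; ++i) {
    const unsigned char *oi = &ob[(size_t)i * p];
    for (int j = 0; j < p; ++j) if (!oi[j]) { todo.push_back(i); break; }
  }

  std::vector<double> dist(nd);
  std::vector<int> best(k + 1);
  std::vector<double> bd(k + 1);

  for (size_t t = 0; t < todo.size(); ++t) {
    const int i = todo[t];
    const double *xi = &v[(size_t)i * p];
    const unsigned char *oi = &ob[(size_t)i * p];

    for (int di = 0; di < nd; ++di) {
      const int r = donors[di];
      if (r == i) { dist[di] = R_PosInf; continue; }
      const double *xr = &v[(size_t)r * p];
      const unsigned char *orr = &ob[(size_t)r * p];
      double s = 0.0; int shared = 0;
      for (int j = 0; j < p; ++j) {
        // both observed: indicator product avoids branching
        int m = oi[j] & orr[j];
        double d = (xi[j] - xr[j]) * m;
        s += d * d;
        shared += m;
      }
      dist[di] = shared > 0 ? s / shared : R_PosInf;
    }

    for (int j = 0; j < p; ++j) {
      if (oi[j]) continue;
      int used = 0;
      for (int di = 0; di < nd; ++di) {
        const int r = donors[di];
        if (!ob[(size_t)r * p + j]) continue;
        double d = dist[di];
        if (!R_FINITE(d)) continue;
        if (used < k || d < bd[used - 1]) {
          int pos = used < k ? used : k - 1;
          if (used < k) ++used;
          // insertion with strict '<': equal distances keep earlier rows
          while (pos > 0 && d < bd[pos - 1]) {
            bd[pos] = bd[pos - 1]; best[pos] = best[pos - 1];
            --pos;
          }
          bd[pos] = d; best[pos] = r;
        }
      }
      if (used == 0) {
        out(i, j) = colMean[j];
      } else {
        double s = 0.0;
        for (int b = 0; b < used; ++b)
          s += v[(size_t)best[b] * p + j];
        out(i, j) = s / used;
      }
    }
  }
  return out;
}
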