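#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Maximal information coefficient.
//
// For a grid shape (l columns on the x-axis, q rows on the y-axis) with
// l * q <= B(m) = floor(m^alpha), the y-axis is equipartitioned (equal
// frequency, ties kept together) and the x-axis cut points are optimized by
// dynamic programming over "clumps" (maximal runs of points that any optimal
// partition keeps together). Mutual information decomposes as
//   MI = H(rows) + sum_cols j(col) / n,  j(col) = sum_r n_cr * log(n_cr / n_c)
// so the column term is additive and the DP over clump boundaries is exact
// for partitions restricted to clump edges. The normalized value
// MI / log(min(l, q)) is maximized over both grid orientations and all
// admissible shapes. `cfac` bounds the number of superclumps at cfac * l
// (cfac <= 0 disables the superclump cap; used by the test oracle).

static inline double xlogx(double v) { return v > 0.0 ? v * std::log(v) : 0.0; }

// equal-frequency row assignment of y into (at most) q rows, ties together;
// input y need not be sorted. Returns 0-based row ids per point.
static std::vector<int> equipartition(const std::vector<double> &y, int q) {
  int n = (int)y.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return y[a] < y[b]; });
  std::vector<int> row(n, 0);
  int r = 0, i = 0;
  double target = (double)n / q;
  int assigned = 0;
  while (i < n) {
    int j = i;
    while (j < n && y[ord[j]] == y[ord[i]]) ++j;  // tie run [i, j)
    int runlen = j - i;
    // start a new row if the current one is non-empty and closer to target
    // without the run than with it (and rows remain)
    if (assigned > 0 && r < q - 1) {
      double with_run = std::fabs(assigned + runlen - target);
      double without = std::fabs(assigned - target);
      if (with_run >= without) {
        ++r;
        assigned = 0;
      }
    }
    for (int t = i; t < j; ++t) row[ord[t]] = r;
    assigned += runlen;
    i = j;
  }
  return row;
}

// clump boundaries over points sorted by x: x-ties are inseparable; adjacent
// x-tie groups wholly in the same row merge into one clump. Returns
// cumulative point counts c_0 = 0 < c_1 < ... < c_P = n.
static std::vector<int> clumps(const std::vector<double> &xs,
                               const std::vector<int> &rows_sorted) {
  int n = (int)xs.size();
  std::vector<int> cum;
  cum.push_back(0);
  int i = 0;
  int prev_row = -2;  // row label of previous group; -1 means mixed
  while (i < n) {
    int j = i;
    while (j < n && xs[j] == xs[i]) ++j;  // x-tie group [i, j)
    int grp_row = rows_sorted[i];
    for (int t = i; t < j; ++t)
      if (rows_sorted[t] != grp_row) { grp_row = -1; break; }
    bool merge = (grp_row >= 0 && grp_row == prev_row);
    if (merge) {
      cum.back() = j;
    } else {
      cum.push_back(j);
    }
    prev_row = grp_row;
    i = j;
  }
  return cum;
}

// cap the number of clumps at khat by merging (equal-frequency over points,
// clump boundaries preserved)
static std::vector<int> superclumps(const std::vector<int> &cum, int n,
                                    int khat) {
  int P = (int)cum.size() - 1;
  if (P <= khat) return cum;
  std::vector<int> out;
  out.push_back(0);
  double target = (double)n / khat;
  double next_cut = target;
  for (int j = 1; j <= P; ++j) {
    if (j == P || cum[j] >= next_cut - 1e-9) {
      out.push_back(cum[j]);
      while (next_cut <= cum[j] + 1e-9) next_cut += target;
    }
  }
  return out;
}

// best normalized MI over shapes with this row count q, x-axis optimized.
// Updates `best`.
static void optimize_axis(const std::vector<double> &xs_sorted_by_x,
                          const std::vector<int> &rows_sorted_by_x,
                          int q, int lmax, double cfac, double hq,
                          const std::vector<double> &logmin_row,
                          double *best) {
  int n = (int)xs_sorted_by_x.size();
  std::vector<int> cum = clumps(xs_sorted_by_x, rows_sorted_by_x);
  if (cfac > 0) {
    int khat = std::max(1, (int)(cfac * lmax));
    cum = superclumps(cum, n, khat);
  }
  int P = (int)cum.size() - 1;
  if (P < 2) return;

  // cumulative row histogram at clump boundaries: rowcum[j*q + r]
  std::vector<int> rowcum((P + 1) * q, 0);
  for (int j = 1; j <= P; ++j) {
    for (int r = 0; r < q; ++r) rowcum[j * q + r] = rowcum[(j - 1) * q + r];
    for (int t = cum[j - 1]; t < cum[j]; ++t) ++rowcum[j * q + rows_sorted_by_x[t]];
  }
  // column contribution j(col) for span (s, t]
  std::vector<double> colJ((P + 1) * (P + 1), 0.0);
  for (int s = 0; s < P; ++s) {
    for (int t = s + 1; t <= P; ++t) {
      double tot = cum[t] - cum[s];
      double acc = 0.0;
      for (int r = 0; r < q; ++r)
        acc += xlogx((double)(rowcum[t * q + r] - rowcum[s * q + r]));
      colJ[s * (P + 1) + t] = acc - xlogx(tot);
    }
  }
  int L = std::min(lmax, P);
  // dp[t] for current column count; base: 1 column over (0, t]
  std::vector<double> dp(P + 1, -1e300), ndp(P + 1);
  for (int t = 1; t <= P; ++t) dp[t] = colJ[t];  // colJ[0*(P+1)+t]
  for (int l = 2; l <= L; ++l) {
    for (int t = 0; t <= P; ++t) ndp[t] = -1e300;
    for (int t = l; t <= P; ++t) {
      double m = -1e300;
      for (int s = l - 1; s < t; ++s) {
        double v = dp[s] + colJ[s * (P + 1) + t];
        if (v > m) m = v;
      }
      ndp[t] = m;
    }
    dp.swap(ndp);
    double mi = hq + dp[P] / n;
    double val = mi / logmin_row[std::min(l, q)];
    if (val > *best) *best = val;
  }
}

static double mic_pair(std::vector<double> x, std::vector<double> y,
                       double alpha, double cfac) {
  int n = (int)x.size();
  int B = std::max(4, (int)std::floor(std::pow((double)n, alpha)));
  double best = 0.0;
  std::vector<double> logmin(B + 2, 1.0);
  for (int v = 2; v < (int)logmin.size(); ++v) logmin[v] = std::log((double)v);

  for (int orient = 0; orient < 2; ++orient) {
    const std::vector<double> &xv = orient == 0 ? x : y;
    const std::vector<double> &yv = orient == 0 ? y : x;
    // sort points by x once
    std::vector<int> ord(n);
    for (int i = 0; i < n; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return xv[a] < xv[b]; });
    std::vector<double> xs(n);
    for (int i = 0; i < n; ++i) xs[i] = xv[ord[i]];
    for (int q = 2; q <= B / 2; ++q) {
      int lmax = B / q;
      if (lmax < 2) break;
      std::vector<int> row_all = equipartition(yv, q);
      std::vector<int> rows_sorted(n);
      for (int i = 0; i < n; ++i) rows_sorted[i] = row_all[ord[i]];
      // row marginal entropy
      std::vector<int> cnt(q, 0);
      for (int i = 0; i < n; ++i) ++cnt[rows_sorted[i]];
      double hq = 0.0;
      for (int r = 0; r < q; ++r)
        if (cnt[r] > 0) {
          double p = (double)cnt[r] / n;
          hq -= p * std::log(p);
        }
      optimize_axis(xs, rows_sorted, q, lmax, cfac, hq, logmin, &best);
    }
  }
  if (best < 0.0) best = 0.0;
  if (best > 1.0) best = 1.0;
  return best;
}

// [[Rcpp::export(name = ".cpp_mic")]]
double cpp_mic(NumericVector x, NumericVector y, double alpha = 0.6,
               double cfac = 5.0) {
  if (x.size() != y.size()) stop("x and y lengths differ");
  return mic_pair(as<std::vector<double>>(x), as<std::vector<double>>(y),
                  alpha, cfac);
}

// [[Rcpp::export(name = ".cpp_mic_matrix")]]
NumericVector cpp_mic_matrix(NumericMatrix X, NumericVector y,
                             double alpha = 0.6, double cfac = 5.0) {
  int p = X.ncol();
  NumericVector out(p);
  std::vector<double> yv = as<std::vector<double>>(y);
  for (int j = 0; j < p; ++j) {
    NumericMatrix::Column col = X(_, j);
    std::vector<double> xv(col.begin(), col.end());
    out[j] = mic_pair(xv, yv, alpha, cfac);
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_equipartition")]]
IntegerVector cpp_equipartition(NumericVector y, int q) {
  std::vector<int> r = equipartition(as<std::vector<double>>(y), q);
  return IntegerVector(r.begin(), r.end());
}
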