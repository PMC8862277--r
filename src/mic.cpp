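#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Simplified maximal information coefficient.
//
// Searches r x c grids with r, c >= 2 and r * c <= B(n) = max(4, n^alpha).
// One axis is cut into c equal-frequency bins; the partition of the other
// axis into at most r contiguous bins is optimized by dynamic programming
// over equal-frequency superclumps (at most cfactor * rmax of them).
// Both orientations are tried and the larger normalized value kept.
//
// MI is decomposed as
//   n * MI = sum_uv n_uv log n_uv - sum_u n_u log n_u
//            - sum_v n_v log n_v + n log n,
// whose partition-dependent part
//   G = sum_u [ sum_v n_uv log n_uv - n_u log n_u ]
// is additive over the optimized bins, so the DP recursion
//   F(p, t) = max_q F(q, t-1) + g(q+1..p)
// is exact for the superclump boundary set.

static inline double xlogx(double v) {
  return v > 0.0 ? v * std::log(v) : 0.0;
}

// order of idx positions by ascending value, stable
static std::vector<int> order_of(const std::vector<double>& v) {
  std::vector<int> ord(v.size());
  for (size_t i = 0; i < v.size(); ++i) ord[i] = (int)i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return v[a] < v[b]; });
  return ord;
}

// equal-frequency bin id per observation (0..c-1), ties broken by stable
// sort position
static std::vector<int> equipartition(const std::vector<double>& v, int c) {
  int n = (int)v.size();
  std::vector<int> ord = order_of(v);
  std::vector<int> bin(n);
  for (int pos = 0; pos < n; ++pos)
    bin[ord[pos]] = (int)(((long long)pos * c) / n);
  return bin;
}

// best G over partitions of the u axis into at most rmax bins, given the
// fixed v binning; returns best[t] for t = 1..rmax bins
static std::vector<double> optimize_axis(const std::vector<double>& u,
                                         const std::vector<int>& vbin,
                                         int c, int rmax, double cfactor) {
  int n = (int)u.size();
  int s = std::min(n, (int)std::ceil(cfactor * rmax));
  std::vector<int> ord = order_of(u);

  // cumulative per-v counts over the first p superclumps
  // cum[(p) * c + v], p = 0..s
  std::vector<double> cum((size_t)(s + 1) * c, 0.0);
  std::vector<double> cumn(s + 1, 0.0);
  int pos = 0;
  for (int p = 1; p <= s; ++p) {
    int upto = (int)(((long long)p * n) / s);  // superclump boundary
    for (int v = 0; v < c; ++v)
      cum[(size_t)p * c + v] = cum[(size_t)(p - 1) * c + v];
    cumn[p] = cumn[p - 1];
    for (; pos < upto; ++pos) {
      cum[(size_t)p * c + vbin[ord[pos]]] += 1.0;
      cumn[p] += 1.0;
    }
  }

  // g(a..b): contribution of one merged bin spanning superclumps a+1..b
  auto g = [&](int a, int b) {
    double tot = cumn[b] - cumn[a];
    double acc = -xlogx(tot);
    for (int v = 0; v < c; ++v)
      acc += xlogx(cum[(size_t)b * c + v] - cum[(size_t)a * c + v]);
    return acc;
  };

  const double NEG = -1e300;
  std::vector<double> prev(s + 1, NEG), curr(s + 1, NEG);
  std::vector<double> best(rmax + 1, NEG);
  for (int p = 1; p <= s; ++p) prev[p] = g(0, p);
  best[1] = prev[s];
  for (int t = 2; t <= rmax; ++t) {
    for (int p = t; p <= s; ++p) {
      double m = NEG;
      for (int q = t - 1; q < p; ++q) {
        double cand = prev[q] + g(q, p);
        if (cand > m) m = cand;
      }
      curr[p] = m;
    }
    best[t] = curr[s];
    std::swap(prev, curr);
    std::fill(curr.begin(), curr.end(), NEG);
  }
  return best;
}

static double mic_core(const std::vector<double>& x,
                       const std::vector<double>& y,
                       double alpha, double cfactor) {
  int n = (int)x.size();
  int B = std::max(4, (int)std::floor(std::pow((double)n, alpha)));
  double n_log_n = (double)n * std::log((double)n);
  double best_mic = 0.0;

  for (int orient = 0; orient < 2; ++orient) {
    const std::vector<double>& u = orient == 0 ? x : y;  // optimized axis
    const std::vector<double>& v = orient == 0 ? y : x;  // equipartitioned
    for (int c = 2; 2 * c <= B; ++c) {
      int rmax = B / c;
      std::vector<int> vbin = equipartition(v, c);
      // fixed marginal term of the equipartitioned axis
      std::vector<double> nv(c, 0.0);
      for (int i = 0; i < n; ++i) nv[vbin[i]] += 1.0;
      double hv_term = 0.0;
      for (int b = 0; b < c; ++b) hv_term += xlogx(nv[b]);
      std::vector<double> best = optimize_axis(u, vbin, c, rmax, cfactor);
      for (int r = 2; r <= rmax; ++r) {
        double n_mi = best[r] - hv_term + n_log_n;
        double mi_bits = (n_mi / n) / std::log(2.0);
        if (mi_bits < 0.0) mi_bits = 0.0;
        double norm = std::log2((double)std::min(r, c));
        double val = mi_bits / norm;
        if (val > 1.0) val = 1.0;
        if (val > best_mic) best_mic = val;
      }
    }
  }
  return best_mic;
}

// [[Rcpp::export]]
double mic_cpp(NumericVector x, NumericVector y, double alpha,
               double max_clumps_factor) {
  std::vector<double> xv(x.begin(), x.end());
  std::vector<double> yv(y.begin(), y.end());
  return mic_core(xv, yv, alpha, max_clumps_factor);
}

// MIC statistics for y permuted by each column of `perms` (1-based)
// [[Rcpp::export]]
NumericVector mic_perm_cpp(NumericVector x, NumericVector y,
                           IntegerMatrix perms, double alpha,
                           double max_clumps_factor) {
  int n = x.size(), m = perms.ncol();
  std::vector<double> xv(x.begin(), x.end());
  std::vector<double> yp(n);
  NumericVector out(m);
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) yp[i] = y[perms(i, j) - 1];
    out[j] = mic_core(xv, yp, alpha, max_clumps_factor);
  }
  return out;
}

// pairwise MIC over rows of a genes x samples matrix
// [[Rcpp::export]]
NumericMatrix mic_matrix_cpp(NumericMatrix expr, double alpha,
                             double max_clumps_factor) {
  int g = expr.nrow(), n = expr.ncol();
  NumericMatrix out(g, g);
  std::vector<std::vector<double>> rows(g, std::vector<double>(n));
  for (int i = 0; i < g; ++i)
    for (int k = 0; k < n; ++k) rows[i][k] = expr(i, k);
  for (int i = 0; i < g; ++i) {
    out(i, i) = 1.0;
    for (int j = i + 1; j < g; ++j) {
      double v = mic_core(rows[i], rows[j], alpha, max_clumps_factor);
      out(i, j) = v;
      out(j, i) = v;
    }
  }
  return out;
}
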