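#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Points are scanned in x-sorted order so the neighbour search can stop as
// soon as the x gap alone exceeds the current best distance; this cuts the
// quadratic scan to the points inside a slab of width 2*d_nn.

struct SortedPts {
  std::vector<double> x, y, z;
  std::vector<int> ord;  // ord[k] = original row of the k-th sorted point
};

static SortedPts sort_by_x(const NumericMatrix& pts) {
  const int n = pts.nrow();
  SortedPts s;
  s.ord.resize(n);
  for (int i = 0; i < n; ++i) s.ord[i] = i;
  std::sort(s.ord.begin(), s.ord.end(),
            [&](int a, int b) { return pts(a, 0) < pts(b, 0); });
  s.x.resize(n); s.y.resize(n); s.z.resize(n);
  for (int k = 0; k < n; ++k) {
    const int i = s.ord[k];
    s.x[k] = pts(i, 0); s.y[k] = pts(i, 1); s.z[k] = pts(i, 2);
  }
  return s;
}

// Nearest-neighbour distance for every point of a 3D pattern.
// [[Rcpp::export]]
NumericVector nn_dist_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  NumericVector out(n, R_PosInf);
  if (n < 2) return out;
  SortedPts s = sort_by_x(pts);
  for (int k = 0; k < n; ++k) {
    double best = R_PosInf;
    const double xk = s.x[k], yk = s.y[k], zk = s.z[k];
    for (int j = k + 1; j < n; ++j) {
      const double dx = s.x[j] - xk;
      if (dx * dx >= best) break;
      const double dy = s.y[j] - yk, dz = s.z[j] - zk;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    for (int j = k - 1; j >= 0; --j) {
      const double dx = xk - s.x[j];
      if (dx * dx >= best) break;
      const double dy = s.y[j] - yk, dz = s.z[j] - zk;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[s.ord[k]] = std::sqrt(best);
  }
  return out;
}

// Distance from each query location to the nearest pattern point.
// [[Rcpp::export]]
NumericVector cross_nn_dist_cpp(NumericMatrix from, NumericMatrix to) {
  const int n = from.nrow(), m = to.nrow();
  NumericVector out(n, R_PosInf);
  if (m == 0) return out;
  SortedPts s = sort_by_x(to);
  for (int i = 0; i < n; ++i) {
    const double xi = from(i, 0), yi = from(i, 1), zi = from(i, 2);
    // first sorted point with x >= xi
    int pos = std::lower_bound(s.x.begin(), s.x.end(), xi) - s.x.begin();
    double best = R_PosInf;
    for (int j = pos; j < m; ++j) {
      const double dx = s.x[j] - xi;
      if (dx * dx >= best) break;
      const double dy = s.y[j] - yi, dz = s.z[j] - zi;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    for (int j = pos - 1; j >= 0; --j) {
      const double dx = xi - s.x[j];
      if (dx * dx >= best) break;
      const double dy = s.y[j] - yi, dz = s.z[j] - zi;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// For each point, the cumulative count of other points within each radius of
// the (sorted, increasing) grid r. Returns an n x length(r) matrix.
// [[Rcpp::export]]
NumericMatrix pair_count_cpp(NumericMatrix pts, NumericVector r) {
  const int n = pts.nrow(), nr = r.size();
  NumericMatrix out(n, nr);
  if (n < 2) return out;
  const double rmax = r[nr - 1], rmax2 = rmax * rmax;
  SortedPts s = sort_by_x(pts);
  std::vector<double> rv(r.begin(), r.end());
  for (int k = 0; k < n; ++k) {
    const double xk = s.x[k], yk = s.y[k], zk = s.z[k];
    const int ik = s.ord[k];
    for (int j = k + 1; j < n; ++j) {
      const double dx = s.x[j] - xk;
      if (dx > rmax) break;
      const double dy = s.y[j] - yk, dz = s.z[j] - zk;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > rmax2) continue;
      const double d = std::sqrt(d2);
      const int bin = std::lower_bound(rv.begin(), rv.end(), d) - rv.begin();
      out(ik, bin) += 1.0;          // symmetric pair: credit both points
      out(s.ord[j], bin) += 1.0;
    }
  }
  for (int i = 0; i < n; ++i)
    for (int b = 1; b < nr; ++b) out(i, b) += out(i, b - 1);
  return out;
}
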