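// Raster / polygon geometry primitives used by mask rasterization and
// contour extraction.

#include <Rcpp.h>
#include <stack>
using namespace Rcpp;

// 8-connected component labels (0 = background) for a logical matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix img) {
  int h = img.nrow(), w = img.ncol();
  IntegerMatrix lab(h, w);
  int next = 0;
  std::stack<std::pair<int, int>> st;
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      if (!img(i, j) || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      st.push({i, j});
      while (!st.empty()) {
        auto [ci, cj] = st.top(); st.pop();
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            int ni = ci + di, nj = cj + dj;
            if (ni < 0 || nj < 0 || ni >= h || nj >= w) continue;
            if (img(ni, nj) && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              st.push({ni, nj});
            }
          }
        }
      }
    }
  }
  return lab;
}

// Even-odd (ray casting) point-in-polygon test for many points at once.
// Points exactly on an edge may land on either side; callers place query
// points away from vertices (pixel centres vs half-integer contours).
// [[Rcpp::export]]
LogicalVector cpp_points_in_polygon(NumericVector px, NumericVector py,
                                    NumericVector vx, NumericVector vy) {
  int n = px.size(), m = vx.size();
  LogicalVector inside(n);
  for (int q = 0; q < n; ++q) {
    double x = px[q], y = py[q];
    bool in = false;
    for (int i = 0, j = m - 1; i < m; j = i++) {
      if (((vy[i] > y) != (vy[j] > y)) &&
          (x < (vx[j] - vx[i]) * (y - vy[i]) / (vy[j] - vy[i]) + vx[i]))
        in = !in;
    }
    inside[q] = in;
  }
  return inside;
}

namespace {
inline double cross3(double ox, double oy, double ax, double ay,
                     double bx, double by) {
  return (ax - ox) * (by - oy) - (ay - oy) * (bx - ox);
}

bool segments_intersect(double ax, double ay, double bx, double by,
                        double cx, double cy, double dx, double dy) {
  double d1 = cross3(cx, cy, dx, dy, ax, ay);
  double d2 = cross3(cx, cy, dx, dy, bx, by);
  double d3 = cross3(ax, ay, bx, by, cx, cy);
  double d4 = cross3(ax, ay, bx, by, dx, dy);
  return ((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0));
}
}  // namespace

// TRUE if the closed polygon has no proper self-intersection between
// non-adjacent edges (O(n^2) with bounding-box prefilter).
// [[Rcpp::export]]
bool cpp_polygon_simple(NumericVector vx, NumericVector vy) {
  int n = vx.size();
  if (n < 3) return false;
  for (int i = 0; i < n; ++i) {
    int i2 = (i + 1) % n;
    double xlo = std::min(vx[i], vx[i2]), xhi = std::max(vx[i], vx[i2]);
    double ylo = std::min(vy[i], vy[i2]), yhi = std::max(vy[i], vy[i2]);
    for (int j = i + 2; j < n; ++j) {
      if (i == 0 && j == n - 1) continue;  // adjacent through closure
      int j2 = (j + 1) % n;
      if (std::max(vx[j], vx[j2]) < xlo || std::min(vx[j], vx[j2]) > xhi ||
          std::max(vy[j], vy[j2]) < ylo || std::min(vy[j], vy[j2]) > yhi)
        continue;
      if (segments_intersect(vx[i], vy[i], vx[i2], vy[i2],
                             vx[j], vy[j], vx[j2], vy[j2]))
        return false;
    }
  }
  return true;
}
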