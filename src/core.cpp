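#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Closed segment vs closed axis-aligned box, by slab clipping. A box is
// occupied only when the intersection has positive length: a segment lying
// exactly on a shared grid edge counts for both adjacent boxes, but a bare
// endpoint or corner touch (a single point, not "a part of the line") does
// not count.
static bool seg_box_intersect(double x0, double y0, double x1, double y1,
                              double bx0, double by0, double bx1, double by1) {
  double tmin = 0.0, tmax = 1.0;
  double p[2] = {x0, y0};
  double d[2] = {x1 - x0, y1 - y0};
  double lo[2] = {bx0, by0};
  double hi[2] = {bx1, by1};
  for (int k = 0; k < 2; ++k) {
    if (d[k] == 0.0) {
      if (p[k] < lo[k] || p[k] > hi[k]) return false;
    } else {
      double t1 = (lo[k] - p[k]) / d[k];
      double t2 = (hi[k] - p[k]) / d[k];
      if (t1 > t2) std::swap(t1, t2);
      if (t1 > tmin) tmin = t1;
      if (t2 < tmax) tmax = t2;
    }
  }
  return tmax - tmin > 1e-12;
}

// Count grid boxes of side `caliber` (grid anchored at (ox, oy)) whose closed
// square intersects the closed polyline (x, y). Exact geometry, no raster.
// [[Rcpp::export]]
int cpp_box_count(NumericVector x, NumericVector y, double caliber,
                  double ox, double oy) {
  int n = x.size();
  if (n < 2) stop("polyline needs at least 2 vertices");
  std::unordered_set<int64_t> occ;
  for (int i = 0; i < n; ++i) {
    int j = (i + 1) % n;
    double x0 = x[i], y0 = y[i], x1 = x[j], y1 = y[j];
    if (x0 == x1 && y0 == y1 && j == 0) continue; // duplicated closing vertex
    double xmin = std::min(x0, x1), xmax = std::max(x0, x1);
    double ymin = std::min(y0, y1), ymax = std::max(y0, y1);
    // candidate cells, widened by one so closed-edge ties are tested
    int ilo = (int)std::floor((xmin - ox) / caliber) - 1;
    int ihi = (int)std::floor((xmax - ox) / caliber) + 1;
    int jlo = (int)std::floor((ymin - oy) / caliber) - 1;
    int jhi = (int)std::floor((ymax - oy) / caliber) + 1;
    for (int ci = ilo; ci <= ihi; ++ci) {
      double bx0 = ox + ci * caliber, bx1 = bx0 + caliber;
      for (int cj = jlo; cj <= jhi; ++cj) {
        double by0 = oy + cj * caliber, by1 = by0 + caliber;
        if (seg_box_intersect(x0, y0, x1, y1, bx0, by0, bx1, by1)) {
          occ.insert(((int64_t)ci << 32) ^ (int64_t)(uint32_t)cj);
        }
      }
    }
  }
  return (int)occ.size();
}

static inline double orient(double ax, double ay, double bx, double by,
                            double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

static inline bool on_seg(double ax, double ay, double bx, double by,
                          double px, double py) {
  return std::min(ax, bx) <= px && px <= std::max(ax, bx) &&
         std::min(ay, by) <= py && py <= std::max(ay, by);
}

static bool seg_seg_intersect(double ax, double ay, double bx, double by,
                              double cx, double cy, double dx, double dy) {
  double d1 = orient(cx, cy, dx, dy, ax, ay);
  double d2 = orient(cx, cy, dx, dy, bx, by);
  double d3 = orient(ax, ay, bx, by, cx, cy);
  double d4 = orient(ax, ay, bx, by, dx, dy);
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return true;
  if (d1 == 0 && on_seg(cx, cy, dx, dy, ax, ay)) return true;
  if (d2 == 0 && on_seg(cx, cy, dx, dy, bx, by)) return true;
  if (d3 == 0 && on_seg(ax, ay, bx, by, cx, cy)) return true;
  if (d4 == 0 && on_seg(ax, ay, bx, by, dx, dy)) return true;
  return false;
}

// TRUE if the closed polyline (no duplicated last vertex) self-intersects.
// Adjacent edges (sharing an endpoint, incl. the closing pair) are skipped.
// [[Rcpp::export]]
bool cpp_self_intersects(NumericVector x, NumericVector y) {
  int n = x.size();
  if (n < 3) return true;
  for (int i = 0; i < n; ++i) {
    int i2 = (i + 1) % n;
    for (int j = i + 1; j < n; ++j) {
      int j2 = (j + 1) % n;
      if (j == i2 || j2 == i) continue; // adjacent edges
      // cheap bounding-interval reject
      if (std::max(x[i], x[i2]) < std::min(x[j], x[j2]) ||
          std::max(x[j], x[j2]) < std::min(x[i], x[i2]) ||
          std::max(y[i], y[i2]) < std::min(y[j], y[j2]) ||
          std::max(y[j], y[j2]) < std::min(y[i], y[i2])) continue;
      if (seg_seg_intersect(x[i], y[i], x[i2], y[i2],
                            x[j], y[j], x[j2], y[j2])) return true;
    }
  }
  return false;
}

// Even-odd scanline fill of a closed polygon given in pixel units (pixel
// centers at integer coordinates, x = column index, y = row index, 0-based).
// Returns a logical matrix [nrow x ncol], TRUE = pixel center inside.
// [[Rcpp::export]]
LogicalMatrix cpp_fill_polygon(NumericVector x, NumericVector y,
                               int nrow, int ncol) {
  int n = x.size();
  LogicalMatrix out(nrow, ncol);
  for (int row = 0; row < nrow; ++row) {
    double yc = (double)row;
    std::vector<double> xs;
    for (int i = 0; i < n; ++i) {
      int j = (i + 1) % n;
      double y0 = y[i], y1 = y[j];
      if ((y0 <= yc && y1 > yc) || (y1 <= yc && y0 > yc)) { // half-open rule
        double t = (yc - y0) / (y1 - y0);
        xs.push_back(x[i] + t * (x[j] - x[i]));
      }
    }
    std::sort(xs.begin(), xs.end());
    for (size_t k = 0; k + 1 < xs.size(); k += 2) {
      int c0 = (int)std::ceil(xs[k] - 1e-9);
      int c1 = (int)std::ceil(xs[k + 1] - 1e-9) - 1; // half-open [a, b)
      if (c0 < 0) c0 = 0;
      if (c1 > ncol - 1) c1 = ncol - 1;
      for (int c = c0; c <= c1; ++c) out(row, c) = true;
    }
  }
  return out;
}

// 4-connected component of TRUE pixels containing (seed_row, seed_col), 1-based.
// [[Rcpp::export]]
LogicalMatrix cpp_flood_fill(LogicalMatrix mask, int seed_row, int seed_col) {
  int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix comp(nr, nc);
  int sr = seed_row - 1, sc = seed_col - 1;
  if (sr < 0 || sr >= nr || sc < 0 || sc >= nc) stop("seed outside image");
  if (!mask(sr, sc)) return comp;
  std::vector<int> stack;
  stack.push_back(sr * nc + sc);
  comp(sr, sc) = true;
  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};
  while (!stack.empty()) {
    int cur = stack.back();
    stack.pop_back();
    int r = cur / nc, c = cur % nc;
    for (int k = 0; k < 4; ++k) {
      int r2 = r + dr[k], c2 = c + dc[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (mask(r2, c2) && !comp(r2, c2)) {
        comp(r2, c2) = true;
        stack.push_back(r2 * nc + c2);
      }
    }
  }
  return comp;
}
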