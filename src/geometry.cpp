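#include <Rcpp.h>
using namespace Rcpp;

// Sutherland-Hodgman clipping of an arbitrary simple subject polygon by a
// CONVEX clip polygon. Both are Nx2 matrices of (x, y) vertices; the clip
// polygon must be counter-clockwise in the stored coordinate frame.
// Returns the clipped polygon (possibly 0 rows).
// [[Rcpp::export]]
NumericMatrix cpp_clip_convex(NumericMatrix subject, NumericMatrix clip) {
  int nc = clip.nrow();
  std::vector<double> inx, iny, outx, outy;
  inx.reserve(subject.nrow() + nc);
  iny.reserve(subject.nrow() + nc);
  for (int i = 0; i < subject.nrow(); ++i) {
    inx.push_back(subject(i, 0));
    iny.push_back(subject(i, 1));
  }
  for (int e = 0; e < nc && !inx.empty(); ++e) {
    double ax = clip(e, 0), ay = clip(e, 1);
    double bx = clip((e + 1) % nc, 0), by = clip((e + 1) % nc, 1);
    double ex = bx - ax, ey = by - ay;
    outx.clear(); outy.clear();
    int n = inx.size();
    for (int i = 0; i < n; ++i) {
      double px = inx[i], py = iny[i];
      double qx = inx[(i + 1) % n], qy = iny[(i + 1) % n];
      // signed side: >= 0 means inside (left of CCW edge)
      double sp = ex * (py - ay) - ey * (px - ax);
      double sq = ex * (qy - ay) - ey * (qx - ax);
      bool pin = sp >= 0.0, qin = sq >= 0.0;
      if (pin) {
        outx.push_back(px); outy.push_back(py);
      }
      if (pin != qin) {
        double t = sp / (sp - sq);
        outx.push_back(px + t * (qx - px));
        outy.push_back(py + t * (qy - py));
      }
    }
    inx = outx; iny = outy;
  }
  NumericMatrix out(inx.size(), 2);
  for (size_t i = 0; i < inx.size(); ++i) {
    out(i, 0) = inx[i];
    out(i, 1) = iny[i];
  }
  return out;
}

// Even-odd (crossing number) point-in-polygon test for many query points
// against one simple polygon (Nx2). Points exactly on an edge may fall on
// either side; callers treat the test as a pixel-center rule.
// [[Rcpp::export]]
LogicalVector cpp_points_in_polygon(NumericVector px, NumericVector py,
                                    NumericMatrix poly) {
  int n = poly.nrow(), m = px.size();
  LogicalVector inside(m);
  for (int k = 0; k < m; ++k) {
    double x = px[k], y = py[k];
    bool in = false;
    for (int i = 0, j = n - 1; i < n; j = i++) {
      double xi = poly(i, 0), yi = poly(i, 1);
      double xj = poly(j, 0), yj = poly(j, 1);
      if (((yi > y) != (yj > y)) &&
          (x < (xj - xi) * (y - yi) / (yj - yi) + xi))
        in = !in;
    }
    inside[k] = in;
  }
  return inside;
}

// Even-odd test for a rectangular grid of pixel centres: xs are the column
// and ys the row coordinates. For each row the polygon's x-crossings with
// the horizontal line are computed once and pixels are classified by how
// many crossings lie to their left. Returns a logical vector over the grid
// in row-major order (x fastest), matching expand-by-row pixel extraction.
// [[Rcpp::export]]
LogicalVector cpp_grid_in_polygon(NumericVector xs, NumericVector ys,
                                  NumericMatrix poly) {
  int nx = xs.size(), ny = ys.size(), n = poly.nrow();
  LogicalVector inside(nx * ny);
  std::vector<double> cross;
  cross.reserve(n);
  for (int r = 0; r < ny; ++r) {
    double y = ys[r];
    cross.clear();
    for (int i = 0, j = n - 1; i < n; j = i++) {
      double yi = poly(i, 1), yj = poly(j, 1);
      if ((yi > y) != (yj > y)) {
        double xi = poly(i, 0), xj = poly(j, 0);
        cross.push_back((xj - xi) * (y - yi) / (yj - yi) + xi);
      }
    }
    std::sort(cross.begin(), cross.end());
    int m = cross.size();
    for (int c = 0; c < nx; ++c) {
      int k = std::upper_bound(cross.begin(), cross.end(), xs[c]) -
              cross.begin();
      inside[r * nx + c] = ((m - k) % 2) == 1;
    }
  }
  return inside;
}

static inline int orient3(double ax, double ay, double bx, double by,
                          double cx, double cy) {
  double v = (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
  if (v > 0) return 1;
  if (v < 0) return -1;
  return 0;
}

static bool point_in_poly(double x, double y, NumericMatrix poly,
                          double ox, double oy) {
  int n = poly.nrow();
  bool in = false;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    double yi = poly(i, 1) + oy, yj = poly(j, 1) + oy;
    if ((yi > y) != (yj > y)) {
      double xi = poly(i, 0) + ox, xj = poly(j, 0) + ox;
      if (x < (xj - xi) * (y - yi) / (yj - yi) + xi) in = !in;
    }
  }
  return in;
}

// Exact interior-overlap test for two simple polygons given with
// translation offsets: true when any edges cross or one polygon contains
// a vertex of the other. Used by the dart-throwing placement after the
// conservative bounding-circle pre-filter.
// [[Rcpp::export]]
bool cpp_polys_overlap(NumericMatrix a, double ax, double ay,
                       NumericMatrix b, double bx, double by) {
  int na = a.nrow(), nb = b.nrow();
  for (int i = 0; i < na; ++i) {
    int i2 = (i + 1) % na;
    double p1x = a(i, 0) + ax, p1y = a(i, 1) + ay;
    double p2x = a(i2, 0) + ax, p2y = a(i2, 1) + ay;
    for (int j = 0; j < nb; ++j) {
      int j2 = (j + 1) % nb;
      double q1x = b(j, 0) + bx, q1y = b(j, 1) + by;
      double q2x = b(j2, 0) + bx, q2y = b(j2, 1) + by;
      int o1 = orient3(p1x, p1y, p2x, p2y, q1x, q1y);
      int o2 = orient3(p1x, p1y, p2x, p2y, q2x, q2y);
      int o3 = orient3(q1x, q1y, q2x, q2y, p1x, p1y);
      int o4 = orient3(q1x, q1y, q2x, q2y, p2x, p2y);
      if (o1 != o2 && o3 != o4) return true;
    }
  }
  if (point_in_poly(a(0, 0) + ax, a(0, 1) + ay, b, bx, by)) return true;
  if (point_in_poly(b(0, 0) + bx, b(0, 1) + by, a, ax, ay)) return true;
  return false;
}

// Do any two of the polygon's non-adjacent edges properly intersect?
// Used to reject self-intersecting (bow-tie) annotation polygons.
// [[Rcpp::export]]
bool cpp_self_intersects(NumericMatrix poly) {
  int n = poly.nrow();
  auto orient = [&](double ax, double ay, double bx, double by,
                    double cx, double cy) {
    double v = (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
    if (v > 0) return 1;
    if (v < 0) return -1;
    return 0;
  };
  auto on_seg = [&](double ax, double ay, double bx, double by,
                    double px2, double py2) {
    return std::min(ax, bx) <= px2 && px2 <= std::max(ax, bx) &&
           std::min(ay, by) <= py2 && py2 <= std::max(ay, by);
  };
  for (int i = 0; i < n; ++i) {
    int i2 = (i + 1) % n;
    for (int j = i + 1; j < n; ++j) {
      int j2 = (j + 1) % n;
      // skip adjacent edges (share a vertex)
      if (i == j || i2 == j || j2 == i) continue;
      double ax = poly(i, 0), ay = poly(i, 1);
      double bx = poly(i2, 0), by = poly(i2, 1);
      double cx = poly(j, 0), cy = poly(j, 1);
      double dx = poly(j2, 0), dy = poly(j2, 1);
      int o1 = orient(ax, ay, bx, by, cx, cy);
      int o2 = orient(ax, ay, bx, by, dx, dy);
      int o3 = orient(cx, cy, dx, dy, ax, ay);
      int o4 = orient(cx, cy, dx, dy, bx, by);
      if (o1 != o2 && o3 != o4) return true;
      if (o1 == 0 && on_seg(ax, ay, bx, by, cx, cy)) return true;
      if (o2 == 0 && on_seg(ax, ay, bx, by, dx, dy)) return true;
      if (o3 == 0 && on_seg(cx, cy, dx, dy, ax, ay)) return true;
      if (o4 == 0 && on_seg(cx, cy, dx, dy, bx, by)) return true;
    }
  }
  return false;
}
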