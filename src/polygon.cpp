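#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exact polygon predicates used by the geometry module. Boundary points are
// treated as inside throughout (filaments may touch the rigid boundary).

static inline double cross3(double ax, double ay, double bx, double by,
                            double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

// tolerance scaled to the polygon's bounding-box diagonal
static double scale_eps(const NumericVector& vx, const NumericVector& vy) {
  double xmin = vx[0], xmax = vx[0], ymin = vy[0], ymax = vy[0];
  for (int i = 1; i < vx.size(); ++i) {
    xmin = std::min(xmin, vx[i]); xmax = std::max(xmax, vx[i]);
    ymin = std::min(ymin, vy[i]); ymax = std::max(ymax, vy[i]);
  }
  double diag = std::hypot(xmax - xmin, ymax - ymin);
  return 1e-9 * std::max(1.0, diag);
}

static bool point_on_edge(double px, double py, double ax, double ay,
                          double bx, double by, double eps) {
  double len = std::hypot(bx - ax, by - ay);
  if (len < eps) return std::hypot(px - ax, py - ay) <= eps;
  if (std::fabs(cross3(ax, ay, bx, by, px, py)) > eps * len) return false;
  double dot = (px - ax) * (bx - ax) + (py - ay) * (by - ay);
  return dot >= -eps * len && dot <= len * len + eps * len;
}

static bool pip(double px, double py, const NumericVector& vx,
                const NumericVector& vy, double eps) {
  int n = vx.size();
  for (int i = 0; i < n; ++i) {
    int j = (i + 1) % n;
    if (point_on_edge(px, py, vx[i], vy[i], vx[j], vy[j], eps)) return true;
  }
  bool inside = false;  // even-odd ray crossing, ray towards +x
  for (int i = 0; i < n; ++i) {
    int j = (i + 1) % n;
    double yi = vy[i], yj = vy[j];
    if ((yi > py) != (yj > py)) {
      double xint = vx[i] + (py - yi) / (yj - yi) * (vx[j] - vx[i]);
      if (px < xint) inside = !inside;
    }
  }
  return inside;
}

// [[Rcpp::export]]
LogicalVector points_in_polygon_cpp(NumericVector px, NumericVector py,
                                    NumericVector vx, NumericVector vy) {
  double eps = scale_eps(vx, vy);
  int m = px.size();
  LogicalVector out(m);
  for (int k = 0; k < m; ++k) out[k] = pip(px[k], py[k], vx, vy, eps);
  return out;
}

static inline int sgn_eps(double v, double eps) {
  return (v > eps) - (v < -eps);
}

// segment fully inside: both endpoints (and three interior guard points)
// inside-or-on-boundary, and no proper crossing of any polygon edge.
// Touching the boundary without crossing is allowed.
static bool seg_inside(double px, double py, double qx, double qy,
                       const NumericVector& vx, const NumericVector& vy,
                       double eps) {
  if (!pip(px, py, vx, vy, eps) || !pip(qx, qy, vx, vy, eps)) return false;
  // guards catch symmetric exits through a vertex, which the proper-crossing
  // test cannot see
  const double ts[3] = {0.25, 0.5, 0.75};
  for (double t : ts)
    if (!pip(px + t * (qx - px), py + t * (qy - py), vx, vy, eps))
      return false;
  int n = vx.size();
  double le = std::hypot(qx - px, qy - py);
  double tol = eps * std::max(1.0, le);
  for (int i = 0; i < n; ++i) {
    int j = (i + 1) % n;
    double ax = vx[i], ay = vy[i], bx = vx[j], by = vy[j];
    int d1 = sgn_eps(cross3(ax, ay, bx, by, px, py), tol);
    int d2 = sgn_eps(cross3(ax, ay, bx, by, qx, qy), tol);
    if (d1 * d2 >= 0) continue;
    int d3 = sgn_eps(cross3(px, py, qx, qy, ax, ay), tol);
    int d4 = sgn_eps(cross3(px, py, qx, qy, bx, by), tol);
    if (d3 * d4 < 0) return false;  // proper crossing
  }
  return true;
}

// [[Rcpp::export]]
LogicalVector segments_inside_cpp(NumericVector px, NumericVector py,
                                  NumericVector qx, NumericVector qy,
                                  NumericVector vx, NumericVector vy) {
  double eps = scale_eps(vx, vy);
  int m = px.size();
  LogicalVector out(m);
  for (int k = 0; k < m; ++k)
    out[k] = seg_inside(px[k], py[k], qx[k], qy[k], vx, vy, eps);
  return out;
}

static bool segs_intersect(double ax, double ay, double bx, double by,
                           double cx, double cy, double dx, double dy,
                           double eps) {
  int d1 = sgn_eps(cross3(cx, cy, dx, dy, ax, ay), eps);
  int d2 = sgn_eps(cross3(cx, cy, dx, dy, bx, by), eps);
  int d3 = sgn_eps(cross3(ax, ay, bx, by, cx, cy), eps);
  int d4 = sgn_eps(cross3(ax, ay, bx, by, dx, dy), eps);
  if (d1 * d2 < 0 && d3 * d4 < 0) return true;
  if (d1 == 0 && point_on_edge(ax, ay, cx, cy, dx, dy, eps)) return true;
  if (d2 == 0 && point_on_edge(bx, by, cx, cy, dx, dy, eps)) return true;
  if (d3 == 0 && point_on_edge(cx, cy, ax, ay, bx, by, eps)) return true;
  if (d4 == 0 && point_on_edge(dx, dy, ax, ay, bx, by, eps)) return true;
  return false;
}

// simple polygon check: no two non-adjacent edges intersect, no zero-length
// edges
// [[Rcpp::export]]
bool polygon_is_simple_cpp(NumericVector vx, NumericVector vy) {
  int n = vx.size();
  double eps = scale_eps(vx, vy);
  for (int i = 0; i < n; ++i) {
    int j = (i + 1) % n;
    if (std::hypot(vx[j] - vx[i], vy[j] - vy[i]) <= eps) return false;
  }
  for (int i = 0; i < n; ++i) {
    int i2 = (i + 1) % n;
    for (int j = i + 1; j < n; ++j) {
      int j2 = (j + 1) % n;
      if (j == i2 || j2 == i) continue;  // adjacent edges share a vertex
      if (segs_intersect(vx[i], vy[i], vx[i2], vy[i2],
                         vx[j], vy[j], vx[j2], vy[j2], eps))
        return false;
    }
  }
  return true;
}

// even-odd containment without the boundary test: adequate for randomly
// sampled points (boundary hits have measure zero)
static inline bool pip_fast(double px, double py, const NumericVector& vx,
                            const NumericVector& vy) {
  int n = vx.size();
  bool inside = false;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    double yi = vy[i], yj = vy[j];
    if ((yi > py) != (yj > py)) {
      double xint = vx[i] + (py - yi) / (yj - yi) * (vx[j] - vx[i]);
      if (px < xint) inside = !inside;
    }
  }
  return inside;
}

// point-sampled segment containment for the Monte-Carlo rejection
// sampler: nsamples points along each segment, early exit on the first
// point outside
// [[Rcpp::export]]
LogicalVector segments_sampled_inside_cpp(NumericVector px, NumericVector py,
                                          NumericVector qx, NumericVector qy,
                                          NumericVector vx, NumericVector vy,
                                          int nsamples) {
  int m = px.size();
  LogicalVector out(m);
  for (int k = 0; k < m; ++k) {
    bool ok = true;
    for (int s = 0; s < nsamples && ok; ++s) {
      double t = (nsamples == 1) ? 0.5 : (double)s / (nsamples - 1);
      ok = pip_fast(px[k] + t * (qx[k] - px[k]),
                    py[k] + t * (qy[k] - py[k]), vx, vy);
    }
    out[k] = ok;
  }
  return out;
}
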