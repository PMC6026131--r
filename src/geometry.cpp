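#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Planar polygon utilities used by the territory module.  Polygons are
// n x 2 matrices of vertices (open ring: last vertex != first); areas are
// unsigned unless noted.  All clipping is done against half-planes, which
// is exact for convex clippers and area-correct (Sutherland-Hodgman) for
// arbitrary simple subject polygons.

typedef std::vector<double> dvec;

static double signedArea(const dvec &x, const dvec &y) {
  const size_t n = x.size();
  if (n < 3) return 0.0;
  double a = 0.0;
  for (size_t i = 0, j = n - 1; i < n; j = i++)
    a += x[j] * y[i] - x[i] * y[j];
  return 0.5 * a;
}

// clip polygon by half-plane {p : a*px + b*py <= c}, in place
static void clipHalfPlane(dvec &x, dvec &y, double a, double b, double c) {
  const size_t n = x.size();
  if (n == 0) return;
  dvec nx, ny;
  nx.reserve(n + 4);
  ny.reserve(n + 4);
  for (size_t i = 0, j = n - 1; i < n; j = i++) {
    const double fj = a * x[j] + b * y[j] - c;
    const double fi = a * x[i] + b * y[i] - c;
    const bool inj = fj <= 0.0, ini = fi <= 0.0;
    if (inj != ini) {
      const double t = fj / (fj - fi);
      nx.push_back(x[j] + t * (x[i] - x[j]));
      ny.push_back(y[j] + t * (y[i] - y[j]));
    }
    if (ini) {
      nx.push_back(x[i]);
      ny.push_back(y[i]);
    }
  }
  x.swap(nx);
  y.swap(ny);
}

static void matToVecs(const NumericMatrix &m, dvec &x, dvec &y) {
  const int n = m.nrow();
  x.resize(n);
  y.resize(n);
  for (int i = 0; i < n; ++i) {
    x[i] = m(i, 0);
    y[i] = m(i, 1);
  }
}

static NumericMatrix vecsToMat(const dvec &x, const dvec &y) {
  NumericMatrix m(x.size(), 2);
  for (size_t i = 0; i < x.size(); ++i) {
    m(i, 0) = x[i];
    m(i, 1) = y[i];
  }
  return m;
}

// [[Rcpp::export]]
double cppPolygonArea(NumericMatrix poly) {
  dvec x, y;
  matToVecs(poly, x, y);
  return std::fabs(signedArea(x, y));
}

// [[Rcpp::export]]
double cppPolygonSignedArea(NumericMatrix poly) {
  dvec x, y;
  matToVecs(poly, x, y);
  return signedArea(x, y);
}

// even-odd ray casting; points on the boundary count as inside
// (within eps perpendicular distance of an edge)
// [[Rcpp::export]]
LogicalVector cppPointsInPolygon(NumericMatrix pts, NumericMatrix poly,
                                 double eps = 1e-12) {
  dvec px, py;
  matToVecs(poly, px, py);
  const size_t n = px.size();
  const int m = pts.nrow();
  LogicalVector out(m);
  for (int k = 0; k < m; ++k) {
    const double qx = pts(k, 0), qy = pts(k, 1);
    bool inside = false, boundary = false;
    for (size_t i = 0, j = n - 1; i < n; j = i++) {
      const double xi = px[i], yi = py[i], xj = px[j], yj = py[j];
      // boundary check: distance from q to segment (j,i)
      const double dx = xi - xj, dy = yi - yj;
      const double L2 = dx * dx + dy * dy;
      double t = L2 > 0 ? ((qx - xj) * dx + (qy - yj) * dy) / L2 : 0.0;
      t = std::max(0.0, std::min(1.0, t));
      const double ex = qx - (xj + t * dx), ey = qy - (yj + t * dy);
      if (ex * ex + ey * ey <= eps * eps) boundary = true;
      if (((yi > qy) != (yj > qy)) &&
          (qx < (xj - xi) * (qy - yi) / (yj - yi) + xi))
        inside = !inside;
    }
    out[k] = inside || boundary;
  }
  return out;
}

// Sutherland-Hodgman: clip arbitrary simple `subject` against a convex
// `clipper` (any vertex order; reoriented CCW internally).  Returns the
// clipped polygon (possibly with degenerate bridging edges, which do not
// affect the shoelace area).
// [[Rcpp::export]]
NumericMatrix cppClipToConvex(NumericMatrix subject, NumericMatrix clipper) {
  dvec sx, sy, cx, cy;
  matToVecs(subject, sx, sy);
  matToVecs(clipper, cx, cy);
  if (signedArea(cx, cy) < 0) { // reorient CCW
    std::reverse(cx.begin(), cx.end());
    std::reverse(cy.begin(), cy.end());
  }
  const size_t n = cx.size();
  for (size_t i = 0, j = n - 1; i < n && !sx.empty(); j = i++) {
    // inside = left of directed edge j->i : cross((i-j),(p-j)) >= 0
    // i.e. -(yi-yj)*px + (xi-xj)*py <= xj*(yi... derive: keep a*px+b*py<=c
    const double a = cy[i] - cy[j];
    const double b = -(cx[i] - cx[j]);
    const double c = a * cx[j] + b * cy[j];
    clipHalfPlane(sx, sy, a, b, c);
  }
  return vecsToMat(sx, sy);
}

// Voronoi cells of `seeds` clipped to convex polygon `slab`.  Cell i is the
// slab clipped by the perpendicular bisector half-plane against every other
// seed; seeds are visited in order of increasing distance and clipping stops
// once half the distance to the next seed exceeds the cell's circumradius
// about its seed (no further bisector can cut).
// [[Rcpp::export]]
List cppVoronoiCells(NumericMatrix seeds, NumericMatrix slab) {
  const int n = seeds.nrow();
  dvec bx, by;
  matToVecs(slab, bx, by);
  if (signedArea(bx, by) < 0) {
    std::reverse(bx.begin(), bx.end());
    std::reverse(by.begin(), by.end());
  }
  List out(n);
  std::vector<int> ord(n);
  std::vector<double> d2(n);
  for (int i = 0; i < n; ++i) {
    const double six = seeds(i, 0), siy = seeds(i, 1);
    for (int k = 0; k < n; ++k) {
      ord[k] = k;
      const double dx = seeds(k, 0) - six, dy = seeds(k, 1) - siy;
      d2[k] = dx * dx + dy * dy;
    }
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return d2[a] < d2[b]; });
    dvec cx = bx, cy = by;
    for (int kk = 1; kk < n && !cx.empty(); ++kk) {
      const int k = ord[kk];
      // prune: max squared distance from seed i to current cell vertices
      double r2 = 0.0;
      for (size_t v = 0; v < cx.size(); ++v) {
        const double dx = cx[v] - six, dy = cy[v] - siy;
        const double q = dx * dx + dy * dy;
        if (q > r2) r2 = q;
      }
      if (d2[k] > 4.0 * r2) break;
      // bisector half-plane: points nearer to seed i than to seed k
      const double ax = seeds(k, 0) - six, ay = seeds(k, 1) - siy;
      const double c =
          ax * 0.5 * (six + seeds(k, 0)) + ay * 0.5 * (siy + seeds(k, 1));
      clipHalfPlane(cx, cy, ax, ay, c);
    }
    out[i] = vecsToMat(cx, cy);
  }
  return out;
}

// minimum distance from each point to the polygon boundary (edges)
// [[Rcpp::export]]
NumericVector cppDistToBoundary(NumericMatrix pts, NumericMatrix poly) {
  dvec px, py;
  matToVecs(poly, px, py);
  const size_t n = px.size();
  const int m = pts.nrow();
  NumericVector out(m);
  for (int k = 0; k < m; ++k) {
    const double qx = pts(k, 0), qy = pts(k, 1);
    double best = R_PosInf;
    for (size_t i = 0, j = n - 1; i < n; j = i++) {
      const double dx = px[i] - px[j], dy = py[i] - py[j];
      const double L2 = dx * dx + dy * dy;
      double t = L2 > 0 ? ((qx - px[j]) * dx + (qy - py[j]) * dy) / L2 : 0.0;
      t = std::max(0.0, std::min(1.0, t));
      const double ex = qx - (px[j] + t * dx), ey = qy - (py[j] + t * dy);
      const double d = std::sqrt(ex * ex + ey * ey);
      if (d < best) best = d;
    }
    out[k] = best;
  }
  return out;
}
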