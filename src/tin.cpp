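// Bowyer-Watson Delaunay triangulation and TIN surface queries.
// Sized for the thinned ground-candidate sets used by progressive TIN
// densification (hundreds to a few thousand vertices), not for full clouds.
#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

namespace {

struct Tri { int a, b, c; bool alive; };

inline bool in_circumcircle(double ax, double ay, double bx, double by,
                            double cx, double cy, double px, double py) {
  // positive determinant <=> p inside circumcircle of ccw triangle abc
  double adx = ax - px, ady = ay - py;
  double bdx = bx - px, bdy = by - py;
  double cdx = cx - px, cdy = cy - py;
  double ad = adx * adx + ady * ady;
  double bd = bdx * bdx + bdy * bdy;
  double cd = cdx * cdx + cdy * cdy;
  double det = adx * (bdy * cd - bd * cdy)
             - ady * (bdx * cd - bd * cdx)
             + ad  * (bdx * cdy - bdy * cdx);
  return det > 1e-12;
}

inline double orient2d(double ax, double ay, double bx, double by,
                       double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

} // namespace

// Delaunay triangulation of 2-D points; returns an m x 3 matrix of 1-based
// vertex indices. Duplicate coordinates must be removed by the caller.
// [[Rcpp::export]]
IntegerMatrix cpp_delaunay(NumericMatrix xy) {
  int n = xy.nrow();
  if (n < 3) return IntegerMatrix(0, 3);

  std::vector<double> px(n + 3), py(n + 3);
  double xlo = R_PosInf, xhi = R_NegInf, ylo = R_PosInf, yhi = R_NegInf;
  for (int i = 0; i < n; ++i) {
    px[i] = xy(i, 0); py[i] = xy(i, 1);
    xlo = std::min(xlo, px[i]); xhi = std::max(xhi, px[i]);
    ylo = std::min(ylo, py[i]); yhi = std::max(yhi, py[i]);
  }
  double dmax = std::max(xhi - xlo, yhi - ylo);
  if (dmax <= 0) dmax = 1.0;
  double cx = (xlo + xhi) / 2, cy = (ylo + yhi) / 2;
  // super-triangle comfortably containing every point
  px[n]     = cx - 20 * dmax; py[n]     = cy - 10 * dmax;
  px[n + 1] = cx + 20 * dmax; py[n + 1] = cy - 10 * dmax;
  px[n + 2] = cx;             py[n + 2] = cy + 20 * dmax;

  std::vector<Tri> tris;
  tris.push_back({n, n + 1, n + 2, true});

  std::vector<std::pair<int, int>> boundary;
  for (int p = 0; p < n; ++p) {
    boundary.clear();
    // edges of the cavity: edges of bad triangles not shared by two of them
    std::vector<int> bad;
    for (size_t t = 0; t < tris.size(); ++t) {
      if (!tris[t].alive) continue;
      if (in_circumcircle(px[tris[t].a], py[tris[t].a], px[tris[t].b], py[tris[t].b],
                          px[tris[t].c], py[tris[t].c], px[p], py[p]))
        bad.push_back(int(t));
    }
    auto add_edge = [&](int u, int v) {
      for (size_t e = 0; e < boundary.size(); ++e)
        if ((boundary[e].first == v && boundary[e].second == u) ||
            (boundary[e].first == u && boundary[e].second == v)) {
          boundary.erase(boundary.begin() + e);
          return;
        }
      boundary.push_back({u, v});
    };
    for (int t : bad) {
      add_edge(tris[t].a, tris[t].b);
      add_edge(tris[t].b, tris[t].c);
      add_edge(tris[t].c, tris[t].a);
      tris[t].alive = false;
    }
    for (auto& e : boundary) {
      // keep ccw orientation
      int a = e.first, b = e.second, c = p;
      if (orient2d(px[a], py[a], px[b], py[b], px[c], py[c]) < 0) std::swap(a, b);
      tris.push_back({a, b, c, true});
    }
  }

  std::vector<std::array<int, 3>> keep;
  for (auto& t : tris) {
    if (!t.alive) continue;
    if (t.a >= n || t.b >= n || t.c >= n) continue; // touches super-triangle
    keep.push_back({t.a, t.b, t.c});
  }
  IntegerMatrix out(int(keep.size()), 3);
  for (size_t i = 0; i < keep.size(); ++i) {
    out(int(i), 0) = keep[i][0] + 1;
    out(int(i), 1) = keep[i][1] + 1;
    out(int(i), 2) = keep[i][2] + 1;
  }
  return out;
}

// Interpolate TIN surface heights at query points. `vert` is the n x 3 vertex
// matrix, `tris` the 1-based triangle index matrix. Returns the facet height
// and the (1-based) containing-triangle index; NA where the query falls
// outside the triangulation.
// [[Rcpp::export]]
List cpp_tin_height(NumericMatrix vert, IntegerMatrix tris, NumericMatrix query) {
  int nt = tris.nrow(), nq = query.nrow();
  NumericVector h(nq, NA_REAL);
  IntegerVector which(nq, NA_INTEGER);
  if (nt == 0 || nq == 0) return List::create(_["height"] = h, _["triangle"] = which);

  // grid index over triangle bounding boxes
  double xlo = R_PosInf, xhi = R_NegInf, ylo = R_PosInf, yhi = R_NegInf;
  for (int i = 0; i < vert.nrow(); ++i) {
    xlo = std::min(xlo, vert(i, 0)); xhi = std::max(xhi, vert(i, 0));
    ylo = std::min(ylo, vert(i, 1)); yhi = std::max(yhi, vert(i, 1));
  }
  int ncell = std::max(1, int(std::sqrt(double(nt))));
  double cw = std::max((xhi - xlo) / ncell, 1e-9);
  double ch = std::max((yhi - ylo) / ncell, 1e-9);
  std::vector<std::vector<int>> bins(size_t(ncell) * ncell);
  auto bin_of = [&](double x, double y) {
    int ix = std::min(ncell - 1, std::max(0, int((x - xlo) / cw)));
    int iy = std::min(ncell - 1, std::max(0, int((y - ylo) / ch)));
    return iy * ncell + ix;
  };
  for (int t = 0; t < nt; ++t) {
    double txlo = R_PosInf, txhi = R_NegInf, tylo = R_PosInf, tyhi = R_NegInf;
    for (int j = 0; j < 3; ++j) {
      int v = tris(t, j) - 1;
      txlo = std::min(txlo, vert(v, 0)); txhi = std::max(txhi, vert(v, 0));
      tylo = std::min(tylo, vert(v, 1)); tyhi = std::max(tyhi, vert(v, 1));
    }
    int ix0 = std::min(ncell - 1, std::max(0, int((txlo - xlo) / cw)));
    int ix1 = std::min(ncell - 1, std::max(0, int((txhi - xlo) / cw)));
    int iy0 = std::min(ncell - 1, std::max(0, int((tylo - ylo) / ch)));
    int iy1 = std::min(ncell - 1, std::max(0, int((tyhi - ylo) / ch)));
    for (int iy = iy0; iy <= iy1; ++iy)
      for (int ix = ix0; ix <= ix1; ++ix)
        bins[size_t(iy) * ncell + ix].push_back(t);
  }

  const double tol = -1e-9;
  for (int q = 0; q < nq; ++q) {
    double x = query(q, 0), y = query(q, 1);
    if (x < xlo - 1e-9 || x > xhi + 1e-9 || y < ylo - 1e-9 || y > yhi + 1e-9) continue;
    for (int t : bins[size_t(bin_of(x, y))]) {
      int a = tris(t, 0) - 1, b = tris(t, 1) - 1, c = tris(t, 2) - 1;
      double ax = vert(a, 0), ay = vert(a, 1);
      double bx = vert(b, 0), by = vert(b, 1);
      double cx = vert(c, 0), cy = vert(c, 1);
      double area = orient2d(ax, ay, bx, by, cx, cy);
      if (std::fabs(area) < 1e-14) continue;
      double w0 = orient2d(bx, by, cx, cy, x, y) / area;
      double w1 = orient2d(cx, cy, ax, ay, x, y) / area;
      double w2 = orient2d(ax, ay, bx, by, x, y) / area;
      if (w0 >= tol && w1 >= tol && w2 >= tol) {
        h[q] = w0 * vert(a, 2) + w1 * vert(b, 2) + w2 * vert(c, 2);
        which[q] = t + 1;
        break;
      }
    }
  }
  return List::create(_["height"] = h, _["triangle"] = which);
}
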