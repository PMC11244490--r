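// Grid-hash neighbour searches for point clouds.
// A uniform grid keyed on integer cell coordinates backs all queries; point
// counts here (1e4-1e6) and query radii (centimetres to metres) make this
// faster and simpler than a kd-tree for the access patterns the pipeline uses.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

inline int64_t cell_key(int ix, int iy, int iz) {
  // pack three 21-bit signed cell indices into one 64-bit key
  const int64_t B = int64_t(1) << 20;
  return ((int64_t(ix) + B) << 42) | ((int64_t(iy) + B) << 21) | (int64_t(iz) + B);
}

struct Grid3 {
  double cell;
  const double *x, *y, *z;
  int n;
  bool three_d;
  int ixlo, ixhi, iylo, iyhi, izlo, izhi; // occupied cell-index bounds
  std::unordered_map<int64_t, std::vector<int>> cells;

  Grid3(const NumericMatrix& pts, double cell_size) {
    n = pts.nrow();
    three_d = pts.ncol() >= 3;
    x = &pts(0, 0);
    y = &pts(0, 1);
    z = three_d ? &pts(0, 2) : nullptr;
    cell = cell_size;
    cells.reserve(size_t(n));
    ixlo = iylo = izlo = INT_MAX;
    ixhi = iyhi = izhi = INT_MIN;
    for (int i = 0; i < n; ++i) {
      int ix = int(std::floor(x[i] / cell));
      int iy = int(std::floor(y[i] / cell));
      int iz = three_d ? int(std::floor(z[i] / cell)) : 0;
      ixlo = std::min(ixlo, ix); ixhi = std::max(ixhi, ix);
      iylo = std::min(iylo, iy); iyhi = std::max(iyhi, iy);
      izlo = std::min(izlo, iz); izhi = std::max(izhi, iz);
      cells[cell_key(ix, iy, iz)].push_back(i);
    }
  }
  inline int64_t key_of(double px, double py, double pz) const {
    return cell_key(int(std::floor(px / cell)), int(std::floor(py / cell)),
                    int(std::floor(pz / cell)));
  }
  inline double dist2(int i, double px, double py, double pz) const {
    double dx = x[i] - px, dy = y[i] - py;
    double d2 = dx * dx + dy * dy;
    if (three_d) { double dz = z[i] - pz; d2 += dz * dz; }
    return d2;
  }
};

// choose a grid cell size giving a few points per cell
double heuristic_cell(const NumericMatrix& pts) {
  int n = pts.nrow();
  if (n == 0) return 1.0;
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  int d = pts.ncol() >= 3 ? 3 : 2;
  for (int j = 0; j < d; ++j) {
    for (int i = 0; i < n; ++i) {
      double v = pts(i, j);
      if (v < lo[j]) lo[j] = v;
      if (v > hi[j]) hi[j] = v;
    }
  }
  double vol = 1.0;
  for (int j = 0; j < d; ++j) vol *= std::max(hi[j] - lo[j], 1e-9);
  double cell = std::pow(vol * 4.0 / std::max(n, 1), 1.0 / d);
  return std::max(cell, 1e-6);
}

} // namespace

// k nearest neighbours in `ref` for every row of `query` (2- or 3-column
// matrices; both must have the same width). Returns 1-based indices and
// distances, padded with NA when ref has fewer than k points.
// [[Rcpp::export]]
List cpp_knn(NumericMatrix ref, NumericMatrix query, int k) {
  int nq = query.nrow(), nr = ref.nrow();
  IntegerMatrix idx(nq, k);
  NumericMatrix dist(nq, k);
  std::fill(idx.begin(), idx.end(), NA_INTEGER);
  std::fill(dist.begin(), dist.end(), NA_REAL);
  if (nr == 0 || nq == 0 || k <= 0) return List::create(_["idx"] = idx, _["dist"] = dist);

  Grid3 grid(ref, heuristic_cell(ref));
  bool three_d = grid.three_d;
  typedef std::pair<double, int> DI; // (dist2, index), max-heap on dist2
  for (int q = 0; q < nq; ++q) {
    double px = query(q, 0), py = query(q, 1), pz = three_d ? query(q, 2) : 0.0;
    int cx = int(std::floor(px / grid.cell));
    int cy = int(std::floor(py / grid.cell));
    int cz = three_d ? int(std::floor(pz / grid.cell)) : 0;
    std::priority_queue<DI> best;
    // rings beyond this cover no occupied cell, so they cannot add points
    int ring_cap = std::max({std::abs(grid.ixlo - cx), std::abs(grid.ixhi - cx),
                             std::abs(grid.iylo - cy), std::abs(grid.iyhi - cy),
                             std::abs(grid.izlo - cz), std::abs(grid.izhi - cz)});
    for (int ring = 0;; ++ring) {
      // candidates in the shell of cells at Chebyshev distance `ring`,
      // clipped to the occupied part of the grid
      int x0 = std::max(cx - ring, grid.ixlo), x1 = std::min(cx + ring, grid.ixhi);
      int y0 = std::max(cy - ring, grid.iylo), y1 = std::min(cy + ring, grid.iyhi);
      int z0 = three_d ? std::max(cz - ring, grid.izlo) : 0;
      int z1 = three_d ? std::min(cz + ring, grid.izhi) : 0;
      for (int ix = x0; ix <= x1; ++ix)
        for (int iy = y0; iy <= y1; ++iy)
          for (int iz = z0; iz <= z1; ++iz) {
            int cheb = std::max(std::abs(ix - cx), std::abs(iy - cy));
            if (three_d) cheb = std::max(cheb, std::abs(iz - cz));
            if (cheb != ring) continue;
            auto it = grid.cells.find(cell_key(ix, iy, iz));
            if (it == grid.cells.end()) continue;
            for (int i : it->second) {
              double d2 = grid.dist2(i, px, py, pz);
              if (int(best.size()) < k) best.push(DI(d2, i));
              else if (d2 < best.top().first) { best.pop(); best.push(DI(d2, i)); }
            }
          }
      // any point in an unscanned shell (>= ring + 1) lies at least
      // ring * cell away from the query
      double bound = double(ring) * grid.cell;
      if (int(best.size()) >= std::min(k, nr) && best.top().first <= bound * bound)
        break;
      if (ring >= ring_cap && int(best.size()) >= std::min(k, nr))
        break; // every occupied cell has been scanned
      if (ring > 2100000) break; // unreachable guard
    }
    int m = int(best.size());
    for (int j = m - 1; j >= 0; --j) {
      idx(q, j) = best.top().second + 1;
      dist(q, j) = std::sqrt(best.top().first);
      best.pop();
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// DBSCAN on 2-D points. Returns 0 for noise, 1..C for clusters; cluster ids
// follow the order in which their first core point occurs, so labels are
// deterministic for a fixed point order.
// [[Rcpp::export]]
IntegerVector cpp_dbscan(NumericMatrix xy, double eps, int min_pts) {
  int n = xy.nrow();
  IntegerVector labels(n, 0);
  if (n == 0) return labels;
  Grid3 grid(xy, eps);
  double eps2 = eps * eps;

  std::vector<int> neigh;
  auto neighbours = [&](int i) {
    neigh.clear();
    int cx = int(std::floor(grid.x[i] / grid.cell));
    int cy = int(std::floor(grid.y[i] / grid.cell));
    for (int ix = cx - 1; ix <= cx + 1; ++ix)
      for (int iy = cy - 1; iy <= cy + 1; ++iy) {
        auto it = grid.cells.find(cell_key(ix, iy, 0));
        if (it == grid.cells.end()) continue;
        for (int j : it->second)
          if (grid.dist2(j, grid.x[i], grid.y[i], 0.0) <= eps2) neigh.push_back(j);
      }
  };

  std::vector<char> visited(n, 0);
  int cluster = 0;
  std::vector<int> stack;
  for (int i = 0; i < n; ++i) {
    if (visited[i]) continue;
    visited[i] = 1;
    neighbours(i);
    if (int(neigh.size()) < min_pts) continue; // noise unless claimed later
    ++cluster;
    labels[i] = cluster;
    stack.assign(neigh.begin(), neigh.end());
    while (!stack.empty()) {
      int j = stack.back();
      stack.pop_back();
      if (labels[j] == 0) labels[j] = cluster; // border or new core
      if (visited[j]) continue;
      visited[j] = 1;
      neighbours(j);
      if (int(neigh.size()) >= min_pts)
        for (int q : neigh)
          if (!visited[q] || labels[q] == 0) stack.push_back(q);
    }
  }
  return labels;
}

// Top-down vertex-based sweep. `xy` rows must already be sorted by
// descending elevation. Each point is assigned to the existing plant whose
// vertex (seed apex) is horizontally nearest; a point farther than d from
// every vertex becomes the vertex of a new plant. Returns 1-based segment
// labels in the input (sorted) order. The vertex count stays in the
// hundreds, so a linear scan over vertices is fast enough.
// [[Rcpp::export]]
IntegerVector cpp_pcs_sweep(NumericMatrix xy, double d) {
  int n = xy.nrow();
  IntegerVector labels(n, NA_INTEGER);
  if (n == 0) return labels;
  double d2max = d * d;
  const double *x = &xy(0, 0), *y = &xy(0, 1);
  std::vector<double> vx, vy; // vertex positions, index = label - 1
  for (int i = 0; i < n; ++i) {
    int best = -1;
    double bestd2 = R_PosInf;
    for (size_t v = 0; v < vx.size(); ++v) {
      double dx = vx[v] - x[i], dy = vy[v] - y[i];
      double d2 = dx * dx + dy * dy;
      if (d2 < bestd2) { bestd2 = d2; best = int(v); }
    }
    if (best >= 0 && bestd2 <= d2max) {
      labels[i] = best + 1;
    } else {
      vx.push_back(x[i]);
      vy.push_back(y[i]);
      labels[i] = int(vx.size());
    }
  }
  return labels;
}

// Count, per query row, the reference points within `radius` (same width rule
// as cpp_knn). Used for density diagnostics.
// [[Rcpp::export]]
IntegerVector cpp_radius_count(NumericMatrix ref, NumericMatrix query, double radius) {
  int nq = query.nrow();
  IntegerVector out(nq, 0);
  if (ref.nrow() == 0 || nq == 0) return out;
  Grid3 grid(ref, radius);
  bool three_d = grid.three_d;
  double r2 = radius * radius;
  for (int q = 0; q < nq; ++q) {
    double px = query(q, 0), py = query(q, 1), pz = three_d ? query(q, 2) : 0.0;
    int cx = int(std::floor(px / grid.cell));
    int cy = int(std::floor(py / grid.cell));
    int cz = three_d ? int(std::floor(pz / grid.cell)) : 0;
    int zlo = three_d ? cz - 1 : 0, zhi = three_d ? cz + 1 : 0;
    int cnt = 0;
    for (int ix = cx - 1; ix <= cx + 1; ++ix)
      for (int iy = cy - 1; iy <= cy + 1; ++iy)
        for (int iz = zlo; iz <= zhi; ++iz) {
          auto it = grid.cells.find(cell_key(ix, iy, iz));
          if (it == grid.cells.end()) continue;
          for (int i : it->second)
            if (grid.dist2(i, px, py, pz) <= r2) ++cnt;
        }
    out[q] = cnt;
  }
  return out;
}
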