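#ifndef PULSETRACK_CELLLIST_H
#define PULSETRACK_CELLLIST_H

#include <RcppArmadillo.h>
#include <vector>
#include <cmath>
#include <limits>

// Uniform-cell spatial index over a 3-D point set. Queries are exact:
// ring expansion continues until no unscanned cell can beat the current
// best squared distance (bound: a cell at Chebyshev ring r around the
// query's clamped base cell is at least (r-1)*h - off away, where off is
// the distance from the query to the base cell's box).
struct CellList {
  const arma::mat &pts;        // n x 3
  double h;                    // cell edge
  double lo[3];
  int nc[3];                   // cells per axis
  std::vector<int> cell_start; // CSR over cells
  std::vector<int> order;      // point ids sorted by cell

  CellList(const arma::mat &p, double cell) : pts(p), h(cell) {
    const int n = p.n_rows;
    double hi[3];
    for (int a = 0; a < 3; ++a) {
      lo[a] = p.col(a).min();
      hi[a] = p.col(a).max();
      nc[a] = std::max(1, (int)std::floor((hi[a] - lo[a]) / h) + 1);
    }
    const int ncell = nc[0] * nc[1] * nc[2];
    std::vector<int> cnt(ncell + 1, 0), cid(n);
    for (int i = 0; i < n; ++i) {
      cid[i] = cell_of(p(i, 0), p(i, 1), p(i, 2));
      cnt[cid[i] + 1]++;
    }
    for (int c = 0; c < ncell; ++c) cnt[c + 1] += cnt[c];
    cell_start = cnt;
    order.resize(n);
    std::vector<int> fill(cell_start.begin(), cell_start.end() - 1);
    for (int i = 0; i < n; ++i) order[fill[cid[i]]++] = i;
  }

  inline int clampi(int v, int m) const { return v < 0 ? 0 : (v >= m ? m - 1 : v); }

  inline int cell_of(double x, double y, double z) const {
    int ix = clampi((int)std::floor((x - lo[0]) / h), nc[0]);
    int iy = clampi((int)std::floor((y - lo[1]) / h), nc[1]);
    int iz = clampi((int)std::floor((z - lo[2]) / h), nc[2]);
    return ix + nc[0] * (iy + nc[1] * iz);
  }

  // squared distance from point q to the box of cell (ix,iy,iz)
  inline double box_d2(const double q[3], int ix, int iy, int iz) const {
    double d2 = 0.0;
    int idx[3] = {ix, iy, iz};
    for (int a = 0; a < 3; ++a) {
      double b0 = lo[a] + idx[a] * h, b1 = b0 + h;
      double d = q[a] < b0 ? b0 - q[a] : (q[a] > b1 ? q[a] - b1 : 0.0);
      d2 += d * d;
    }
    return d2;
  }

  // exact nearest neighbour: returns index, writes squared distance
  int nearest(const double q[3], double &best_d2) const {
    int bx = clampi((int)std::floor((q[0] - lo[0]) / h), nc[0]);
    int by = clampi((int)std::floor((q[1] - lo[1]) / h), nc[1]);
    int bz = clampi((int)std::floor((q[2] - lo[2]) / h), nc[2]);
    double off2 = box_d2(q, bx, by, bz);
    double off = std::sqrt(off2);
    best_d2 = std::numeric_limits<double>::infinity();
    int best = -1;
    int max_ring = std::max(nc[0], std::max(nc[1], nc[2]));
    for (int r = 0; ; ++r) {
      bool any_cell = false;
      for (int dz = -r; dz <= r; ++dz) {
        int iz = bz + dz;
        if (iz < 0 || iz >= nc[2]) continue;
        for (int dy = -r; dy <= r; ++dy) {
          int iy = by + dy;
          if (iy < 0 || iy >= nc[1]) continue;
          for (int dx = -r; dx <= r; ++dx) {
            if (std::max(std::abs(dx), std::max(std::abs(dy), std::abs(dz))) != r)
              continue; // shell only
            int ix = bx + dx;
            if (ix < 0 || ix >= nc[0]) continue;
            any_cell = true;
            if (box_d2(q, ix, iy, iz) >= best_d2) continue;
            int c = ix + nc[0] * (iy + nc[1] * iz);
            for (int s = cell_start[c]; s < cell_start[c + 1]; ++s) {
              int i = order[s];
              double dxp = pts(i, 0) - q[0], dyp = pts(i, 1) - q[1],
                     dzp = pts(i, 2) - q[2];
              double d2 = dxp * dxp + dyp * dyp + dzp * dzp;
              if (d2 < best_d2) { best_d2 = d2; best = i; }
            }
          }
        }
      }
      double lb = (double)r * h - off; // next ring is at least this far
      if (best >= 0 && lb > 0 && best_d2 <= lb * lb) break;
      if (r > max_ring && !any_cell) break;
    }
    return best;
  }

  // exact k nearest neighbours (k small); fills idx/d2 (sorted ascending)
  int knn(const double q[3], int k, std::vector<int> &idx,
          std::vector<double> &d2) const {
    idx.clear(); d2.clear();
    int bx = clampi((int)std::floor((q[0] - lo[0]) / h), nc[0]);
    int by = clampi((int)std::floor((q[1] - lo[1]) / h), nc[1]);
    int bz = clampi((int)std::floor((q[2] - lo[2]) / h), nc[2]);
    double off = std::sqrt(box_d2(q, bx, by, bz));
    int max_ring = nc[0] + nc[1] + nc[2] + 2;
    for (int r = 0; ; ++r) {
      bool any_cell = false;
      double worst = idx.size() == (size_t)k ? d2.back()
                                             : std::numeric_limits<double>::infinity();
      for (int dz = -r; dz <= r; ++dz) {
        int iz = bz + dz;
        if (iz < 0 || iz >= nc[2]) continue;
        for (int dy = -r; dy <= r; ++dy) {
          int iy = by + dy;
          if (iy < 0 || iy >= nc[1]) continue;
          for (int dx = -r; dx <= r; ++dx) {
            if (std::max(std::abs(dx), std::max(std::abs(dy), std::abs(dz))) != r)
              continue;
            int ix = bx + dx;
            if (ix < 0 || ix >= nc[0]) continue;
            any_cell = true;
            if (idx.size() == (size_t)k && box_d2(q, ix, iy, iz) >= d2.back())
              continue;
            int c = ix + nc[0] * (iy + nc[1] * iz);
            for (int s = cell_start[c]; s < cell_start[c + 1]; ++s) {
              int i = order[s];
              double dxp = pts(i, 0) - q[0], dyp = pts(i, 1) - q[1],
                     dzp = pts(i, 2) - q[2];
              double dd = dxp * dxp + dyp * dyp + dzp * dzp;
              if (idx.size() < (size_t)k || dd < d2.back()) {
                // insertion into sorted short list
                size_t pos = 0;
                while (pos < d2.size() && d2[pos] <= dd) ++pos;
                d2.insert(d2.begin() + pos, dd);
                idx.insert(idx.begin() + pos, i);
                if (d2.size() > (size_t)k) { d2.pop_back(); idx.pop_back(); }
              }
            }
          }
        }
      }
      (void)worst;
      double lb = (double)r * h - off;
      if (idx.size() == (size_t)k && lb > 0 && d2.back() <= lb * lb) break;
      if (r > max_ring && !any_cell) break;
    }
    return (int)idx.size();
  }
};

#endif
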