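// [[Rcpp::depends(RcppArmadillo)]]
#include "celllist.h"
using namespace Rcpp;

// Exact nearest-neighbour distances from each query point to a reference
// point set. Used for null-node classification and stagnation pruning;
// the test oracle is a brute-force distance scan.
// [[Rcpp::export(name = ".cpp_nn_dist")]]
NumericVector cpp_nn_dist(const arma::mat &query, const arma::mat &ref,
                          double cell) {
  if (ref.n_rows == 0) stop("reference point set is empty");
  CellList cl(ref, cell);
  const int n = query.n_rows;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double q[3] = {query(i, 0), query(i, 1), query(i, 2)};
    double d2;
    cl.nearest(q, d2);
    out[i] = std::sqrt(d2);
  }
  return out;
}

// Local-linear least-squares regridding of scattered vector samples onto
// query points: fit v ~ 1 + dx + dy + dz over the k nearest sources
// (coordinates centred at the query, so the intercept is the estimate).
// Reproduces affine fields exactly when the neighbourhood spans 3-D.
// Degenerate neighbourhoods fall back to a ridge, then to the nearest value.
// [[Rcpp::export(name = ".cpp_regrid_lls")]]
arma::mat cpp_regrid_lls(const arma::mat &src, const arma::mat &val,
                         const arma::mat &query, int k, double cell) {
  if (src.n_rows == 0) stop("no flow points");
  if (src.n_rows != val.n_rows) stop("source/value length mismatch");
  const int n = query.n_rows, nc = val.n_cols;
  if ((int)src.n_rows < k) k = src.n_rows;
  CellList cl(src, cell);
  arma::mat out(n, nc, arma::fill::zeros);
  std::vector<int> idx; std::vector<double> d2;
  for (int i = 0; i < n; ++i) {
    double q[3] = {query(i, 0), query(i, 1), query(i, 2)};
    int m = cl.knn(q, k, idx, d2);
    if (m == 0) continue;
    if (m < 4) { out.row(i) = val.row(idx[0]); continue; }
    arma::mat A(m, 4);
    arma::mat b(m, nc);
    for (int j = 0; j < m; ++j) {
      A(j, 0) = 1.0;
      A(j, 1) = src(idx[j], 0) - q[0];
      A(j, 2) = src(idx[j], 1) - q[1];
      A(j, 3) = src(idx[j], 2) - q[2];
      b.row(j) = val.row(idx[j]);
    }
    arma::mat AtA = A.t() * A, Atb = A.t() * b, coef;
    bool ok = arma::solve(coef, AtA, Atb, arma::solve_opts::no_approx);
    if (!ok || !coef.is_finite()) {
      AtA.diag() += 1e-8 * arma::trace(AtA);
      ok = arma::solve(coef, AtA, Atb);
    }
    if (ok && coef.is_finite()) out.row(i) = coef.row(0);
    else out.row(i) = val.row(idx[0]);
  }
  return out;
}

// Trilinear interpolation of a gridded velocity-field time series at
// scattered positions, with linear blending of two bracketing frames.
// Node order is x-fastest (ix + nx*(iy + ny*iz)). Positions outside the
// grid bounding box get zero velocity and inside = FALSE.
// [[Rcpp::export(name = ".cpp_sample_trilinear")]]
List cpp_sample_trilinear(const NumericVector &V, int nx, int ny, int nz,
                          double x0, double y0, double z0, double d,
                          const arma::mat &pos, int f0, int f1, double alpha) {
  const int n = pos.n_rows;
  const R_xlen_t nnodes = (R_xlen_t)nx * ny * nz;
  const R_xlen_t stride_f = nnodes * 3;
  arma::mat out(n, 3, arma::fill::zeros);
  LogicalVector inside(n);
  const double *v = V.begin();
  for (int i = 0; i < n; ++i) {
    double fx = (pos(i, 0) - x0) / d, fy = (pos(i, 1) - y0) / d,
           fz = (pos(i, 2) - z0) / d;
    if (fx < 0 || fy < 0 || fz < 0 || fx > nx - 1 || fy > ny - 1 ||
        fz > nz - 1 || !std::isfinite(fx) || !std::isfinite(fy) ||
        !std::isfinite(fz)) {
      inside[i] = false;
      continue;
    }
    inside[i] = true;
    int ix = std::min((int)fx, nx - 2 < 0 ? 0 : nx - 2);
    int iy = std::min((int)fy, ny - 2 < 0 ? 0 : ny - 2);
    int iz = std::min((int)fz, nz - 2 < 0 ? 0 : nz - 2);
    if (nx == 1) ix = 0;
    if (ny == 1) iy = 0;
    if (nz == 1) iz = 0;
    double tx = fx - ix, ty = fy - iy, tz = fz - iz;
    if (nx == 1) tx = 0;
    if (ny == 1) ty = 0;
    if (nz == 1) tz = 0;
    double w[8] = {(1 - tx) * (1 - ty) * (1 - tz), tx * (1 - ty) * (1 - tz),
                   (1 - tx) * ty * (1 - tz),       tx * ty * (1 - tz),
                   (1 - tx) * (1 - ty) * tz,       tx * (1 - ty) * tz,
                   (1 - tx) * ty * tz,             tx * ty * tz};
    R_xlen_t base[8];
    int c = 0;
    for (int dz = 0; dz <= 1; ++dz)
      for (int dy = 0; dy <= 1; ++dy)
        for (int dx = 0; dx <= 1; ++dx) {
          int jx = std::min(ix + dx, nx - 1), jy = std::min(iy + dy, ny - 1),
              jz = std::min(iz + dz, nz - 1);
          base[c++] = (R_xlen_t)jx + nx * ((R_xlen_t)jy + ny * (R_xlen_t)jz);
        }
    for (int comp = 0; comp < 3; ++comp) {
      double a0 = 0, a1 = 0;
      for (int j = 0; j < 8; ++j) {
        a0 += w[j] * v[f0 * stride_f + comp * nnodes + base[j]];
        a1 += w[j] * v[f1 * stride_f + comp * nnodes + base[j]];
      }
      out(i, comp) = (1 - alpha) * a0 + alpha * a1;
    }
  }
  return List::create(_["v"] = out, _["inside"] = inside);
}
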