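// Voxel-grid kernels: protein occupancy, the 7-direction protein-solvent-
// protein cavity scan, and the probe-energy channel accumulators.  Grids are
// stored flat in R array order: voxel (i,j,k) (0-based) sits at
// i + nx*(j + ny*k); the voxel center is origin + (i+0.5, j+0.5, k+0.5)*h.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline int vidx(int i, int j, int k, const int *d) {
  return i + d[0] * (j + d[1] * k);
}

// [[Rcpp::export]]
LogicalVector occupancy_cpp(IntegerVector dims, NumericVector origin, double h,
                            NumericMatrix pos, NumericVector radius) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  LogicalVector out(d[0] * d[1] * d[2], false);
  for (int a = 0; a < pos.nrow(); ++a) {
    const double r = radius[a], r2 = r * r;
    const double px = pos(a, 0), py = pos(a, 1), pz = pos(a, 2);
    int lo[3], hi[3];
    const double p[3] = {px, py, pz};
    for (int ax = 0; ax < 3; ++ax) {
      lo[ax] = std::max(0, (int)std::floor((p[ax] - r - origin[ax]) / h - 0.5));
      hi[ax] = std::min(d[ax] - 1, (int)std::ceil((p[ax] + r - origin[ax]) / h - 0.5));
    }
    for (int k = lo[2]; k <= hi[2]; ++k) {
      const double dz = origin[2] + (k + 0.5) * h - pz;
      for (int j = lo[1]; j <= hi[1]; ++j) {
        const double dy = origin[1] + (j + 0.5) * h - py;
        for (int i = lo[0]; i <= hi[0]; ++i) {
          const double dx = origin[0] + (i + 0.5) * h - px;
          if (dx * dx + dy * dy + dz * dz <= r2) out[vidx(i, j, k, d)] = true;
        }
      }
    }
  }
  return out;
}

// Seven scan directions: the three axes and the four cube diagonals chosen
// pairwise non-antiparallel.  A solvent run counts only when protein voxels
// bound it on both ends; runs reaching the grid boundary are open to solvent.
// [[Rcpp::export]]
IntegerVector psp_scan_cpp(LogicalVector mask, IntegerVector dims) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  const int n = d[0] * d[1] * d[2];
  IntegerVector out(n, 0);
  const int dirs[7][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1},
                          {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {-1, 1, 1}};
  std::vector<int> run;
  for (int dir = 0; dir < 7; ++dir) {
    const int sx = dirs[dir][0], sy = dirs[dir][1], sz = dirs[dir][2];
    for (int k = 0; k < d[2]; ++k)
      for (int j = 0; j < d[1]; ++j)
        for (int i = 0; i < d[0]; ++i) {
          // line start: predecessor along the direction lies outside the grid
          const int pi = i - sx, pj = j - sy, pk = k - sz;
          if (pi >= 0 && pi < d[0] && pj >= 0 && pj < d[1] && pk >= 0 && pk < d[2])
            continue;
          bool seen_protein = false;
          run.clear();
          int x = i, y = j, z = k;
          while (x >= 0 && x < d[0] && y >= 0 && y < d[1] && z >= 0 && z < d[2]) {
            const int v = vidx(x, y, z, d);
            if (mask[v]) {
              if (seen_protein)
                for (size_t t = 0; t < run.size(); ++t) ++out[run[t]];
              seen_protein = true;
              run.clear();
            } else if (seen_protein) {
              run.push_back(v);
            }
            x += sx; y += sy; z += sz;
          }
        }
  }
  return out;
}

// Sum over atoms of A/r^12 - B/r^6 (per-atom pair coefficients precomputed
// against the probe), zero beyond the cutoff.  r is clamped away from zero so
// that a voxel center coinciding with an atom stays finite.
// [[Rcpp::export]]
NumericVector lj_sum_grid_cpp(IntegerVector dims, NumericVector origin, double h,
                              NumericMatrix pos, NumericVector A, NumericVector B,
                              double cutoff) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  NumericVector out(d[0] * d[1] * d[2], 0.0);
  const double c2 = cutoff * cutoff, rmin2 = 1e-12;
  for (int a = 0; a < pos.nrow(); ++a) {
    const double p[3] = {pos(a, 0), pos(a, 1), pos(a, 2)};
    int lo[3], hi[3];
    for (int ax = 0; ax < 3; ++ax) {
      lo[ax] = std::max(0, (int)std::floor((p[ax] - cutoff - origin[ax]) / h - 0.5));
      hi[ax] = std::min(d[ax] - 1, (int)std::ceil((p[ax] + cutoff - origin[ax]) / h - 0.5));
    }
    for (int k = lo[2]; k <= hi[2]; ++k) {
      const double dz = origin[2] + (k + 0.5) * h - p[2];
      for (int j = lo[1]; j <= hi[1]; ++j) {
        const double dy = origin[1] + (j + 0.5) * h - p[1];
        for (int i = lo[0]; i <= hi[0]; ++i) {
          const double dx = origin[0] + (i + 0.5) * h - p[0];
          double r2 = dx * dx + dy * dy + dz * dz;
          if (r2 > c2) continue;
          if (r2 < rmin2) r2 = rmin2;
          const double r6 = r2 * r2 * r2;
          out[vidx(i, j, k, d)] += A[a] / (r6 * r6) - B[a] / r6;
        }
      }
    }
  }
  return out;
}

// Hydrogen-bond channel: 12-10 potential per (probe atom, protein atom) pair;
// each voxel keeps the candidate with the largest |E|.  CD is (n x 2m):
// columns 2*m_i, 2*m_i+1 hold C and D for probe atom m_i; negative C and D
// mark an ineligible pair.  offsets is (m x 3): probe-atom displacement from
// the voxel center.
// [[Rcpp::export]]
NumericVector hbond_max_grid_cpp(IntegerVector dims, NumericVector origin, double h,
                                 NumericMatrix pos, NumericMatrix CD,
                                 NumericMatrix offsets, double cutoff) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  const int n = d[0] * d[1] * d[2], m = offsets.nrow();
  NumericVector out(n, 0.0);
  std::vector<double> bestabs(n, 0.0);
  const double c2 = cutoff * cutoff, rmin2 = 1e-12;
  for (int a = 0; a < pos.nrow(); ++a) {
    for (int pa = 0; pa < m; ++pa) {
      const double C = CD(a, 2 * pa), D = CD(a, 2 * pa + 1);
      if (C < 0) continue;  // pair cannot hydrogen-bond
      // probe atom reaches atom a when the voxel center is within cutoff of
      // (atom position - probe offset)
      const double p[3] = {pos(a, 0) - offsets(pa, 0), pos(a, 1) - offsets(pa, 1),
                           pos(a, 2) - offsets(pa, 2)};
      int lo[3], hi[3];
      for (int ax = 0; ax < 3; ++ax) {
        lo[ax] = std::max(0, (int)std::floor((p[ax] - cutoff - origin[ax]) / h - 0.5));
        hi[ax] = std::min(d[ax] - 1, (int)std::ceil((p[ax] + cutoff - origin[ax]) / h - 0.5));
      }
      for (int k = lo[2]; k <= hi[2]; ++k) {
        const double dz = origin[2] + (k + 0.5) * h - p[2];
        for (int j = lo[1]; j <= hi[1]; ++j) {
          const double dy = origin[1] + (j + 0.5) * h - p[1];
          for (int i = lo[0]; i <= hi[0]; ++i) {
            const double dx = origin[0] + (i + 0.5) * h - p[0];
            double r2 = dx * dx + dy * dy + dz * dz;
            if (r2 > c2) continue;
            if (r2 < rmin2) r2 = rmin2;
            const double r10 = r2 * r2 * r2 * r2 * r2;
            const double e = C / (r10 * r2) - D / r10;
            const int v = vidx(i, j, k, d);
            if (std::fabs(e) > bestabs[v]) { bestabs[v] = std::fabs(e); out[v] = e; }
          }
        }
      }
    }
  }
  return out;
}

// Coulomb channel with a unit positive probe: sum of K * q / r^expnt (the
// squared-distance form, expnt = 2, is the default), zero beyond the cutoff.
// [[Rcpp::export]]
NumericVector coulomb_grid_cpp(IntegerVector dims, NumericVector origin, double h,
                               NumericMatrix pos, NumericVector q, double K,
                               double cutoff, int expnt) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  NumericVector out(d[0] * d[1] * d[2], 0.0);
  const double c2 = cutoff * cutoff, rmin2 = 1e-12;
  for (int a = 0; a < pos.nrow(); ++a) {
    if (q[a] == 0) continue;
    const double p[3] = {pos(a, 0), pos(a, 1), pos(a, 2)};
    int lo[3], hi[3];
    for (int ax = 0; ax < 3; ++ax) {
      lo[ax] = std::max(0, (int)std::floor((p[ax] - cutoff - origin[ax]) / h - 0.5));
      hi[ax] = std::min(d[ax] - 1, (int)std::ceil((p[ax] + cutoff - origin[ax]) / h - 0.5));
    }
    for (int k = lo[2]; k <= hi[2]; ++k) {
      const double dz = origin[2] + (k + 0.5) * h - p[2];
      for (int j = lo[1]; j <= hi[1]; ++j) {
        const double dy = origin[1] + (j + 0.5) * h - p[1];
        for (int i = lo[0]; i <= hi[0]; ++i) {
          const double dx = origin[0] + (i + 0.5) * h - p[0];
          double r2 = dx * dx + dy * dy + dz * dz;
          if (r2 > c2) continue;
          if (r2 < rmin2) r2 = rmin2;
          out[vidx(i, j, k, d)] += K * q[a] / (expnt == 2 ? r2 : std::sqrt(r2));
        }
      }
    }
  }
  return out;
}
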