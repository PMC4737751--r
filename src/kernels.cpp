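#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <unordered_map>
using namespace Rcpp;

// Accumulate an isotropic Gaussian of the given sigma for every bead onto a
// voxel grid. Grid is column-major with x fastest, matching the in-memory
// layout of a density_map array. Each Gaussian is truncated at cutoff*sigma.
// [[Rcpp::export]]
NumericVector cpp_splat_gauss(const NumericMatrix& coords,
                              double sigma,
                              const NumericVector& origin,
                              double voxel,
                              const IntegerVector& dims,
                              double cutoff) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double reach = cutoff * sigma;
  for (int b = 0; b < coords.nrow(); ++b) {
    const double bx = coords(b, 0), by = coords(b, 1), bz = coords(b, 2);
    int ix0 = (int)std::ceil((bx - reach - origin[0]) / voxel);
    int ix1 = (int)std::floor((bx + reach - origin[0]) / voxel);
    int iy0 = (int)std::ceil((by - reach - origin[1]) / voxel);
    int iy1 = (int)std::floor((by + reach - origin[1]) / voxel);
    int iz0 = (int)std::ceil((bz - reach - origin[2]) / voxel);
    int iz1 = (int)std::floor((bz + reach - origin[2]) / voxel);
    if (ix0 < 0) ix0 = 0; if (ix1 > nx - 1) ix1 = nx - 1;
    if (iy0 < 0) iy0 = 0; if (iy1 > ny - 1) iy1 = ny - 1;
    if (iz0 < 0) iz0 = 0; if (iz1 > nz - 1) iz1 = nz - 1;
    for (int iz = iz0; iz <= iz1; ++iz) {
      const double dz = origin[2] + iz * voxel - bz;
      for (int iy = iy0; iy <= iy1; ++iy) {
        const double dy = origin[1] + iy * voxel - by;
        const double d2yz = dy * dy + dz * dz;
        const R_xlen_t base = ((R_xlen_t)iz * ny + iy) * nx;
        for (int ix = ix0; ix <= ix1; ++ix) {
          const double dx = origin[0] + ix * voxel - bx;
          const double d2 = dx * dx + d2yz;
          if (d2 <= reach * reach)
            out[base + ix] += std::exp(-d2 * inv2s2);
        }
      }
    }
  }
  return out;
}

static inline long long cell_key(int cx, int cy, int cz) {
  // offset to keep components non-negative; assemblies are < 2^20 cells wide
  const long long off = 1 << 20;
  return ((cx + off) << 42) ^ ((cy + off) << 21) ^ (cz + off);
}

// Count inter-component bead pairs with centre distance < (ri+rj)*overlap,
// using a cell list of the given cell size. Returns the exact all-pairs count.
// [[Rcpp::export]]
double cpp_clash_count_grid(const NumericMatrix& coords,
                            const NumericVector& radii,
                            const IntegerVector& comp,
                            double cell,
                            double overlap) {
  const int n = coords.nrow();
  if (n < 2) return 0.0;
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) if (radii[i] > rmax) rmax = radii[i];
  const double reach = 2.0 * rmax * overlap;
  const int span = (int)std::ceil(reach / cell);
  std::unordered_map<long long, std::vector<int> > bins;
  bins.reserve(n * 2);
  std::vector<int> cxs(n), cys(n), czs(n);
  for (int i = 0; i < n; ++i) {
    cxs[i] = (int)std::floor(coords(i, 0) / cell);
    cys[i] = (int)std::floor(coords(i, 1) / cell);
    czs[i] = (int)std::floor(coords(i, 2) / cell);
    bins[cell_key(cxs[i], cys[i], czs[i])].push_back(i);
  }
  double count = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int dx = -span; dx <= span; ++dx)
      for (int dy = -span; dy <= span; ++dy)
        for (int dz = -span; dz <= span; ++dz) {
          std::unordered_map<long long, std::vector<int> >::const_iterator it =
            bins.find(cell_key(cxs[i] + dx, cys[i] + dy, czs[i] + dz));
          if (it == bins.end()) continue;
          const std::vector<int>& v = it->second;
          for (size_t k = 0; k < v.size(); ++k) {
            const int j = v[k];
            if (j <= i || comp[j] == comp[i]) continue;
            const double ddx = coords(i, 0) - coords(j, 0);
            const double ddy = coords(i, 1) - coords(j, 1);
            const double ddz = coords(i, 2) - coords(j, 2);
            const double lim = (radii[i] + radii[j]) * overlap;
            if (ddx * ddx + ddy * ddy + ddz * ddz < lim * lim) count += 1.0;
          }
        }
  }
  return count;
}

// Count pairs between two bead sets with centre distance < (ri+rj)*overlap.
// [[Rcpp::export]]
double cpp_clash_between(const NumericMatrix& a, const NumericVector& ra,
                         const NumericMatrix& b, const NumericVector& rb,
                         double overlap) {
  double count = 0.0;
  for (int i = 0; i < a.nrow(); ++i) {
    for (int j = 0; j < b.nrow(); ++j) {
      const double dx = a(i, 0) - b(j, 0);
      const double dy = a(i, 1) - b(j, 1);
      const double dz = a(i, 2) - b(j, 2);
      const double lim = (ra[i] + rb[j]) * overlap;
      if (dx * dx + dy * dy + dz * dz < lim * lim) count += 1.0;
    }
  }
  return count;
}

// Minimum surface-to-surface distance min_ij(|a_i-b_j| - ra_i - rb_j).
// [[Rcpp::export]]
double cpp_min_surface_dist(const NumericMatrix& a, const NumericVector& ra,
                            const NumericMatrix& b, const NumericVector& rb) {
  double best = R_PosInf;
  for (int i = 0; i < a.nrow(); ++i) {
    for (int j = 0; j < b.nrow(); ++j) {
      const double dx = a(i, 0) - b(j, 0);
      const double dy = a(i, 1) - b(j, 1);
      const double dz = a(i, 2) - b(j, 2);
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz) - ra[i] - rb[j];
      if (d < best) best = d;
    }
  }
  return best;
}

// For each bead, the (1-based) slots of mask voxels whose centre lies within
// the bead radius. `slot` maps full-grid linear index -> mask slot (0 =
// voxel not in mask). One entry per (bead, voxel) incidence.
// [[Rcpp::export]]
IntegerVector cpp_cover_slots(const NumericMatrix& coords,
                              const NumericVector& radii,
                              const NumericVector& origin,
                              double voxel,
                              const IntegerVector& dims,
                              const IntegerVector& slot) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<int> out;
  out.reserve(coords.nrow() * 8);
  for (int b = 0; b < coords.nrow(); ++b) {
    const double bx = coords(b, 0), by = coords(b, 1), bz = coords(b, 2);
    const double r = radii[b], r2 = r * r;
    int ix0 = (int)std::ceil((bx - r - origin[0]) / voxel);
    int ix1 = (int)std::floor((bx + r - origin[0]) / voxel);
    int iy0 = (int)std::ceil((by - r - origin[1]) / voxel);
    int iy1 = (int)std::floor((by + r - origin[1]) / voxel);
    int iz0 = (int)std::ceil((bz - r - origin[2]) / voxel);
    int iz1 = (int)std::floor((bz + r - origin[2]) / voxel);
    if (ix0 < 0) ix0 = 0; if (ix1 > nx - 1) ix1 = nx - 1;
    if (iy0 < 0) iy0 = 0; if (iy1 > ny - 1) iy1 = ny - 1;
    if (iz0 < 0) iz0 = 0; if (iz1 > nz - 1) iz1 = nz - 1;
    for (int iz = iz0; iz <= iz1; ++iz) {
      const double dz = origin[2] + iz * voxel - bz;
      for (int iy = iy0; iy <= iy1; ++iy) {
        const double dy = origin[1] + iy * voxel - by;
        const double d2yz = dy * dy + dz * dz;
        if (d2yz > r2) continue;
        const R_xlen_t base = ((R_xlen_t)iz * ny + iy) * nx;
        for (int ix = ix0; ix <= ix1; ++ix) {
          const double dx = origin[0] + ix * voxel - bx;
          if (dx * dx + d2yz <= r2) {
            const int s = slot[base + ix];
            if (s > 0) out.push_back(s);
          }
        }
      }
    }
  }
  return wrap(out);
}

// In-place update of per-slot cover counts; returns the net change in the
// number of slots with count > 0. `cover` must be a private (unshared) vector.
// [[Rcpp::export]]
int cpp_cover_update(IntegerVector cover, const IntegerVector& slots,
                     int delta) {
  int change = 0;
  for (R_xlen_t k = 0; k < slots.size(); ++k) {
    const int s = slots[k] - 1;
    const int before = cover[s];
    cover[s] = before + delta;
    if (before == 0 && cover[s] > 0) ++change;
    else if (before > 0 && cover[s] == 0) --change;
  }
  return change;
}

// Weighted variant: returns the change in total covered weight, where
// wt[s-1] is the weight of slot s.
// [[Rcpp::export]]
double cpp_cover_update_w(IntegerVector cover, const IntegerVector& slots,
                          int delta, const NumericVector& wt) {
  double change = 0.0;
  for (R_xlen_t k = 0; k < slots.size(); ++k) {
    const int s = slots[k] - 1;
    const int before = cover[s];
    cover[s] = before + delta;
    if (before == 0 && cover[s] > 0) change += wt[s];
    else if (before > 0 && cover[s] == 0) change -= wt[s];
  }
  return change;
}
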