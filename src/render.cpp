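#include <Rcpp.h>
using namespace Rcpp;

// Phantom rendering hot loops. Arrays are R arrays ordered (z, y, x):
// linear index i = z + nz*(y + ny*x), all 0-based here.

// Rasterize Gaussian-profile tubes: seg columns are
// x0, y0, z0, x1, y1, z1 (um), sigma (um), level. Voxel centers sit at
// (i + 0.5) * voxel um. Accumulation by maximum over a tissue background
// level applied from axial index z_surf (0-based) downward.
// [[Rcpp::export(name = ".rasterize_tubes_cpp")]]
NumericVector rasterize_tubes(IntegerVector dims, NumericMatrix seg,
                              double voxel, double bg_level, int z_surf) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  NumericVector out(static_cast<R_xlen_t>(nz) * ny * nx);
  if (bg_level > 0) {
    R_xlen_t ncol = static_cast<R_xlen_t>(ny) * nx;
    for (R_xlen_t c = 0; c < ncol; ++c) {
      double *col = &out[c * nz];
      for (int z = z_surf; z < nz; ++z) col[z] = bg_level;
    }
  }
  for (int v = 0; v < seg.nrow(); ++v) {
    double x0 = seg(v, 0), y0 = seg(v, 1), z0 = seg(v, 2);
    double x1 = seg(v, 3), y1 = seg(v, 4), z1 = seg(v, 5);
    double sig = seg(v, 6), level = seg(v, 7);
    double R = std::max(2.5 * sig, 3.0);
    double wx = x1 - x0, wy = y1 - y0, wz = z1 - z0;
    double L2 = wx * wx + wy * wy + wz * wz;
    double inv2s2 = 1.0 / (2.0 * sig * sig);
    int ix0 = std::max(0, (int)std::floor((std::min(x0, x1) - R) / voxel));
    int ix1 = std::min(nx - 1, (int)std::ceil((std::max(x0, x1) + R) / voxel));
    int iy0 = std::max(0, (int)std::floor((std::min(y0, y1) - R) / voxel));
    int iy1 = std::min(ny - 1, (int)std::ceil((std::max(y0, y1) + R) / voxel));
    int iz0 = std::max(0, (int)std::floor((std::min(z0, z1) - R) / voxel));
    int iz1 = std::min(nz - 1, (int)std::ceil((std::max(z0, z1) + R) / voxel));
    for (int ix = ix0; ix <= ix1; ++ix) {
      double X = (ix + 0.5) * voxel;
      for (int iy = iy0; iy <= iy1; ++iy) {
        double Y = (iy + 0.5) * voxel;
        R_xlen_t base = (static_cast<R_xlen_t>(ix) * ny + iy) *
          static_cast<R_xlen_t>(nz);
        for (int iz = iz0; iz <= iz1; ++iz) {
          double Z = (iz + 0.5) * voxel;
          double t = 0.0;
          if (L2 > 1e-9) {
            t = ((X - x0) * wx + (Y - y0) * wy + (Z - z0) * wz) / L2;
            if (t < 0) t = 0; else if (t > 1) t = 1;
          }
          double dx = X - x0 - t * wx, dy = Y - y0 - t * wy,
                 dz = Z - z0 - t * wz;
          double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 > R * R) continue;
          double val = level * std::exp(-d2 * inv2s2);
          R_xlen_t i = base + iz;
          if (val > out[i]) out[i] = val;
        }
      }
    }
  }
  return out;
}

// Projection tails: below each vessel the signal floor is the running
// maximum of tail_strength * intensity above, attenuated by `decay` per
// voxel. Operates in place on a (nz, ny, nx) array.
// [[Rcpp::export(name = ".add_tails_cpp")]]
NumericVector add_tails(NumericVector vol_in, IntegerVector dims,
                        double strength, double decay) {
  NumericVector vol = clone(vol_in);
  int nz = dims[0];
  R_xlen_t ncol = vol.size() / nz;
  for (R_xlen_t c = 0; c < ncol; ++c) {
    double *col = &vol[c * nz];
    double run = col[0] * strength;
    for (int z = 1; z < nz; ++z) {
      run *= decay;
      if (run > col[z]) col[z] = run;
      double cand = col[z] * strength;
      if (cand > run) run = cand;
    }
  }
  return vol;
}

// Multiplicative lognormal speckle (mean 1, log-sd sl) on every voxel plus
// an additive half-normal detector floor on dark voxels; clamps to [0, 1].
// Uses R's RNG so results follow set.seed().
// [[Rcpp::export(name = ".apply_noise_cpp")]]
NumericVector apply_noise(NumericVector vol_in, double sl, double floor_sd) {
  NumericVector vol = clone(vol_in);
  R_xlen_t n = vol.size();
  double mu = -0.5 * sl * sl;
  double dark_thr = 5.0 * floor_sd;
  RNGScope scope;
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = vol[i];
    double v0 = v;
    if (sl > 0) v *= std::exp(mu + sl * norm_rand());
    if (floor_sd > 0 && v0 < dark_thr)
      v += floor_sd * std::fabs(norm_rand());
    if (v > 1.0) v = 1.0;
    vol[i] = v;
  }
  return vol;
}
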