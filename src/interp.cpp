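#include <Rcpp.h>
using namespace Rcpp;

// Trilinear interpolation at a continuous 0-based voxel coordinate.
// Corners outside the grid contribute 0, so values fade to zero across the
// half-voxel band at the edge and are exactly 0 beyond it.
static inline double sample3(const double* v, int nx, int ny, int nz,
                             double x, double y, double z) {
  if (x <= -0.5 || y <= -0.5 || z <= -0.5 ||
      x >= nx - 0.5 || y >= ny - 0.5 || z >= nz - 0.5)
    return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  double out = 0.0;
  for (int dz = 0; dz <= 1; ++dz) {
    int zz = z0 + dz;
    if (zz < 0 || zz >= nz) continue;
    double wz = dz ? fz : 1.0 - fz;
    for (int dy = 0; dy <= 1; ++dy) {
      int yy = y0 + dy;
      if (yy < 0 || yy >= ny) continue;
      double wy = dy ? fy : 1.0 - fy;
      for (int dx = 0; dx <= 1; ++dx) {
        int xx = x0 + dx;
        if (xx < 0 || xx >= nx) continue;
        double wx = dx ? fx : 1.0 - fx;
        out += wx * wy * wz * v[xx + (size_t)nx * (yy + (size_t)ny * zz)];
      }
    }
  }
  return out;
}

double bf_sample3(const double* v, int nx, int ny, int nz,
                  double x, double y, double z) {
  return sample3(v, nx, ny, nz, x, y, z);
}

// [[Rcpp::export(name = ".cppSampleTrilinear")]]
NumericVector cppSampleTrilinear(NumericVector vol, IntegerVector dim,
                                 NumericMatrix pts) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = pts.nrow();
  NumericVector out(n);
  const double* v = REAL(vol);
  for (int i = 0; i < n; ++i)
    out[i] = sample3(v, nx, ny, nz, pts(i, 0), pts(i, 1), pts(i, 2));
  return out;
}

// Resample src onto a target grid. M is the combined 4x4 map taking a
// 0-based target voxel index to a continuous 0-based source voxel index
// (src_affine^-1 . transform^-1 . target_affine).
// [[Rcpp::export(name = ".cppResample")]]
NumericVector cppResample(NumericVector src, IntegerVector sdim,
                          NumericMatrix M, IntegerVector tdim) {
  int nx = sdim[0], ny = sdim[1], nz = sdim[2];
  int tx = tdim[0], ty = tdim[1], tz = tdim[2];
  NumericVector out((size_t)tx * ty * tz);
  const double* v = REAL(src);
  size_t q = 0;
  for (int k = 0; k < tz; ++k)
    for (int j = 0; j < ty; ++j)
      for (int i = 0; i < tx; ++i, ++q) {
        double x = M(0, 0) * i + M(0, 1) * j + M(0, 2) * k + M(0, 3);
        double y = M(1, 0) * i + M(1, 1) * j + M(1, 2) * k + M(1, 3);
        double z = M(2, 0) * i + M(2, 1) * j + M(2, 2) * k + M(2, 3);
        out[q] = sample3(v, nx, ny, nz, x, y, z);
      }
  out.attr("dim") = tdim;
  return out;
}
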