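#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Separable squared Euclidean distance transform (Felzenszwalb &
// Huttenlocher, lower envelope of parabolas), anisotropic voxel spacing.
// Input: logical mask; output: squared distance (mm^2) from each voxel
// centre to the nearest TRUE voxel centre.

static const double DT_INF = 1e30;

static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, double h) {
  const int n = (int)f.size();
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; ++q) {
    double s;
    for (;;) {
      const double qh = q * h, vh = v[k] * h;
      s = ((f[q] + qh * qh) - (f[v[k]] + vh * vh)) / (2.0 * (qh - vh));
      if (s <= z[k] && k > 0) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    const double qh = q * h;
    while (z[k + 1] < qh) ++k;
    const double vh = v[k] * h;
    d[q] = (qh - vh) * (qh - vh) + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dims,
                         NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector D(nvox);
  for (R_xlen_t i = 0; i < nvox; ++i) D[i] = mask[i] ? 0.0 : DT_INF;

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (stride 1)
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      const R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; ++i) f[i] = D[base + i];
      dt1d(std::vector<double>(f.begin(), f.begin() + nx), d, v, z, spacing[0]);
      for (int i = 0; i < nx; ++i) D[base + i] = d[i];
    }
  // pass along y (stride nx)
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      const R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; ++j) f[j] = D[base + (R_xlen_t)j * nx];
      dt1d(std::vector<double>(f.begin(), f.begin() + ny), d, v, z, spacing[1]);
      for (int j = 0; j < ny; ++j) D[base + (R_xlen_t)j * nx] = d[j];
    }
  // pass along z (stride nx*ny)
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      const R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; ++k) f[k] = D[base + (R_xlen_t)k * sz];
      dt1d(std::vector<double>(f.begin(), f.begin() + nz), d, v, z, spacing[2]);
      for (int k = 0; k < nz; ++k) D[base + (R_xlen_t)k * sz] = d[k];
    }
  return D;
}
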