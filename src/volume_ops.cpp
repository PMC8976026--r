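// 3-D volume primitives: trilinear resampling/translation, 3-D median
// filtering, and 3-D connected-component labelling. These operate on plain
// R arrays indexed (x, y, z), column-major.
#include <RcppArmadillo.h>
#include <vector>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double clamp_d(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Trilinear sample at continuous 0-based voxel coordinate, clamped to the
// grid (edge replication outside the field of view).
static double sample_trilinear(const double *a, int nx, int ny, int nz,
                               double x, double y, double z) {
  x = clamp_d(x, 0.0, nx - 1.0);
  y = clamp_d(y, 0.0, ny - 1.0);
  z = clamp_d(z, 0.0, nz - 1.0);
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  int x1 = std::min(x0 + 1, nx - 1);
  int y1 = std::min(y0 + 1, ny - 1);
  int z1 = std::min(z0 + 1, nz - 1);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  #define AT(i,j,k) a[(size_t)(i) + (size_t)nx * ((size_t)(j) + (size_t)ny * (size_t)(k))]
  double c00 = AT(x0,y0,z0) * (1-fx) + AT(x1,y0,z0) * fx;
  double c10 = AT(x0,y1,z0) * (1-fx) + AT(x1,y1,z0) * fx;
  double c01 = AT(x0,y0,z1) * (1-fx) + AT(x1,y0,z1) * fx;
  double c11 = AT(x0,y1,z1) * (1-fx) + AT(x1,y1,z1) * fx;
  #undef AT
  double c0 = c00 * (1-fy) + c10 * fy;
  double c1 = c01 * (1-fy) + c11 * fy;
  return c0 * (1-fz) + c1 * fz;
}

static double sample_nearest(const double *a, int nx, int ny, int nz,
                             double x, double y, double z) {
  int xi = (int)clamp_d(std::round(x), 0.0, nx - 1.0);
  int yi = (int)clamp_d(std::round(y), 0.0, ny - 1.0);
  int zi = (int)clamp_d(std::round(z), 0.0, nz - 1.0);
  return a[(size_t)xi + (size_t)nx * ((size_t)yi + (size_t)ny * (size_t)zi)];
}

// Resample a volume onto a new grid. Both grids span the same physical
// extent and are centre-aligned: output voxel i samples input coordinate
// (i + 0.5) * (outSpacing/inSpacing) - 0.5, so edge slices are weighted
// symmetrically and a same-spacing resample is the identity.
// [[Rcpp::export(name = ".cpp_resample")]]
NumericVector cpp_resample(NumericVector vol, NumericVector inSpacing,
                           IntegerVector outDims, NumericVector outSpacing,
                           bool nearest) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  int ox = outDims[0], oy = outDims[1], oz = outDims[2];
  NumericVector out((size_t)ox * oy * oz);
  const double *a = vol.begin();
  double sx = outSpacing[0] / inSpacing[0];
  double sy = outSpacing[1] / inSpacing[1];
  double sz = outSpacing[2] / inSpacing[2];
  size_t idx = 0;
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i, ++idx) {
        double x = (i + 0.5) * sx - 0.5;
        double y = (j + 0.5) * sy - 0.5;
        double z = (k + 0.5) * sz - 0.5;
        // column-major over (i fastest): recompute idx accordingly
        size_t lin = (size_t)i + (size_t)ox * ((size_t)j + (size_t)oy * (size_t)k);
        out[lin] = nearest ? sample_nearest(a, nx, ny, nz, x, y, z)
                           : sample_trilinear(a, nx, ny, nz, x, y, z);
      }
  out.attr("dim") = IntegerVector::create(ox, oy, oz);
  return out;
}

// Translate a volume by a continuous voxel shift (content moves by +shift):
// out(i,j,k) = in(i - dx, j - dy, k - dz), trilinear, edge-replicated.
// [[Rcpp::export(name = ".cpp_shift_volume")]]
NumericVector cpp_shift_volume(NumericVector vol, NumericVector shift,
                               bool nearest) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  NumericVector out((size_t)nx * ny * nz);
  const double *a = vol.begin();
  double dx = shift[0], dy = shift[1], dz = shift[2];
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t lin = (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * (size_t)k);
        out[lin] = nearest
          ? sample_nearest(a, nx, ny, nz, i - dx, j - dy, k - dz)
          : sample_trilinear(a, nx, ny, nz, i - dx, j - dy, k - dz);
      }
  out.attr("dim") = d;
  return out;
}

// 3-D median filter with odd cubic kernel, reflected boundaries.
// [[Rcpp::export(name = ".cpp_median_filter3")]]
NumericVector cpp_median_filter3(NumericVector vol, int k) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  int r = k / 2;
  NumericVector out((size_t)nx * ny * nz);
  const double *a = vol.begin();
  std::vector<double> buf((size_t)k * k * k);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        size_t n = 0;
        for (int dz = -r; dz <= r; ++dz)
          for (int dy = -r; dy <= r; ++dy)
            for (int dx = -r; dx <= r; ++dx) {
              int xi = x + dx, yi = y + dy, zi = z + dz;
              if (xi < 0) xi = -xi; else if (xi >= nx) xi = 2 * nx - 2 - xi;
              if (yi < 0) yi = -yi; else if (yi >= ny) yi = 2 * ny - 2 - yi;
              if (zi < 0) zi = -zi; else if (zi >= nz) zi = 2 * nz - 2 - zi;
              buf[n++] = a[(size_t)xi + (size_t)nx * ((size_t)yi + (size_t)ny * (size_t)zi)];
            }
        std::nth_element(buf.begin(), buf.begin() + n / 2, buf.begin() + n);
        out[(size_t)x + (size_t)nx * ((size_t)y + (size_t)ny * (size_t)z)] = buf[n / 2];
      }
  out.attr("dim") = d;
  return out;
}

// Connected-component labelling of a logical 3-D array, 6- or 26-
// connectivity. Labels start at 1, assigned in scan order.
// [[Rcpp::export(name = ".cpp_label3d")]]
IntegerVector cpp_label3d(LogicalVector mask, int connectivity) {
  IntegerVector d = mask.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n);
  const int *m = mask.begin();
  std::vector<std::array<int,3>> nbrs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        nbrs.push_back({dx, dy, dz});
      }
  int next = 0;
  std::vector<size_t> stack;
  for (size_t s = 0; s < n; ++s) {
    if (!m[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      size_t cur = stack.back(); stack.pop_back();
      int ci = (int)(cur % nx);
      int cj = (int)((cur / nx) % ny);
      int ck = (int)(cur / ((size_t)nx * ny));
      for (auto &o : nbrs) {
        int xi = ci + o[0], yj = cj + o[1], zk = ck + o[2];
        if (xi < 0 || xi >= nx || yj < 0 || yj >= ny || zk < 0 || zk >= nz)
          continue;
        size_t t = (size_t)xi + (size_t)nx * ((size_t)yj + (size_t)ny * (size_t)zk);
        if (m[t] && lab[t] == 0) { lab[t] = next; stack.push_back(t); }
      }
    }
  }
  lab.attr("dim") = d;
  return lab;
}
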