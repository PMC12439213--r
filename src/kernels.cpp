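#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// 3-D binary erosion with the face-connected (6-neighbourhood) structuring
// element. Voxels outside the array are treated as unset, so voxels on the
// array border always erode away.
// [[Rcpp::export]]
LogicalVector cpp_erode6(const LogicalVector& mask, const IntegerVector& dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out(mask.size());
  const int sx = 1, sy = nx, sz = nx * ny;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        const int idx = i + nx * (j + ny * k);
        if (!mask[idx]) { out[idx] = FALSE; continue; }
        bool keep =
          i > 0 && i < nx - 1 && j > 0 && j < ny - 1 && k > 0 && k < nz - 1 &&
          mask[idx - sx] && mask[idx + sx] &&
          mask[idx - sy] && mask[idx + sy] &&
          mask[idx - sz] && mask[idx + sz];
        out[idx] = keep;
      }
    }
  }
  return out;
}

// Felzenszwalb & Huttenlocher lower-envelope transform of one line of
// squared distances, with samples at physical positions i * s.
static void dt1d(std::vector<double>& f, std::vector<double>& d, double s) {
  const int n = (int)f.size();
  static const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  // infinite parabolas never contribute to the lower envelope; skip them
  int q0 = 0;
  while (q0 < n && f[q0] == INF) ++q0;
  if (q0 == n) { for (int q = 0; q < n; ++q) d[q] = INF; return; }
  int k = 0;
  v[0] = q0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double xq = q * s;
    double sq = f[q] + xq * xq;
    while (true) {
      double xv = v[k] * s;
      double den = 2.0 * (xq - xv);
      double sv = f[v[k]] + xv * xv;
      double inter = (sq - sv) / den;
      if (inter <= z[k]) {
        --k;
      } else {
        ++k;
        v[k] = q;
        z[k] = inter;
        z[k + 1] = INF;
        break;
      }
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * s;
    d[q] = dx * dx + f[v[k]];
  }
}

// Exact Euclidean distance transform on an anisotropic grid: for every voxel,
// the distance in mm to the nearest foreground (true) voxel. Voxels of an
// all-false input get Inf.
// [[Rcpp::export]]
NumericVector cpp_edt(const LogicalVector& fg, const IntegerVector& dim,
                      const NumericVector& spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = fg[i] ? 0.0 : INF;

  std::vector<double> f, d;
  // pass along x
  f.resize(nx); d.resize(nx);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      const R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      bool any = false;
      for (int i = 0; i < nx; ++i) { f[i] = out[base + i]; if (f[i] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, spacing[0]);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  // pass along y
  f.resize(ny); d.resize(ny);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      const R_xlen_t base = i + (R_xlen_t)nx * ny * k;
      bool any = false;
      for (int j = 0; j < ny; ++j) { f[j] = out[base + (R_xlen_t)nx * j]; if (f[j] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, spacing[1]);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)nx * j] = d[j];
    }
  // pass along z
  f.resize(nz); d.resize(nz);
  const R_xlen_t stridez = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      const R_xlen_t base = i + (R_xlen_t)nx * j;
      bool any = false;
      for (int k = 0; k < nz; ++k) { f[k] = out[base + stridez * k]; if (f[k] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, spacing[2]);
      for (int k = 0; k < nz; ++k) out[base + stridez * k] = d[k];
    }
  for (R_xlen_t i = 0; i < n; ++i)
    if (out[i] < INF) out[i] = std::sqrt(out[i]);
  return out;
}

// 1-based inclusive bounding box of true voxels; integer(0) if none set.
// [[Rcpp::export]]
IntegerVector cpp_bbox(const LogicalVector& mask, const IntegerVector& dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  int lo[3] = {nx, ny, nz}, hi[3] = {-1, -1, -1};
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        if (!mask[idx]) continue;
        if (i < lo[0]) lo[0] = i;
        if (j < lo[1]) lo[1] = j;
        if (k < lo[2]) lo[2] = k;
        if (i > hi[0]) hi[0] = i;
        if (j > hi[1]) hi[1] = j;
        if (k > hi[2]) hi[2] = k;
      }
  if (hi[0] < 0) return IntegerVector(0);
  return IntegerVector::create(lo[0] + 1, lo[1] + 1, lo[2] + 1,
                               hi[0] + 1, hi[1] + 1, hi[2] + 1);
}

// Mean 0-based (i, j, k) index of true voxels plus the count.
// [[Rcpp::export]]
NumericVector cpp_centroid(const LogicalVector& mask, const IntegerVector& dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  double si = 0, sj = 0, sk = 0, n = 0;
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx)
        if (mask[idx]) { si += i; sj += j; sk += k; n += 1; }
  if (n == 0) return NumericVector::create(NA_REAL, NA_REAL, NA_REAL, 0);
  return NumericVector::create(si / n, sj / n, sk / n, n);
}

// Crop a logical 3-D array to a 1-based inclusive index window.
// [[Rcpp::export]]
LogicalVector cpp_crop3d(const LogicalVector& mask, const IntegerVector& dim,
                         const IntegerVector& lo, const IntegerVector& hi) {
  const int nx = dim[0], ny = dim[1];
  const int ox = hi[0] - lo[0] + 1, oy = hi[1] - lo[1] + 1,
            oz = hi[2] - lo[2] + 1;
  LogicalVector out((R_xlen_t)ox * oy * oz);
  R_xlen_t o = 0;
  for (int k = lo[2] - 1; k < hi[2]; ++k)
    for (int j = lo[1] - 1; j < hi[1]; ++j) {
      const R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k) + lo[0] - 1;
      for (int i = 0; i < ox; ++i, ++o) out[o] = mask[base + i];
    }
  return out;
}

static void conv1d(std::vector<double>& line, const std::vector<double>& ker) {
  const int n = (int)line.size();
  const int r = ((int)ker.size() - 1) / 2;
  std::vector<double> out(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int t = -r; t <= r; ++t) {
      int j = i + t;
      if (j < 0) j = 0; else if (j >= n) j = n - 1;  // clamp at borders
      acc += ker[t + r] * line[j];
    }
    out[i] = acc;
  }
  line.swap(out);
}

static std::vector<double> gauss_kernel(double sigma_vox) {
  int r = (int)std::ceil(3.0 * sigma_vox);
  if (r < 1) r = 1;
  std::vector<double> k(2 * r + 1);
  double sum = 0.0;
  for (int t = -r; t <= r; ++t) {
    double v = std::exp(-0.5 * t * t / (sigma_vox * sigma_vox));
    k[t + r] = v;
    sum += v;
  }
  for (double& v : k) v /= sum;
  return k;
}

// Separable Gaussian smoothing of a 3-D array; sigma given per axis in
// voxel units. Border handling: clamp (replicate edge value).
// [[Rcpp::export]]
NumericVector cpp_smooth_gauss(const NumericVector& x, const IntegerVector& dim,
                               const NumericVector& sigma_vox) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out = clone(x);
  std::vector<double> line;

  if (sigma_vox[0] > 0) {
    std::vector<double> k = gauss_kernel(sigma_vox[0]);
    line.resize(nx);
    for (int kk = 0; kk < nz; ++kk)
      for (int j = 0; j < ny; ++j) {
        const R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * kk);
        for (int i = 0; i < nx; ++i) line[i] = out[base + i];
        conv1d(line, k);
        for (int i = 0; i < nx; ++i) out[base + i] = line[i];
      }
  }
  if (sigma_vox[1] > 0) {
    std::vector<double> k = gauss_kernel(sigma_vox[1]);
    line.resize(ny);
    for (int kk = 0; kk < nz; ++kk)
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t base = i + (R_xlen_t)nx * ny * kk;
        for (int j = 0; j < ny; ++j) line[j] = out[base + (R_xlen_t)nx * j];
        conv1d(line, k);
        for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)nx * j] = line[j];
      }
  }
  if (sigma_vox[2] > 0) {
    std::vector<double> k = gauss_kernel(sigma_vox[2]);
    line.resize(nz);
    const R_xlen_t stridez = (R_xlen_t)nx * ny;
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t base = i + (R_xlen_t)nx * j;
        for (int kk = 0; kk < nz; ++kk) line[kk] = out[base + stridez * kk];
        conv1d(line, k);
        for (int kk = 0; kk < nz; ++kk) out[base + stridez * kk] = line[kk];
      }
  }
  return out;
}
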