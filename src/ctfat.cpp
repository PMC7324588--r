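#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Linear index convention throughout: column-major over dim = (nz, ny, nx),
// i.e. i = z + nz * (y + ny * x), 0-based.

// 6-connected flood fill restricted to `candidate`; returns the connected
// component containing `seed` (0-based linear index).
// [[Rcpp::export(name = ".flood_fill_6")]]
LogicalVector flood_fill_6(LogicalVector candidate, IntegerVector dim, int seed) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (candidate.size() != n) stop("candidate length does not match dim");
  if (seed < 0 || seed >= n) stop("seed outside volume");
  LogicalVector out(n, false);
  if (!candidate[seed]) stop("seed voxel is not inside the candidate set");
  std::vector<int> stack;
  stack.reserve(1024);
  stack.push_back(seed);
  out[seed] = true;
  while (!stack.empty()) {
    const int i = stack.back();
    stack.pop_back();
    const int z = i % nz;
    const int r = i / nz;
    const int y = r % ny;
    const int x = r / ny;
    const int nb[6][3] = {
      {z - 1, y, x}, {z + 1, y, x},
      {z, y - 1, x}, {z, y + 1, x},
      {z, y, x - 1}, {z, y, x + 1}
    };
    for (int k = 0; k < 6; ++k) {
      const int zz = nb[k][0], yy = nb[k][1], xx = nb[k][2];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      const int j = zz + nz * (yy + ny * xx);
      if (candidate[j] && !out[j]) {
        out[j] = true;
        stack.push_back(j);
      }
    }
  }
  return out;
}

static inline int reflect_index(int i, int n) {
  // mirror boundary without edge repetition: ... 2 1 | 0 1 2 ... n-1 | n-2 n-3 ...
  if (n == 1) return 0;
  const int period = 2 * n - 2;
  i = i % period;
  if (i < 0) i += period;
  return (i < n) ? i : period - i;
}

static void blur_axis(std::vector<double> &a, std::vector<double> &tmp,
                      int nz, int ny, int nx, int axis,
                      const std::vector<double> &kernel) {
  const int r = ((int)kernel.size() - 1) / 2;
  const int len = (axis == 0) ? nz : (axis == 1) ? ny : nx;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        double s = 0.0;
        for (int k = -r; k <= r; ++k) {
          int zz = z, yy = y, xx = x;
          if (axis == 0) zz = reflect_index(z + k, len);
          else if (axis == 1) yy = reflect_index(y + k, len);
          else xx = reflect_index(x + k, len);
          s += kernel[k + r] * a[zz + (size_t)nz * (yy + (size_t)ny * xx)];
        }
        tmp[z + (size_t)nz * (y + (size_t)ny * x)] = s;
      }
  a.swap(tmp);
}

// Separable Gaussian blur with mirror boundary; sigma in voxels.
// [[Rcpp::export(name = ".gauss_blur_3d")]]
NumericVector gauss_blur_3d(NumericVector x, IntegerVector dim, double sigma) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const size_t n = (size_t)nz * ny * nx;
  if ((size_t)x.size() != n) stop("length does not match dim");
  if (sigma <= 0) return clone(x);
  const int r = std::max(1, (int)std::ceil(3.5 * sigma));
  std::vector<double> kernel(2 * r + 1);
  double ksum = 0.0;
  for (int k = -r; k <= r; ++k) {
    kernel[k + r] = std::exp(-0.5 * (k / sigma) * (k / sigma));
    ksum += kernel[k + r];
  }
  for (double &w : kernel) w /= ksum;
  std::vector<double> a(x.begin(), x.end()), tmp(n);
  for (int axis = 0; axis < 3; ++axis) blur_axis(a, tmp, nz, ny, nx, axis, kernel);
  return NumericVector(a.begin(), a.end());
}

// Parallel-beam forward projection of one slice by linear splatting: each
// pixel's value is distributed between the two detector bins straddling its
// projected coordinate, so the per-angle bin sum equals the slice sum exactly.
// Units are pixel units: t and the detector pitch are both one pixel.
// [[Rcpp::export(name = ".radon_splat")]]
NumericMatrix radon_splat(NumericMatrix slice, NumericVector angles_rad, int n_bins) {
  const int ny = slice.nrow(), nx = slice.ncol();
  const int na = angles_rad.size();
  NumericMatrix out(n_bins, na);
  const double cy = 0.5 * (ny - 1), cx = 0.5 * (nx - 1), cb = 0.5 * (n_bins - 1);
  for (int a = 0; a < na; ++a) {
    const double c = std::cos(angles_rad[a]), s = std::sin(angles_rad[a]);
    for (int ix = 0; ix < nx; ++ix) {
      const double xr = (ix - cx) * c;
      for (int iy = 0; iy < ny; ++iy) {
        const double v = slice(iy, ix);
        if (v == 0.0) continue;
        const double t = xr + (iy - cy) * s + cb;
        const int i0 = (int)std::floor(t);
        const double w = t - i0;
        if (i0 >= 0 && i0 < n_bins) out(i0, a) += v * (1.0 - w);
        if (i0 + 1 >= 0 && i0 + 1 < n_bins) out(i0 + 1, a) += v * w;
      }
    }
  }
  return out;
}

// Backprojection of filtered projections (n_bins x n_angles) onto an
// ny x nx grid with linear interpolation along the detector.
// Caller applies the pi / n_angles weight.
// [[Rcpp::export(name = ".back_project")]]
NumericMatrix back_project(NumericMatrix qf, NumericVector angles_rad, int ny, int nx) {
  const int n_bins = qf.nrow();
  const int na = angles_rad.size();
  NumericMatrix out(ny, nx);
  const double cy = 0.5 * (ny - 1), cx = 0.5 * (nx - 1), cb = 0.5 * (n_bins - 1);
  for (int a = 0; a < na; ++a) {
    const double c = std::cos(angles_rad[a]), s = std::sin(angles_rad[a]);
    for (int ix = 0; ix < nx; ++ix) {
      const double xr = (ix - cx) * c;
      for (int iy = 0; iy < ny; ++iy) {
        const double t = xr + (iy - cy) * s + cb;
        const int i0 = (int)std::floor(t);
        const double w = t - i0;
        double v = 0.0;
        if (i0 >= 0 && i0 < n_bins) v += qf(i0, a) * (1.0 - w);
        if (i0 + 1 >= 0 && i0 + 1 < n_bins) v += qf(i0 + 1, a) * w;
        out(iy, ix) += v;
      }
    }
  }
  return out;
}
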