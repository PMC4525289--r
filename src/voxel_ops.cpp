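#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Index helper for (z, y, x) arrays stored column-major, 0-based.
static inline int idx3(int i, int j, int k, int nz, int ny) {
  return i + j * nz + k * nz * (size_t)ny;
}

// 26-connected component labelling of a 3D logical mask.
// Returns an integer array of the same shape; background = 0, labels 1..n
// in first-encounter order (scan order z fastest).
// [[Rcpp::export(name = ".label3d_cpp")]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  lab.attr("dim") = dims;
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int i = cur % nz;
      int j = (cur / nz) % ny;
      int k = cur / ((R_xlen_t)nz * ny);
      for (int dk = -1; dk <= 1; ++dk) {
        int kk = k + dk;
        if (kk < 0 || kk >= nx) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          int jj = j + dj;
          if (jj < 0 || jj >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            int ii = i + di;
            if (ii < 0 || ii >= nz) continue;
            if (di == 0 && dj == 0 && dk == 0) continue;
            R_xlen_t nb = idx3(ii, jj, kk, nz, ny);
            if (mask[nb] && lab[nb] == 0) {
              lab[nb] = next;
              stack.push_back(nb);
            }
          }
        }
      }
    }
  }
  lab.attr("n_labels") = next;
  return lab;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher) with grid
// spacing w; f is read/overwritten through strided access.
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z,
                 int n, double w2) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + w2 * q * (double)q) - (f[v[k]] + w2 * v[k] * (double)v[k])) /
          (2.0 * w2 * (q - v[k]));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = w2 * dq * dq + f[v[k]];
  }
}

// Euclidean distance transform of a 3D mask with anisotropic voxel spacing
// (dz, dy, dx) in physical units. Returns distance (not squared) from every
// voxel center to the nearest TRUE voxel center; 0 inside the mask.
// [[Rcpp::export(name = ".edt3d_cpp")]]
NumericVector edt3d_cpp(LogicalVector mask, IntegerVector dims,
                        NumericVector spacing) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  // large finite sentinel: true infinities produce NaN in the envelope
  // intersection when two empty parabolas meet
  const double INF = 1e30;
  NumericVector out(n);
  std::vector<double> g(n);
  for (R_xlen_t s = 0; s < n; ++s) g[s] = mask[s] ? 0.0 : INF;

  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along z
  double w2 = spacing[0] * spacing[0];
  for (int k = 0; k < nx; ++k)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nz; ++i) f[i] = g[idx3(i, j, k, nz, ny)];
      dt1d(f, d, v, z, nz, w2);
      for (int i = 0; i < nz; ++i) g[idx3(i, j, k, nz, ny)] = d[i];
    }
  // pass along y
  w2 = spacing[1] * spacing[1];
  for (int k = 0; k < nx; ++k)
    for (int i = 0; i < nz; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = g[idx3(i, j, k, nz, ny)];
      dt1d(f, d, v, z, ny, w2);
      for (int j = 0; j < ny; ++j) g[idx3(i, j, k, nz, ny)] = d[j];
    }
  // pass along x
  w2 = spacing[2] * spacing[2];
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nz; ++i) {
      for (int k = 0; k < nx; ++k) f[k] = g[idx3(i, j, k, nz, ny)];
      dt1d(f, d, v, z, nx, w2);
      for (int k = 0; k < nx; ++k) g[idx3(i, j, k, nz, ny)] = d[k];
    }
  for (R_xlen_t s = 0; s < n; ++s) out[s] = std::sqrt(g[s]);
  out.attr("dim") = dims;
  return out;
}

// Catmull-Rom cubic kernel weights for fractional offset t in [0,1]
static inline void cr_weights(double t, double w[4]) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = 0.5 * (-t + 2 * t2 - t3);
  w[1] = 0.5 * (2 - 5 * t2 + 3 * t3);
  w[2] = 0.5 * (t + 4 * t2 - 3 * t3);
  w[3] = 0.5 * (-t2 + t3);
}

// Pull-back affine resampling with tricubic (Catmull-Rom) interpolation;
// border cells are clamped. Used by the registration optimizer, where the
// lower interpolation error of the cubic kernel matters (trilinear
// resampling biases sub-voxel parameter estimates at marginal axial
// sampling).
// [[Rcpp::export(name = ".affine_sample_cubic_cpp")]]
List affine_sample_cubic_cpp(NumericVector src, IntegerVector dims,
                             NumericVector spacing, NumericVector A,
                             NumericVector b) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  const double dz = spacing[0], dy = spacing[1], dx = spacing[2];
  NumericVector out(n);
  LogicalVector inframe(n);
  out.attr("dim") = dims;
  inframe.attr("dim") = dims;
  double wz[4], wy[4], wx[4];
  for (int k = 0; k < nx; ++k) {
    double qx = (k + 0.5) * dx;
    for (int j = 0; j < ny; ++j) {
      double qy = (j + 0.5) * dy;
      for (int i = 0; i < nz; ++i) {
        double qz = (i + 0.5) * dz;
        double sz = A[0] * qz + A[1] * qy + A[2] * qx + b[0];
        double sy = A[3] * qz + A[4] * qy + A[5] * qx + b[1];
        double sx = A[6] * qz + A[7] * qy + A[8] * qx + b[2];
        double fz = sz / dz - 0.5, fy = sy / dy - 0.5, fx = sx / dx - 0.5;
        R_xlen_t o = idx3(i, j, k, nz, ny);
        if (fz < 0 || fy < 0 || fx < 0 || fz > nz - 1 || fy > ny - 1 ||
            fx > nx - 1) {
          out[o] = 0.0;
          inframe[o] = false;
          continue;
        }
        int i0 = std::min((int)std::floor(fz), nz - 2);
        int j0 = std::min((int)std::floor(fy), ny - 2);
        int k0 = std::min((int)std::floor(fx), nx - 2);
        cr_weights(fz - i0, wz);
        cr_weights(fy - j0, wy);
        cr_weights(fx - k0, wx);
        double acc = 0.0;
        for (int c = 0; c < 4; ++c) {
          int kk = k0 - 1 + c;
          if (kk < 0) kk = 0; else if (kk >= nx) kk = nx - 1;
          double accy = 0.0;
          for (int bj = 0; bj < 4; ++bj) {
            int jj = j0 - 1 + bj;
            if (jj < 0) jj = 0; else if (jj >= ny) jj = ny - 1;
            double accz = 0.0;
            for (int ai = 0; ai < 4; ++ai) {
              int ii = i0 - 1 + ai;
              if (ii < 0) ii = 0; else if (ii >= nz) ii = nz - 1;
              accz += wz[ai] * src[idx3(ii, jj, kk, nz, ny)];
            }
            accy += wy[bj] * accz;
          }
          acc += wx[c] * accy;
        }
        out[o] = acc;
        inframe[o] = true;
      }
    }
  }
  return List::create(_["values"] = out, _["inframe"] = inframe);
}

// Pull-back sampling restricted to selected output voxels (0-based linear
// indices), used by the registration objective so that only informative
// voxels are resampled. interp: 0 = trilinear, 1 = tricubic Catmull-Rom.
// Out-of-frame samples return 0 with inframe = FALSE.
// [[Rcpp::export(name = ".sample_indices_cpp")]]
List sample_indices_cpp(NumericVector src, IntegerVector dims,
                        NumericVector spacing, NumericVector A,
                        NumericVector b, IntegerVector idx0, int interp) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double dz = spacing[0], dy = spacing[1], dx = spacing[2];
  const R_xlen_t m = idx0.size();
  NumericVector out(m);
  LogicalVector inframe(m);
  double wz[4], wy[4], wx[4];
  for (R_xlen_t s = 0; s < m; ++s) {
    R_xlen_t lin = idx0[s];
    int i = lin % nz;
    int j = (lin / nz) % ny;
    int k = lin / ((R_xlen_t)nz * ny);
    double qz = (i + 0.5) * dz, qy = (j + 0.5) * dy, qx = (k + 0.5) * dx;
    double sz = A[0] * qz + A[1] * qy + A[2] * qx + b[0];
    double sy = A[3] * qz + A[4] * qy + A[5] * qx + b[1];
    double sx = A[6] * qz + A[7] * qy + A[8] * qx + b[2];
    double fz = sz / dz - 0.5, fy = sy / dy - 0.5, fx = sx / dx - 0.5;
    if (fz < 0 || fy < 0 || fx < 0 || fz > nz - 1 || fy > ny - 1 ||
        fx > nx - 1) {
      out[s] = 0.0;
      inframe[s] = false;
      continue;
    }
    int i0 = std::min((int)std::floor(fz), nz - 2);
    int j0 = std::min((int)std::floor(fy), ny - 2);
    int k0 = std::min((int)std::floor(fx), nx - 2);
    if (interp == 0) {
      double tz = fz - i0, ty = fy - j0, tx = fx - k0;
      double c000 = src[idx3(i0, j0, k0, nz, ny)];
      double c100 = src[idx3(i0 + 1, j0, k0, nz, ny)];
      double c010 = src[idx3(i0, j0 + 1, k0, nz, ny)];
      double c110 = src[idx3(i0 + 1, j0 + 1, k0, nz, ny)];
      double c001 = src[idx3(i0, j0, k0 + 1, nz, ny)];
      double c101 = src[idx3(i0 + 1, j0, k0 + 1, nz, ny)];
      double c011 = src[idx3(i0, j0 + 1, k0 + 1, nz, ny)];
      double c111 = src[idx3(i0 + 1, j0 + 1, k0 + 1, nz, ny)];
      double c00 = c000 * (1 - tz) + c100 * tz;
      double c01 = c001 * (1 - tz) + c101 * tz;
      double c10 = c010 * (1 - tz) + c110 * tz;
      double c11 = c011 * (1 - tz) + c111 * tz;
      double c0 = c00 * (1 - ty) + c10 * ty;
      double c1 = c01 * (1 - ty) + c11 * ty;
      out[s] = c0 * (1 - tx) + c1 * tx;
    } else {
      cr_weights(fz - i0, wz);
      cr_weights(fy - j0, wy);
      cr_weights(fx - k0, wx);
      double acc = 0.0;
      for (int c = 0; c < 4; ++c) {
        int kk = k0 - 1 + c;
        if (kk < 0) kk = 0; else if (kk >= nx) kk = nx - 1;
        double accy = 0.0;
        for (int bj = 0; bj < 4; ++bj) {
          int jj = j0 - 1 + bj;
          if (jj < 0) jj = 0; else if (jj >= ny) jj = ny - 1;
          double accz = 0.0;
          for (int ai = 0; ai < 4; ++ai) {
            int ii = i0 - 1 + ai;
            if (ii < 0) ii = 0; else if (ii >= nz) ii = nz - 1;
            accz += wz[ai] * src[idx3(ii, jj, kk, nz, ny)];
          }
          accy += wy[bj] * accz;
        }
        acc += wx[c] * accy;
      }
      out[s] = acc;
    }
    inframe[s] = true;
  }
  return List::create(_["values"] = out, _["inframe"] = inframe);
}

// Pull-back affine resampling with trilinear interpolation.
// For each output voxel center q (physical, (z,y,x) nm) the source position
// is A q + b; intensity is interpolated from src; positions outside the
// source grid give 0 and inframe = FALSE. A is 3x3 (row major rows given as
// a length-9 vector), acting on (z,y,x).
// [[Rcpp::export(name = ".affine_sample_cpp")]]
List affine_sample_cpp(NumericVector src, IntegerVector dims,
                       NumericVector spacing, NumericVector A,
                       NumericVector b) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  const double dz = spacing[0], dy = spacing[1], dx = spacing[2];
  NumericVector out(n);
  LogicalVector inframe(n);
  out.attr("dim") = dims;
  inframe.attr("dim") = dims;
  for (int k = 0; k < nx; ++k) {
    double qx = (k + 0.5) * dx;
    for (int j = 0; j < ny; ++j) {
      double qy = (j + 0.5) * dy;
      for (int i = 0; i < nz; ++i) {
        double qz = (i + 0.5) * dz;
        double sz = A[0] * qz + A[1] * qy + A[2] * qx + b[0];
        double sy = A[3] * qz + A[4] * qy + A[5] * qx + b[1];
        double sx = A[6] * qz + A[7] * qy + A[8] * qx + b[2];
        // fractional 0-based voxel index of the source position; the
        // upper grid edge is sampled exactly (interpolation cell clamped)
        double fz = sz / dz - 0.5, fy = sy / dy - 0.5, fx = sx / dx - 0.5;
        R_xlen_t o = idx3(i, j, k, nz, ny);
        if (fz < 0 || fy < 0 || fx < 0 || fz > nz - 1 || fy > ny - 1 ||
            fx > nx - 1) {
          out[o] = 0.0;
          inframe[o] = false;
          continue;
        }
        int i0 = std::min((int)std::floor(fz), nz - 2);
        int j0 = std::min((int)std::floor(fy), ny - 2);
        int k0 = std::min((int)std::floor(fx), nx - 2);
        double wz = fz - i0, wy = fy - j0, wx = fx - k0;
        double c000 = src[idx3(i0, j0, k0, nz, ny)];
        double c100 = src[idx3(i0 + 1, j0, k0, nz, ny)];
        double c010 = src[idx3(i0, j0 + 1, k0, nz, ny)];
        double c110 = src[idx3(i0 + 1, j0 + 1, k0, nz, ny)];
        double c001 = src[idx3(i0, j0, k0 + 1, nz, ny)];
        double c101 = src[idx3(i0 + 1, j0, k0 + 1, nz, ny)];
        double c011 = src[idx3(i0, j0 + 1, k0 + 1, nz, ny)];
        double c111 = src[idx3(i0 + 1, j0 + 1, k0 + 1, nz, ny)];
        double c00 = c000 * (1 - wz) + c100 * wz;
        double c01 = c001 * (1 - wz) + c101 * wz;
        double c10 = c010 * (1 - wz) + c110 * wz;
        double c11 = c011 * (1 - wz) + c111 * wz;
        double c0 = c00 * (1 - wy) + c10 * wy;
        double c1 = c01 * (1 - wy) + c11 * wy;
        out[o] = c0 * (1 - wx) + c1 * wx;
        inframe[o] = true;
      }
    }
  }
  return List::create(_["values"] = out, _["inframe"] = inframe);
}
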