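#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double BIG = 1e20;

// 1-D squared distance transform (Felzenszwalb-Huttenlocher lower envelope)
// for samples at positions i*s, i = 0..n-1.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double s) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; ++q) {
    double xq = q * s;
    double num, den, inter;
    while (true) {
      double xv = v[k] * s;
      num = (f[q] + xq * xq) - (f[v[k]] + xv * xv);
      den = 2.0 * (xq - xv);
      inter = num / den;
      if (inter <= z[k]) {
        --k;
      } else break;
    }
    ++k;
    v[k] = q;
    z[k] = inter;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (z[k + 1] < xq) ++k;
    double xv = v[k] * s;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// Squared Euclidean distance (mm^2) from each voxel center to the nearest
// TRUE voxel center of `mask`, honoring anisotropic spacing.
// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : BIG;

  // pass along x (fastest index)
  {
    std::vector<double> f(nx), d(nx);
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
        for (int i = 0; i < nx; ++i) f[i] = out[base + i];
        dt1d(f, d, nx, spacing[0]);
        for (int i = 0; i < nx; ++i) out[base + i] = d[i];
      }
  }
  // pass along y
  {
    std::vector<double> f(ny), d(ny);
    for (int k = 0; k < nz; ++k)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t base = (R_xlen_t)k * nx * ny + i;
        for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)j * nx];
        dt1d(f, d, ny, spacing[1]);
        for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)j * nx] = d[j];
      }
  }
  // pass along z
  {
    std::vector<double> f(nz), d(nz);
    R_xlen_t nxy = (R_xlen_t)nx * ny;
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t base = (R_xlen_t)j * nx + i;
        for (int k = 0; k < nz; ++k) f[k] = out[base + (R_xlen_t)k * nxy];
        dt1d(f, d, nz, spacing[2]);
        for (int k = 0; k < nz; ++k) out[base + (R_xlen_t)k * nxy] = d[k];
      }
  }
  return out;
}

static inline double trilinear(const double* vol, int nx, int ny, int nz,
                               double gx, double gy, double gz) {
  if (gx < 0) gx = 0; if (gx > nx - 1) gx = nx - 1;
  if (gy < 0) gy = 0; if (gy > ny - 1) gy = ny - 1;
  if (gz < 0) gz = 0; if (gz > nz - 1) gz = nz - 1;
  int i0 = (int)gx, j0 = (int)gy, k0 = (int)gz;
  int i1 = i0 < nx - 1 ? i0 + 1 : i0;
  int j1 = j0 < ny - 1 ? j0 + 1 : j0;
  int k1 = k0 < nz - 1 ? k0 + 1 : k0;
  double fx = gx - i0, fy = gy - j0, fz = gz - k0;
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  #define V(i, j, k) vol[(R_xlen_t)(k) * nxy + (R_xlen_t)(j) * nx + (i)]
  double c00 = V(i0, j0, k0) * (1 - fx) + V(i1, j0, k0) * fx;
  double c10 = V(i0, j1, k0) * (1 - fx) + V(i1, j1, k0) * fx;
  double c01 = V(i0, j0, k1) * (1 - fx) + V(i1, j0, k1) * fx;
  double c11 = V(i0, j1, k1) * (1 - fx) + V(i1, j1, k1) * fx;
  #undef V
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

static inline double bilinear(const double* img, int nu, int nv,
                              double u, double v) {
  // zero outside the image
  if (u < 0 || v < 0 || u > nu - 1 || v > nv - 1) return 0.0;
  int i0 = (int)u, j0 = (int)v;
  int i1 = i0 < nu - 1 ? i0 + 1 : i0;
  int j1 = j0 < nv - 1 ? j0 + 1 : j0;
  double fu = u - i0, fv = v - j0;
  double a = img[(R_xlen_t)j0 * nu + i0] * (1 - fu) + img[(R_xlen_t)j0 * nu + i1] * fu;
  double b = img[(R_xlen_t)j1 * nu + i0] * (1 - fu) + img[(R_xlen_t)j1 * nu + i1] * fu;
  return a * (1 - fv) + b * fv;
}

// Dose from one arc control point.
// density: column-major nx*ny*nz relative-electron-density grid (0 outside body).
// trans:   transmission image in the isocenter plane, rows = leaf-travel axis
//          (x_bev), cols = leaf-stack axis (z_bev); pixel (r,c) center at
//          (tx0 + r*pitch, tz0 + c*pitch).
// Per voxel: T * f_fff(r) * exp(-mu * d_eff) * (SAD / dist)^2, where d_eff is
// the line integral of density from the grid boundary to the voxel along the
// source ray (density is zero outside the body, so this is water-equivalent
// depth from the body surface).
// [[Rcpp::export]]
NumericVector cp_dose_cpp(NumericVector density, IntegerVector dim,
                          NumericVector spacing, NumericVector origin,
                          NumericMatrix trans, double tx0, double tz0,
                          double pitch,
                          NumericVector src, NumericVector iso,
                          NumericVector ex, NumericVector ez,
                          double sad, double mu, double kfff,
                          double step, double tmin) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  const double* vol = density.begin();
  const double* img = trans.begin();
  const int ntx = trans.nrow(), ntz = trans.ncol();

  double ub[3];  // unit beam axis, source -> isocenter
  double sl = 0;
  for (int a = 0; a < 3; ++a) { ub[a] = iso[a] - src[a]; sl += ub[a] * ub[a]; }
  sl = std::sqrt(sl);
  for (int a = 0; a < 3; ++a) ub[a] /= sl;

  double blo[3], bhi[3];
  for (int a = 0; a < 3; ++a) {
    blo[a] = origin[a] - 0.5 * spacing[a];
    bhi[a] = origin[a] + (dim[a] - 0.5) * spacing[a];
  }

  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    double wz = origin[2] + k * spacing[2];
    for (int j = 0; j < ny; ++j) {
      double wy = origin[1] + j * spacing[1];
      for (int i = 0; i < nx; ++i, ++idx) {
        double wx = origin[0] + i * spacing[0];
        double dvx = wx - src[0], dvy = wy - src[1], dvz = wz - src[2];
        double daxis = dvx * ub[0] + dvy * ub[1] + dvz * ub[2];
        if (daxis < 1e-6) continue;
        double mag = sad / daxis;
        double rx = wx - iso[0], ry = wy - iso[1], rz = wz - iso[2];
        double xb = (rx * ex[0] + ry * ex[1] + rz * ex[2]) * mag;
        double zb = (rx * ez[0] + ry * ez[1] + rz * ez[2]) * mag;
        double T = bilinear(img, ntx, ntz, (xb - tx0) / pitch, (zb - tz0) / pitch);
        if (T < tmin) continue;
        double f = 1.0 - kfff * std::sqrt(xb * xb + zb * zb);
        if (f <= 0) continue;
        double dist2 = dvx * dvx + dvy * dvy + dvz * dvz;
        double L = std::sqrt(dist2);
        double dirx = dvx / L, diry = dvy / L, dirz = dvz / L;
        // ray/grid-box intersection
        double t0 = 0.0, t1 = L;
        double dira[3] = {dirx, diry, dirz}, srca[3] = {src[0], src[1], src[2]};
        bool hit = true;
        for (int a = 0; a < 3; ++a) {
          if (std::fabs(dira[a]) < 1e-12) {
            if (srca[a] < blo[a] || srca[a] > bhi[a]) { hit = false; break; }
          } else {
            double tA = (blo[a] - srca[a]) / dira[a];
            double tB = (bhi[a] - srca[a]) / dira[a];
            if (tA > tB) std::swap(tA, tB);
            if (tA > t0) t0 = tA;
            if (tB < t1) t1 = tB;
            if (t0 >= t1) { hit = false; break; }
          }
        }
        double deff = 0.0;
        if (hit && t1 > t0) {
          int nsteps = (int)std::ceil((t1 - t0) / step);
          if (nsteps < 1) nsteps = 1;
          double h = (t1 - t0) / nsteps;
          for (int s = 0; s < nsteps; ++s) {
            double t = t0 + (s + 0.5) * h;
            double px = src[0] + t * dirx;
            double py = src[1] + t * diry;
            double pz = src[2] + t * dirz;
            deff += trilinear(vol, nx, ny, nz,
                              (px - origin[0]) / spacing[0],
                              (py - origin[1]) / spacing[1],
                              (pz - origin[2]) / spacing[2]) * h;
          }
        }
        out[idx] = T * f * std::exp(-mu * deff) * (sad * sad) / dist2;
      }
    }
  }
  return out;
}
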