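#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Volumes are passed as flat numeric vectors in R array order:
// index = i + nx * (j + ny * k), i along x (patient left), j along y
// (posterior), k along z (superior).  All coordinates are physical mm.

// Even-odd (crossing number) point-in-polygon test for a batch of points
// against one closed planar polygon.  Edges are half-open so points are
// counted once when the polygon is closed (first vertex == last vertex).
// [[Rcpp::export]]
LogicalVector c_points_in_polygon(NumericVector px, NumericVector py,
                                  NumericVector vx, NumericVector vy) {
  const int np = px.size();
  const int nv = vx.size();
  LogicalVector inside(np);
  for (int p = 0; p < np; ++p) {
    const double x = px[p], y = py[p];
    bool in = false;
    for (int a = 0, b = nv - 1; a < nv; b = a++) {
      const bool cross = ((vy[a] > y) != (vy[b] > y));
      if (cross) {
        const double xint = vx[b] + (y - vy[b]) * (vx[a] - vx[b]) / (vy[a] - vy[b]);
        if (x < xint) in = !in;
      }
    }
    inside[p] = in;
  }
  return inside;
}

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Trilinear interpolation of a volume at arbitrary physical points.
// Points outside the volume extent (beyond the outermost voxel centers)
// receive `fill` and are counted.  Used for dose resampling.
// [[Rcpp::export]]
List c_trilinear(NumericVector vol, IntegerVector dim,
                 NumericVector origin, NumericVector spacing,
                 NumericMatrix pts, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = pts.nrow();
  NumericVector out(n);
  int n_outside = 0;
  for (int p = 0; p < n; ++p) {
    const double tx = (pts(p, 0) - origin[0]) / spacing[0];
    const double ty = (pts(p, 1) - origin[1]) / spacing[1];
    const double tz = (pts(p, 2) - origin[2]) / spacing[2];
    if (tx < 0 || ty < 0 || tz < 0 ||
        tx > nx - 1 || ty > ny - 1 || tz > nz - 1) {
      out[p] = fill;
      ++n_outside;
      continue;
    }
    int i0 = (int)std::floor(tx), j0 = (int)std::floor(ty), k0 = (int)std::floor(tz);
    if (i0 > nx - 2) i0 = nx - 2; if (i0 < 0) i0 = 0;
    if (j0 > ny - 2) j0 = ny - 2; if (j0 < 0) j0 = 0;
    if (k0 > nz - 2) k0 = nz - 2; if (k0 < 0) k0 = 0;
    const double fx = tx - i0, fy = ty - j0, fz = tz - k0;
    const int i1 = nx > 1 ? i0 + 1 : i0;
    const int j1 = ny > 1 ? j0 + 1 : j0;
    const int k1 = nz > 1 ? k0 + 1 : k0;
#define V(i, j, k) vol[(i) + nx * ((j) + (size_t)ny * (k))]
    const double c00 = V(i0, j0, k0) * (1 - fx) + V(i1, j0, k0) * fx;
    const double c10 = V(i0, j1, k0) * (1 - fx) + V(i1, j1, k0) * fx;
    const double c01 = V(i0, j0, k1) * (1 - fx) + V(i1, j0, k1) * fx;
    const double c11 = V(i0, j1, k1) * (1 - fx) + V(i1, j1, k1) * fx;
#undef V
    const double c0 = c00 * (1 - fy) + c10 * fy;
    const double c1 = c01 * (1 - fy) + c11 * fy;
    out[p] = c0 * (1 - fz) + c1 * fz;
  }
  return List::create(_["values"] = out, _["n_outside"] = n_outside);
}

// Cubic B-spline basis weights for fractional offset u in [0,1), applied to
// control points base-1 .. base+2.
static inline void bspline_w(double u, double *w) {
  const double u2 = u * u, u3 = u2 * u;
  w[0] = (1 - 3 * u + 3 * u2 - u3) / 6.0;
  w[1] = (3 * u3 - 6 * u2 + 4) / 6.0;
  w[2] = (-3 * u3 + 3 * u2 + 3 * u + 1) / 6.0;
  w[3] = u3 / 6.0;
}

struct AxisTab {
  std::vector<int> base;      // first contributing control index per voxel
  std::vector<double> w;      // 4 weights per voxel
};

static AxisTab axis_table(int n, double origin, double spacing,
                          int nc, double corigin, double cspacing) {
  AxisTab t;
  t.base.resize(n);
  t.w.resize(4 * (size_t)n);
  for (int i = 0; i < n; ++i) {
    const double x = origin + i * spacing;
    double s = (x - corigin) / cspacing;
    int i0 = (int)std::floor(s);
    double u = s - i0;
    int b = i0 - 1;
    // clamp support into the control grid (wrapper allocates a margin so
    // this only triggers by rounding at the very edge)
    if (b < 0) { b = 0; }
    if (b > nc - 4) { b = nc - 4; }
    t.base[i] = b;
    bspline_w(u, &t.w[4 * (size_t)i]);
  }
  return t;
}

// Dense displacement field of a cubic B-spline transform evaluated at the
// voxel centers of a target grid.  coef layout: i + ncx*(j + ncy*(k + ncz*d)).
// [[Rcpp::export]]
NumericMatrix c_bspline_field(NumericVector coef, IntegerVector cdim,
                              NumericVector corigin, NumericVector cspacing,
                              IntegerVector gdim, NumericVector gorigin,
                              NumericVector gspacing) {
  const int nx = gdim[0], ny = gdim[1], nz = gdim[2];
  const int ncx = cdim[0], ncy = cdim[1], ncz = cdim[2];
  const size_t ncxyz = (size_t)ncx * ncy * ncz;
  AxisTab tx = axis_table(nx, gorigin[0], gspacing[0], ncx, corigin[0], cspacing[0]);
  AxisTab ty = axis_table(ny, gorigin[1], gspacing[1], ncy, corigin[1], cspacing[1]);
  AxisTab tz = axis_table(nz, gorigin[2], gspacing[2], ncz, corigin[2], cspacing[2]);
  NumericMatrix out((size_t)nx * ny * nz, 3);
  size_t row = 0;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i, ++row) {
        double u0 = 0, u1 = 0, u2 = 0;
        for (int c = 0; c < 4; ++c) {
          const int kc = tz.base[k] + c;
          const double wz = tz.w[4 * (size_t)k + c];
          for (int b = 0; b < 4; ++b) {
            const int jc = ty.base[j] + b;
            const double wyz = ty.w[4 * (size_t)j + b] * wz;
            const size_t off = ncx * ((size_t)jc + (size_t)ncy * kc);
            for (int a = 0; a < 4; ++a) {
              const double w = tx.w[4 * (size_t)i + a] * wyz;
              const size_t ci = (size_t)(tx.base[i] + a) + off;
              u0 += w * coef[ci];
              u1 += w * coef[ci + ncxyz];
              u2 += w * coef[ci + 2 * ncxyz];
            }
          }
        }
        out(row, 0) = u0; out(row, 1) = u1; out(row, 2) = u2;
      }
    }
  }
  return out;
}

static inline double sample_clamp(const double *vol, int nx, int ny, int nz,
                                  double tx, double ty, double tz) {
  tx = clampd(tx, 0, nx - 1);
  ty = clampd(ty, 0, ny - 1);
  tz = clampd(tz, 0, nz - 1);
  int i0 = (int)std::floor(tx), j0 = (int)std::floor(ty), k0 = (int)std::floor(tz);
  if (i0 > nx - 2) i0 = nx > 1 ? nx - 2 : 0;
  if (j0 > ny - 2) j0 = ny > 1 ? ny - 2 : 0;
  if (k0 > nz - 2) k0 = nz > 1 ? nz - 2 : 0;
  const double fx = tx - i0, fy = ty - j0, fz = tz - k0;
  const int i1 = nx > 1 ? i0 + 1 : i0;
  const int j1 = ny > 1 ? j0 + 1 : j0;
  const int k1 = nz > 1 ? k0 + 1 : k0;
#define V(i, j, k) vol[(i) + nx * ((j) + (size_t)ny * (k))]
  const double c00 = V(i0, j0, k0) * (1 - fx) + V(i1, j0, k0) * fx;
  const double c10 = V(i0, j1, k0) * (1 - fx) + V(i1, j1, k0) * fx;
  const double c01 = V(i0, j0, k1) * (1 - fx) + V(i1, j0, k1) * fx;
  const double c11 = V(i0, j1, k1) * (1 - fx) + V(i1, j1, k1) * fx;
#undef V
  const double c0 = c00 * (1 - fy) + c10 * fy;
  const double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Mean-squared-error cost and analytic gradient with respect to the B-spline
// coefficients, for a fixed image and a moving image with precomputed
// spatial gradient volumes (mm^-1 units handled by the caller).
// [[Rcpp::export]]
List c_reg_cost_grad(NumericVector fvol, IntegerVector fdim,
                     NumericVector forigin, NumericVector fspacing,
                     NumericVector mvol, NumericVector mgx, NumericVector mgy,
                     NumericVector mgz, IntegerVector mdim,
                     NumericVector morigin, NumericVector mspacing,
                     NumericVector coef, IntegerVector cdim,
                     NumericVector corigin, NumericVector cspacing,
                     bool want_grad) {
  const int nx = fdim[0], ny = fdim[1], nz = fdim[2];
  const int mx = mdim[0], my = mdim[1], mz = mdim[2];
  const int ncx = cdim[0], ncy = cdim[1], ncz = cdim[2];
  const size_t ncxyz = (size_t)ncx * ncy * ncz;
  AxisTab tx = axis_table(nx, forigin[0], fspacing[0], ncx, corigin[0], cspacing[0]);
  AxisTab ty = axis_table(ny, forigin[1], fspacing[1], ncy, corigin[1], cspacing[1]);
  AxisTab tz = axis_table(nz, forigin[2], fspacing[2], ncz, corigin[2], cspacing[2]);
  NumericVector grad(want_grad ? 3 * ncxyz : (size_t)1);
  double cost = 0;
  const size_t n = (size_t)nx * ny * nz;
  const double *mv = mvol.begin();
  const double *gxv = mgx.begin(), *gyv = mgy.begin(), *gzv = mgz.begin();
  size_t row = 0;
  for (int k = 0; k < nz; ++k) {
    const double z = forigin[2] + k * fspacing[2];
    for (int j = 0; j < ny; ++j) {
      const double y = forigin[1] + j * fspacing[1];
      for (int i = 0; i < nx; ++i, ++row) {
        const double x = forigin[0] + i * fspacing[0];
        double u0 = 0, u1 = 0, u2 = 0;
        for (int c = 0; c < 4; ++c) {
          const int kc = tz.base[k] + c;
          const double wz = tz.w[4 * (size_t)k + c];
          for (int b = 0; b < 4; ++b) {
            const int jc = ty.base[j] + b;
            const double wyz = ty.w[4 * (size_t)j + b] * wz;
            const size_t off = ncx * ((size_t)jc + (size_t)ncy * kc);
            for (int a = 0; a < 4; ++a) {
              const double w = tx.w[4 * (size_t)i + a] * wyz;
              const size_t ci = (size_t)(tx.base[i] + a) + off;
              u0 += w * coef[ci];
              u1 += w * coef[ci + ncxyz];
              u2 += w * coef[ci + 2 * ncxyz];
            }
          }
        }
        const double px = (x + u0 - morigin[0]) / mspacing[0];
        const double py = (y + u1 - morigin[1]) / mspacing[1];
        const double pz = (z + u2 - morigin[2]) / mspacing[2];
        const double m = sample_clamp(mv, mx, my, mz, px, py, pz);
        const double r = m - fvol[row];
        cost += r * r;
        if (want_grad) {
          const double gx = sample_clamp(gxv, mx, my, mz, px, py, pz);
          const double gy = sample_clamp(gyv, mx, my, mz, px, py, pz);
          const double gz = sample_clamp(gzv, mx, my, mz, px, py, pz);
          const double f = 2.0 * r / n;
          for (int c = 0; c < 4; ++c) {
            const int kc = tz.base[k] + c;
            const double wz = tz.w[4 * (size_t)k + c];
            for (int b = 0; b < 4; ++b) {
              const int jc = ty.base[j] + b;
              const double wyz = ty.w[4 * (size_t)j + b] * wz;
              const size_t off = ncx * ((size_t)jc + (size_t)ncy * kc);
              for (int a = 0; a < 4; ++a) {
                const double w = tx.w[4 * (size_t)i + a] * wyz;
                const size_t ci = (size_t)(tx.base[i] + a) + off;
                grad[ci] += f * w * gx;
                grad[ci + ncxyz] += f * w * gy;
                grad[ci + 2 * ncxyz] += f * w * gz;
              }
            }
          }
        }
      }
    }
  }
  cost /= n;
  return List::create(_["cost"] = cost, _["grad"] = grad);
}
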