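#ifndef AORTAPWV_CORE_H
#define AORTAPWV_CORE_H

#include <Rcpp.h>
#include <cmath>

// Voxel grid with world mapping: world = org + dir %*% (spc * ijk), 0-based ijk.
struct Grid {
  int nx, ny, nz;
  double spc[3], org[3];
  double dir[9];  // row-major
  double inv[9];  // inverse of dir, row-major
  const double *dat;

  void init(const Rcpp::NumericVector &data, const Rcpp::IntegerVector &dim,
            const Rcpp::NumericVector &spacing, const Rcpp::NumericVector &origin,
            const Rcpp::NumericMatrix &direction) {
    nx = dim[0]; ny = dim[1]; nz = dim[2];
    for (int a = 0; a < 3; ++a) { spc[a] = spacing[a]; org[a] = origin[a]; }
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 3; ++c) dir[3 * r + c] = direction(r, c);
    // 3x3 inverse via adjugate
    const double *d = dir;
    double det = d[0]*(d[4]*d[8]-d[5]*d[7]) - d[1]*(d[3]*d[8]-d[5]*d[6])
               + d[2]*(d[3]*d[7]-d[4]*d[6]);
    if (std::fabs(det) < 1e-12) Rcpp::stop("singular direction matrix");
    double id = 1.0 / det;
    inv[0] =  (d[4]*d[8]-d[5]*d[7]) * id;
    inv[1] = -(d[1]*d[8]-d[2]*d[7]) * id;
    inv[2] =  (d[1]*d[5]-d[2]*d[4]) * id;
    inv[3] = -(d[3]*d[8]-d[5]*d[6]) * id;
    inv[4] =  (d[0]*d[8]-d[2]*d[6]) * id;
    inv[5] = -(d[0]*d[5]-d[2]*d[3]) * id;
    inv[6] =  (d[3]*d[7]-d[4]*d[6]) * id;
    inv[7] = -(d[0]*d[7]-d[1]*d[6]) * id;
    inv[8] =  (d[0]*d[4]-d[1]*d[3]) * id;
    dat = &data[0];
  }

  inline long idx(int i, int j, int k) const {
    return (long)i + (long)nx * ((long)j + (long)ny * (long)k);
  }

  inline void voxel_to_world(double i, double j, double k, double *w) const {
    double v[3] = { spc[0]*i, spc[1]*j, spc[2]*k };
    for (int r = 0; r < 3; ++r)
      w[r] = org[r] + dir[3*r]*v[0] + dir[3*r+1]*v[1] + dir[3*r+2]*v[2];
  }

  inline void world_to_voxel(const double *w, double *v) const {
    double q[3] = { w[0]-org[0], w[1]-org[1], w[2]-org[2] };
    for (int r = 0; r < 3; ++r)
      v[r] = (inv[3*r]*q[0] + inv[3*r+1]*q[1] + inv[3*r+2]*q[2]) / spc[r];
  }

  // trilinear interpolation at continuous 0-based voxel coords; ok=false outside
  inline double trilinear(double x, double y, double z, bool *ok) const {
    if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
      *ok = false; return 0.0;
    }
    *ok = true;
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 >= nx - 1) i0 = nx - 2; if (i0 < 0) i0 = 0;
    if (j0 >= ny - 1) j0 = ny - 2; if (j0 < 0) j0 = 0;
    if (k0 >= nz - 1) k0 = nz - 2; if (k0 < 0) k0 = 0;
    if (nx == 1) { i0 = 0; x = 0; }
    if (ny == 1) { j0 = 0; y = 0; }
    if (nz == 1) { k0 = 0; z = 0; }
    double fx = x - i0, fy = y - j0, fz = z - k0;
    int i1 = (nx == 1) ? i0 : i0 + 1;
    int j1 = (ny == 1) ? j0 : j0 + 1;
    int k1 = (nz == 1) ? k0 : k0 + 1;
    double c000 = dat[idx(i0,j0,k0)], c100 = dat[idx(i1,j0,k0)];
    double c010 = dat[idx(i0,j1,k0)], c110 = dat[idx(i1,j1,k0)];
    double c001 = dat[idx(i0,j0,k1)], c101 = dat[idx(i1,j0,k1)];
    double c011 = dat[idx(i0,j1,k1)], c111 = dat[idx(i1,j1,k1)];
    double c00 = c000*(1-fx) + c100*fx, c10 = c010*(1-fx) + c110*fx;
    double c01 = c001*(1-fx) + c101*fx, c11 = c011*(1-fx) + c111*fx;
    double c0 = c00*(1-fy) + c10*fy, c1 = c01*(1-fy) + c11*fy;
    return c0*(1-fz) + c1*fz;
  }

  inline double nearest(double x, double y, double z, bool *ok) const {
    int i = (int)std::lround(x), j = (int)std::lround(y), k = (int)std::lround(z);
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) {
      *ok = false; return 0.0;
    }
    *ok = true;
    return dat[idx(i, j, k)];
  }
};

// Cubic B-spline free-form deformation: displacement field over a control grid.
// coef layout matches an R array [nx, ny, nz, 3].
struct BsplineField {
  int nx, ny, nz;
  double org[3], spc[3];
  const double *coef;
  bool active;

  BsplineField() : active(false) {}

  void init(const Rcpp::List &bs) {
    Rcpp::NumericVector o = bs["origin"], s = bs["spacing"], cf = bs["coef"];
    Rcpp::IntegerVector d = bs["dims"];
    nx = d[0]; ny = d[1]; nz = d[2];
    for (int a = 0; a < 3; ++a) { org[a] = o[a]; spc[a] = s[a]; }
    coef = &cf[0];
    active = true;
  }

  static inline double b3(double u, int p) {
    // uniform cubic B-spline basis, u in [0,1), p in 0..3 (control i-1..i+2)
    double v = 1 - u;
    switch (p) {
      case 0: return v*v*v/6.0;
      case 1: return (3*u*u*u - 6*u*u + 4)/6.0;
      case 2: return (-3*u*u*u + 3*u*u + 3*u + 1)/6.0;
      default: return u*u*u/6.0;
    }
  }

  // weights and control-point base index along one axis
  inline void weights(double t, int *i0, double *w) const {
    int fl = (int)std::floor(t);
    double u = t - fl;
    *i0 = fl - 1;
    w[0] = b3(u, 0); w[1] = b3(u, 1); w[2] = b3(u, 2); w[3] = b3(u, 3);
  }

  inline long cidx(int i, int j, int k, int dim) const {
    return (long)i + (long)nx * ((long)j + (long)ny * ((long)k + (long)nz * dim));
  }

  // displacement at world point y; missing control points count as zero
  inline void disp(const double *y, double *d) const {
    d[0] = d[1] = d[2] = 0.0;
    if (!active) return;
    double wx[4], wy[4], wz[4];
    int ix, iy, iz;
    weights((y[0]-org[0])/spc[0], &ix, wx);
    weights((y[1]-org[1])/spc[1], &iy, wy);
    weights((y[2]-org[2])/spc[2], &iz, wz);
    for (int c = 0; c < 4; ++c) {
      int kk = iz + c; if (kk < 0 || kk >= nz) continue;
      for (int b = 0; b < 4; ++b) {
        int jj = iy + b; if (jj < 0 || jj >= ny) continue;
        double wyz = wy[b]*wz[c];
        for (int a = 0; a < 4; ++a) {
          int ii = ix + a; if (ii < 0 || ii >= nx) continue;
          double w = wx[a]*wyz;
          d[0] += w * coef[cidx(ii,jj,kk,0)];
          d[1] += w * coef[cidx(ii,jj,kk,1)];
          d[2] += w * coef[cidx(ii,jj,kk,2)];
        }
      }
    }
  }
};

inline void apply_affine4(const double *A, const double *x, double *y) {
  // A row-major 4x4 (only first 3 rows used)
  for (int r = 0; r < 3; ++r)
    y[r] = A[4*r]*x[0] + A[4*r+1]*x[1] + A[4*r+2]*x[2] + A[4*r+3];
}

#endif
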