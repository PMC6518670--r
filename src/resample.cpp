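#include "core.h"
using namespace Rcpp;

// Resample a source volume onto a target grid through T(x) = B(A x) where
// A is a 4x4 world affine and B an optional B-spline displacement
// (B(y) = y + D(y)). interp: 0 = nearest neighbour, 1 = trilinear.
// [[Rcpp::export]]
NumericVector cpp_resample_volume(NumericVector srcData, IntegerVector srcDim,
                                  NumericVector srcSpc, NumericVector srcOrg,
                                  NumericMatrix srcDir,
                                  IntegerVector tgtDim, NumericVector tgtSpc,
                                  NumericVector tgtOrg, NumericMatrix tgtDir,
                                  NumericMatrix affine, Nullable<List> bspline,
                                  int interp, double background) {
  Grid src; src.init(srcData, srcDim, srcSpc, srcOrg, srcDir);
  NumericVector dummy(1);
  Grid tgt;
  {
    // target grid carries no data; reuse Grid for geometry only
    tgt.init(dummy, tgtDim, tgtSpc, tgtOrg, tgtDir);
  }
  double A[16];
  for (int r = 0; r < 4; ++r)
    for (int c = 0; c < 4; ++c) A[4*r+c] = affine(r, c);
  BsplineField bs;
  if (bspline.isNotNull()) bs.init(bspline.get());

  long n = (long)tgt.nx * tgt.ny * tgt.nz;
  NumericVector out(n);
  double w[3], y[3], d[3], v[3];
  long p = 0;
  for (int k = 0; k < tgt.nz; ++k)
    for (int j = 0; j < tgt.ny; ++j)
      for (int i = 0; i < tgt.nx; ++i, ++p) {
        tgt.voxel_to_world(i, j, k, w);
        apply_affine4(A, w, y);
        if (bs.active) { bs.disp(y, d); y[0]+=d[0]; y[1]+=d[1]; y[2]+=d[2]; }
        src.world_to_voxel(y, v);
        bool ok;
        double val = (interp == 0) ? src.nearest(v[0], v[1], v[2], &ok)
                                   : src.trilinear(v[0], v[1], v[2], &ok);
        out[p] = ok ? val : background;
      }
  return out;
}

// Trilinear sample of a volume at world points (n x 3); NA outside.
// [[Rcpp::export]]
NumericVector cpp_sample_points(NumericVector data, IntegerVector dim,
                                NumericVector spc, NumericVector org,
                                NumericMatrix dir, NumericMatrix pts) {
  Grid g; g.init(data, dim, spc, org, dir);
  int n = pts.nrow();
  NumericVector out(n);
  double w[3], v[3];
  for (int i = 0; i < n; ++i) {
    w[0] = pts(i,0); w[1] = pts(i,1); w[2] = pts(i,2);
    g.world_to_voxel(w, v);
    bool ok;
    double val = g.trilinear(v[0], v[1], v[2], &ok);
    out[i] = ok ? val : NA_REAL;
  }
  return out;
}

// B-spline displacement at world points (n x 3) -> n x 3 displacements.
// [[Rcpp::export]]
NumericMatrix cpp_bspline_disp(List bs, NumericMatrix pts) {
  BsplineField f; f.init(bs);
  int n = pts.nrow();
  NumericMatrix out(n, 3);
  double y[3], d[3];
  for (int i = 0; i < n; ++i) {
    y[0] = pts(i,0); y[1] = pts(i,1); y[2] = pts(i,2);
    f.disp(y, d);
    out(i,0) = d[0]; out(i,1) = d[1]; out(i,2) = d[2];
  }
  return out;
}

// Separable Gaussian smoothing, sigma in voxels per axis, reflected boundary.
// [[Rcpp::export]]
NumericVector cpp_smooth3d(NumericVector data, IntegerVector dim,
                           NumericVector sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long n = (long)nx * ny * nz;
  std::vector<double> buf(data.begin(), data.end()), tmp(n);
  int strides[3] = {1, nx, nx * ny};
  int sizes[3] = {nx, ny, nz};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0 || sizes[ax] == 1) continue;
    int rad = (int)std::ceil(3.0 * s);
    std::vector<double> ker(2*rad + 1);
    double sum = 0;
    for (int t = -rad; t <= rad; ++t) {
      ker[t+rad] = std::exp(-0.5 * t * t / (s * s));
      sum += ker[t+rad];
    }
    for (double &kv : ker) kv /= sum;
    int st = strides[ax], sz = sizes[ax];
    long nline = n / sz;
    // iterate all lines along axis ax
    for (long line = 0; line < nline; ++line) {
      // compute base index of this line
      long rem = line, base = 0;
      for (int a = 0; a < 3; ++a) {
        if (a == ax) continue;
        long c = rem % sizes[a];
        rem /= sizes[a];
        base += c * strides[a];
      }
      for (int p = 0; p < sz; ++p) {
        double acc = 0;
        for (int t = -rad; t <= rad; ++t) {
          int q = p + t;
          if (q < 0) q = -q - 1;
          if (q >= sz) q = 2*sz - q - 1;
          if (q < 0) q = 0;
          if (q >= sz) q = sz - 1;
          acc += ker[t+rad] * buf[base + (long)q * st];
        }
        tmp[base + (long)p * st] = acc;
      }
    }
    buf.swap(tmp);
  }
  return NumericVector(buf.begin(), buf.end());
}

// Connected-component labelling (conn = 6 or 26); labels 1..K, 0 background.
// [[Rcpp::export]]
IntegerVector cpp_label_cc(IntegerVector mask, IntegerVector dim, int conn) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long n = (long)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<long> stack;
  int next = 0;
  for (long s = 0; s < n; ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      long cur = stack.back(); stack.pop_back();
      int ci = cur % nx, cj = (cur / nx) % ny, ck = cur / ((long)nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            int ad = std::abs(di) + std::abs(dj) + std::abs(dk);
            if (ad == 0) continue;
            if (conn == 6 && ad > 1) continue;
            int ii = ci + di, jj = cj + dj, kk = ck + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            long q = (long)ii + (long)nx * ((long)jj + (long)ny * kk);
            if (mask[q] != 0 && lab[q] == 0) { lab[q] = next; stack.push_back(q); }
          }
    }
  }
  return lab;
}
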