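#include "core.h"
using namespace Rcpp;

// Cubic B-spline Parzen kernel and derivative (support (-2, 2)).
static inline double parzen(double x) {
  double a = std::fabs(x);
  if (a < 1) return (4 - 6*a*a + 3*a*a*a) / 6.0;
  if (a < 2) { double v = 2 - a; return v*v*v / 6.0; }
  return 0.0;
}
static inline double parzen_d(double x) {
  double a = std::fabs(x), d;
  if (a < 1) d = (-12*a + 9*a*a) / 6.0;
  else if (a < 2) { double v = 2 - a; d = -v*v / 2.0; }
  else return 0.0;
  return x < 0 ? -d : d;
}

struct MIWork {
  int bins;
  std::vector<double> joint, pf, pm, lterm;
  void reset(int b) {
    bins = b;
    joint.assign(b * b, 0.0);
    pf.assign(b, 0.0); pm.assign(b, 0.0);
    lterm.assign(b * b, 0.0);
  }
};

// Mutual information (nats) from paired samples: fixed binned order-0,
// moving spread with a cubic Parzen window. Also fills lterm = log(p/pm)
// for the gradient pass. mtil: continuous moving bin coordinate per sample.
static double mi_from_hist(MIWork &w, int nvalid) {
  int B = w.bins;
  for (int f = 0; f < B; ++f)
    for (int m = 0; m < B; ++m) {
      w.joint[f*B + m] /= nvalid;
      w.pf[f] += w.joint[f*B + m];
      w.pm[m] += w.joint[f*B + m];
    }
  double mi = 0;
  for (int f = 0; f < B; ++f)
    for (int m = 0; m < B; ++m) {
      double p = w.joint[f*B + m];
      if (p > 0 && w.pf[f] > 0 && w.pm[m] > 0) {
        mi += p * std::log(p / (w.pf[f] * w.pm[m]));
        w.lterm[f*B + m] = std::log(p / w.pm[m]);
      }
    }
  return mi;
}

// One stage of intensity-based registration by stochastic gradient ascent on
// Parzen-window mutual information.
//   model 0: affine stage S(y) = (I + L)(y - c) + c + t on top of init affine
//   model 1: B-spline displacement on top of init affine: T(x) = y + D(y),
//            y = A x, D given by a control grid (coef optimised)
// cand: 0-based linear indices of fixed voxels eligible for sampling.
// Returns list(params, mi_trace, valid_frac). Deterministic given R's RNG.
// [[Rcpp::export]]
List cpp_register_stage(NumericVector fdat, IntegerVector fdim, NumericVector fspc,
                        NumericVector forg, NumericMatrix fdir,
                        NumericVector mdat, IntegerVector mdim, NumericVector mspc,
                        NumericVector morg, NumericMatrix mdir,
                        IntegerVector cand, int model, NumericMatrix initAffine,
                        Nullable<List> bsInit, NumericVector center,
                        int iterations, int nSamples, int bins,
                        double step0, double gainA, double gainAlpha, double rho) {
  Grid F; F.init(fdat, fdim, fspc, forg, fdir);
  Grid M; M.init(mdat, mdim, mspc, morg, mdir);
  double A[16];
  for (int r = 0; r < 4; ++r)
    for (int c = 0; c < 4; ++c) A[4*r+c] = initAffine(r, c);

  // intensity ranges
  double fmin = R_PosInf, fmax = R_NegInf, mmin = R_PosInf, mmax = R_NegInf;
  for (double v : fdat) { if (v < fmin) fmin = v; if (v > fmax) fmax = v; }
  for (double v : mdat) { if (v < mmin) mmin = v; if (v > mmax) mmax = v; }
  if (fmax <= fmin) fmax = fmin + 1;
  if (mmax <= mmin) mmax = mmin + 1;
  double mscale = (bins - 5.0) / (mmax - mmin);  // maps to [2, bins-3]

  // parameters
  int nPar;
  BsplineField bs;
  std::vector<double> coefLocal;
  int gnx = 0, gny = 0, gnz = 0;
  double gorg[3] = {0,0,0}, gspc[3] = {1,1,1};
  if (model == 0) {
    nPar = 12;  // 9 linear (row-major) + 3 translation
  } else {
    List b = bsInit.get();
    NumericVector o = b["origin"], s = b["spacing"], cf = b["coef"];
    IntegerVector d = b["dims"];
    gnx = d[0]; gny = d[1]; gnz = d[2];
    for (int a = 0; a < 3; ++a) { gorg[a] = o[a]; gspc[a] = s[a]; }
    nPar = gnx * gny * gnz * 3;
    coefLocal.assign(cf.begin(), cf.end());
  }
  std::vector<double> par(nPar, 0.0), grad(nPar), best(nPar, 0.0);
  if (model == 1) { par = coefLocal; best = par; }

  double cc[3] = { center[0], center[1], center[2] };
  int nCand = cand.size();
  if (nCand < 1) stop("no candidate sample voxels");

  MIWork w;
  NumericVector trace(iterations);
  double bestMI = R_NegInf;
  double hM = 0.5 * std::min(mspc[0], std::min(mspc[1], mspc[2]));
  double validFrac = 1.0;

  std::vector<double> mtil(nSamples), gM(nSamples * 3), y0s(nSamples * 3);
  std::vector<int> fb(nSamples);

  RNGScope scope;

  for (int it = 0; it < iterations; ++it) {
    w.reset(bins);
    int nvalid = 0;
    for (int s = 0; s < nSamples; ++s) {
      long ci = cand[(int)std::floor(unif_rand() * nCand)];
      int i = ci % F.nx, j = (ci / F.nx) % F.ny;
      int k = ci / ((long)F.nx * F.ny);
      double vx = i + unif_rand() - 0.5, vy = j + unif_rand() - 0.5,
             vz = k + unif_rand() - 0.5;
      if (vx < 0) vx = 0; if (vx > F.nx - 1) vx = F.nx - 1;
      if (vy < 0) vy = 0; if (vy > F.ny - 1) vy = F.ny - 1;
      if (vz < 0) vz = 0; if (vz > F.nz - 1) vz = F.nz - 1;
      bool ok;
      double fval = F.trilinear(vx, vy, vz, &ok);
      if (!ok) continue;
      double x[3], y0[3], y[3], d[3], v[3];
      F.voxel_to_world(vx, vy, vz, x);
      apply_affine4(A, x, y0);
      if (model == 0) {
        // S(y0) with current params
        double q[3] = { y0[0]-cc[0], y0[1]-cc[1], y0[2]-cc[2] };
        for (int r = 0; r < 3; ++r)
          y[r] = y0[r]
               + (par[3*r]*q[0] + par[3*r+1]*q[1] + par[3*r+2]*q[2]) / rho
               + par[9+r];
      } else {
        bs.active = true; bs.nx = gnx; bs.ny = gny; bs.nz = gnz;
        for (int a = 0; a < 3; ++a) { bs.org[a] = gorg[a]; bs.spc[a] = gspc[a]; }
        bs.coef = par.data();
        bs.disp(y0, d);
        y[0] = y0[0]+d[0]; y[1] = y0[1]+d[1]; y[2] = y0[2]+d[2];
      }
      M.world_to_voxel(y, v);
      double mval = M.trilinear(v[0], v[1], v[2], &ok);
      if (!ok) continue;
      // world-space moving gradient by central differences
      double gw[3];
      bool gok = true;
      for (int a = 0; a < 3; ++a) {
        double yp[3] = { y[0], y[1], y[2] }, ym[3] = { y[0], y[1], y[2] };
        yp[a] += hM; ym[a] -= hM;
        double vp[3], vm[3];
        M.world_to_voxel(yp, vp); M.world_to_voxel(ym, vm);
        bool o1, o2;
        double a1 = M.trilinear(vp[0], vp[1], vp[2], &o1);
        double a2 = M.trilinear(vm[0], vm[1], vm[2], &o2);
        if (!o1 || !o2) { gok = false; break; }
        gw[a] = (a1 - a2) / (2 * hM);
      }
      if (!gok) continue;
      int fbin = (int)std::floor((fval - fmin) / (fmax - fmin) * bins);
      if (fbin < 0) fbin = 0; if (fbin >= bins) fbin = bins - 1;
      double mt = 2.0 + (mval - mmin) * mscale;
      int m0 = (int)std::floor(mt);
      for (int t = -1; t <= 2; ++t) {
        int mb = m0 + t;
        if (mb < 0 || mb >= bins) continue;
        w.joint[fbin * bins + mb] += parzen(mt - mb);
      }
      fb[nvalid] = fbin;
      mtil[nvalid] = mt;
      for (int a = 0; a < 3; ++a) {
        gM[nvalid*3 + a] = gw[a];
        y0s[nvalid*3 + a] = y0[a];
      }
      ++nvalid;
    }
    validFrac = (double)nvalid / nSamples;
    if (nvalid < 100) {
      return List::create(_["params"] = NumericVector(best.begin(), best.end()),
                          _["mi_trace"] = trace, _["valid_frac"] = validFrac,
                          _["insufficient_overlap"] = true);
    }
    double mi = mi_from_hist(w, nvalid);
    trace[it] = mi;
    if (mi > bestMI) { bestMI = mi; best = par; }

    // gradient of MI wrt params
    std::fill(grad.begin(), grad.end(), 0.0);
    for (int s = 0; s < nvalid; ++s) {
      double mt = mtil[s];
      int m0 = (int)std::floor(mt), fbin = fb[s];
      double alpha = 0;
      for (int t = -1; t <= 2; ++t) {
        int mb = m0 + t;
        if (mb < 0 || mb >= bins) continue;
        double p = w.joint[fbin * bins + mb];
        if (p <= 0) continue;
        alpha += parzen_d(mt - mb) * w.lterm[fbin * bins + mb];
      }
      alpha *= mscale / nvalid;
      if (alpha == 0) continue;
      const double *g = &gM[s*3];
      if (model == 0) {
        const double *y0 = &y0s[s*3];
        double q[3] = { y0[0]-cc[0], y0[1]-cc[1], y0[2]-cc[2] };
        for (int r = 0; r < 3; ++r) {
          for (int c = 0; c < 3; ++c) grad[3*r+c] += alpha * g[r] * q[c] / rho;
          grad[9+r] += alpha * g[r];
        }
      } else {
        double wx[4], wy[4], wz[4];
        int ix, iy, iz;
        const double *y0 = &y0s[s*3];
        bs.weights((y0[0]-gorg[0])/gspc[0], &ix, wx);
        bs.weights((y0[1]-gorg[1])/gspc[1], &iy, wy);
        bs.weights((y0[2]-gorg[2])/gspc[2], &iz, wz);
        for (int c3 = 0; c3 < 4; ++c3) {
          int kk = iz + c3; if (kk < 0 || kk >= gnz) continue;
          for (int b3i = 0; b3i < 4; ++b3i) {
            int jj = iy + b3i; if (jj < 0 || jj >= gny) continue;
            double wyz = wy[b3i]*wz[c3];
            for (int a3 = 0; a3 < 4; ++a3) {
              int ii = ix + a3; if (ii < 0 || ii >= gnx) continue;
              double wgt = wx[a3]*wyz;
              long ci0 = (long)ii + (long)gnx*((long)jj + (long)gny*kk);
              long nctl = (long)gnx*gny*gnz;
              for (int a = 0; a < 3; ++a)
                grad[ci0 + nctl*a] += alpha * g[a] * wgt;
            }
          }
        }
      }
    }
    double gn = 0;
    for (double v : grad) gn += v * v;
    gn = std::sqrt(gn);
    if (gn < 1e-14) continue;
    double gain = step0 * std::pow(gainA / (gainA + it), gainAlpha);
    for (int p = 0; p < nPar; ++p) par[p] += gain * grad[p] / gn;
  }

  return List::create(_["params"] = NumericVector(best.begin(), best.end()),
                      _["mi_trace"] = trace, _["valid_frac"] = validFrac,
                      _["insufficient_overlap"] = false);
}
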