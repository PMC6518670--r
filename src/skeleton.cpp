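#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D homotopic (curve) thinning: iterative removal of simple points with
// six directional sub-iterations; endpoints of curves are preserved so the
// result is a one-voxel-wide centerline skeleton. Foreground is
// 26-connected, background 6-connected.

static inline int off(int di, int dj, int dk) {
  return (di + 1) + 3 * (dj + 1) + 9 * (dk + 1);
}

// number of 26-connected components of the foreground in the 26-neighbourhood
static int count_cstar(const int nb[27]) {
  bool seen[27] = {false};
  int comps = 0;
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || seen[s]) continue;
    ++comps;
    std::vector<int> stack(1, s);
    seen[s] = true;
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int ci = cur % 3 - 1, cj = (cur / 3) % 3 - 1, ck = cur / 9 - 1;
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            int ii = ci + di, jj = cj + dj, kk = ck + dk;
            if (ii < -1 || ii > 1 || jj < -1 || jj > 1 || kk < -1 || kk > 1)
              continue;
            int q = off(ii, jj, kk);
            if (q == 13 || seen[q] || !nb[q]) continue;
            seen[q] = true;
            stack.push_back(q);
          }
    }
  }
  return comps;
}

// number of 6-components of the background restricted to the 18-neighbourhood
// that are 6-adjacent to the centre voxel
static int count_cbar(const int nb[27]) {
  bool seen[27] = {false};
  int comps = 0;
  static const int face[6] = { off(-1,0,0), off(1,0,0), off(0,-1,0),
                               off(0,1,0), off(0,0,-1), off(0,0,1) };
  for (int f = 0; f < 6; ++f) {
    int s = face[f];
    if (nb[s] || seen[s]) continue;
    ++comps;
    std::vector<int> stack(1, s);
    seen[s] = true;
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int ci = cur % 3 - 1, cj = (cur / 3) % 3 - 1, ck = cur / 9 - 1;
      static const int step[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
      for (int t = 0; t < 6; ++t) {
        int ii = ci + step[t][0], jj = cj + step[t][1], kk = ck + step[t][2];
        if (ii < -1 || ii > 1 || jj < -1 || jj > 1 || kk < -1 || kk > 1) continue;
        int ad = std::abs(ii) + std::abs(jj) + std::abs(kk);
        if (ad == 0 || ad == 3) continue;  // stay in N18, skip centre
        int q = off(ii, jj, kk);
        if (seen[q] || nb[q]) continue;
        seen[q] = true;
        stack.push_back(q);
      }
    }
  }
  return comps;
}

struct Vol {
  int nx, ny, nz;
  std::vector<int> d;
  inline int get(int i, int j, int k) const {
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return 0;
    return d[(long)i + (long)nx * ((long)j + (long)ny * k)];
  }
  inline void neighbourhood(int i, int j, int k, int nb[27]) const {
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di)
          nb[off(di, dj, dk)] = get(i + di, j + dj, k + dk);
  }
};

static inline int n26_count(const int nb[27]) {
  int c = 0;
  for (int s = 0; s < 27; ++s) if (s != 13 && nb[s]) ++c;
  return c;
}

// [[Rcpp::export]]
IntegerVector cpp_thin3d(IntegerVector mask, IntegerVector dim) {
  Vol v;
  v.nx = dim[0]; v.ny = dim[1]; v.nz = dim[2];
  v.d.assign(mask.begin(), mask.end());
  for (int &x : v.d) x = (x != 0);

  static const int dirs[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  int nb[27];
  bool changed = true;
  std::vector<long> cands;
  while (changed) {
    changed = false;
    for (int d6 = 0; d6 < 6; ++d6) {
      cands.clear();
      // deletable: border point in direction d with foreground support on
      // the opposite side (stops one-voxel-thick structures from being
      // unzipped end-to-end within a single sub-iteration), simple, and
      // not a curve endpoint
      for (int k = 0; k < v.nz; ++k)
        for (int j = 0; j < v.ny; ++j)
          for (int i = 0; i < v.nx; ++i) {
            if (!v.get(i, j, k)) continue;
            if (v.get(i + dirs[d6][0], j + dirs[d6][1], k + dirs[d6][2]))
              continue;  // not a border point in this direction
            if (!v.get(i - dirs[d6][0], j - dirs[d6][1], k - dirs[d6][2]))
              continue;  // no opposite support
            v.neighbourhood(i, j, k, nb);
            if (n26_count(nb) <= 1) continue;  // curve endpoint preserved
            if (count_cstar(nb) != 1 || count_cbar(nb) != 1) continue;
            cands.push_back((long)i + (long)v.nx * ((long)j + (long)v.ny * k));
          }
      // sequential re-check keeps the deletion homotopic
      for (long c : cands) {
        int i = c % v.nx, j = (c / v.nx) % v.ny, k = c / ((long)v.nx * v.ny);
        if (!v.get(i - dirs[d6][0], j - dirs[d6][1], k - dirs[d6][2]))
          continue;
        v.neighbourhood(i, j, k, nb);
        if (n26_count(nb) <= 1) continue;
        if (count_cstar(nb) != 1 || count_cbar(nb) != 1) continue;
        v.d[c] = 0;
        changed = true;
      }
    }
  }
  return IntegerVector(v.d.begin(), v.d.end());
}
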