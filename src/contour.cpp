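#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact minimum-cost closed contour over an (angle x radius) cost matrix.
// Transitions between adjacent angles are limited to |delta radius index| <=
// maxJump and penalised by lambda * |delta|; the contour must close
// (first/last column constraint). Solved exactly by fixing the start radius
// and running the DP once per candidate start.
// Returns 0-based radius indices, one per angle.
// [[Rcpp::export]]
IntegerVector cpp_contour_dp(NumericMatrix cost, double lambda, int maxJump) {
  int nA = cost.nrow(), nR = cost.ncol();
  const double INF = 1e300;
  std::vector<double> dp(nA * nR), dpPrev(nR);
  std::vector<int> parent(nA * nR);
  double bestTotal = INF;
  std::vector<int> bestPath(nA), path(nA);

  for (int s = 0; s < nR; ++s) {
    // dp over angles with r_0 = s fixed
    std::vector<double> cur(nR, INF), nxt(nR);
    std::vector<int> par(nA * nR, -1);
    cur[s] = cost(0, s);
    for (int a = 1; a < nA; ++a) {
      for (int r = 0; r < nR; ++r) {
        double best = INF;
        int barg = -1;
        int lo = std::max(0, r - maxJump), hi = std::min(nR - 1, r + maxJump);
        for (int q = lo; q <= hi; ++q) {
          if (cur[q] >= INF) continue;
          double c = cur[q] + lambda * std::abs(r - q);
          if (c < best) { best = c; barg = q; }
        }
        nxt[r] = (barg < 0) ? INF : best + cost(a, r);
        par[a * nR + r] = barg;
      }
      cur.swap(nxt);
    }
    // closure back to start radius
    for (int r = 0; r < nR; ++r) {
      if (cur[r] >= INF) continue;
      if (std::abs(r - s) > maxJump) continue;
      double total = cur[r] + lambda * std::abs(r - s);
      if (total < bestTotal) {
        bestTotal = total;
        path[nA - 1] = r;
        for (int a = nA - 1; a > 0; --a) path[a - 1] = par[a * nR + path[a]];
        bestPath = path;
      }
    }
  }
  if (bestTotal >= INF) stop("contour DP found no feasible closed path");
  return IntegerVector(bestPath.begin(), bestPath.end());
}
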