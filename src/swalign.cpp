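#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap (Gotoh) local alignment between two sequences, iterated with
// greedy masking to extract non-overlapping high-scoring hits. Gap costs are
// positive: the first gapped base costs gapOpen + gapExt, each further base
// gapExt (the blastn convention for -gapopen/-gapextend).
//
// Hits are returned in descending score order; after each traceback the
// aligned positions in both sequences are masked so subsequent hits cannot
// reuse them. maxRun is the longest run of consecutive identical aligned
// bases, used by the caller to enforce an exact seed-word requirement.

// [[Rcpp::export(name = ".sw_local_hits")]]
DataFrame sw_local_hits(std::string a, std::string b,
                        double reward, double penalty,
                        double gapOpen, double gapExt,
                        double minScore, int maxHits = 100) {
  const int n = (int) a.size();
  const int m = (int) b.size();
  const double NEG = -1e18;
  std::vector<char> maskA(n, 0), maskB(m, 0);

  std::vector<int> sA, eA, sB, eB, alen, mrun;
  std::vector<double> sc;

  std::vector<double> H((size_t)(n + 1) * (m + 1));
  std::vector<double> E((size_t)(n + 1) * (m + 1));
  std::vector<double> F((size_t)(n + 1) * (m + 1));
  const size_t W = (size_t) m + 1;

  for (int hit = 0; hit < maxHits; ++hit) {
    // forward pass
    for (int j = 0; j <= m; ++j) { H[j] = 0; E[j] = NEG; F[j] = NEG; }
    double best = 0; int bi = 0, bj = 0;
    for (int i = 1; i <= n; ++i) {
      size_t r = (size_t) i * W, p = (size_t)(i - 1) * W;
      H[r] = 0; E[r] = NEG; F[r] = NEG;
      for (int j = 1; j <= m; ++j) {
        double sub;
        if (maskA[i - 1] || maskB[j - 1]) sub = NEG;
        else sub = (a[i - 1] == b[j - 1]) ? reward : penalty;
        double e = std::max(H[r + j - 1] - (gapOpen + gapExt),
                            E[r + j - 1] - gapExt);
        double f = std::max(H[p + j] - (gapOpen + gapExt),
                            F[p + j] - gapExt);
        double h = H[p + j - 1] + sub;
        if (e > h) h = e;
        if (f > h) h = f;
        if (h < 0) h = 0;
        E[r + j] = e; F[r + j] = f; H[r + j] = h;
        if (h > best) { best = h; bi = i; bj = j; }
      }
    }
    if (best <= minScore) break;

    // traceback from (bi, bj), state 0 = H, 1 = E (gap in A), 2 = F (gap in B)
    int i = bi, j = bj, state = 0;
    int endAi = bi, endBj = bj;
    int len = 0, run = 0, maxRun = 0;
    std::vector<std::pair<int, int> > cells;
    while (true) {
      size_t r = (size_t) i * W, p = (size_t)(i - 1) * W;
      if (state == 0) {
        double h = H[r + j];
        if (h <= 0) break;
        if (h == E[r + j]) { state = 1; continue; }
        if (h == F[r + j]) { state = 2; continue; }
        // diagonal
        cells.push_back(std::make_pair(i, j));
        ++len;
        if (a[i - 1] == b[j - 1]) { ++run; if (run > maxRun) maxRun = run; }
        else run = 0;
        --i; --j;
        if (i == 0 || j == 0) break;
      } else if (state == 1) {
        ++len; run = 0;
        cells.push_back(std::make_pair(-1, j));
        double e = E[r + j];
        bool cont = (e == E[r + j - 1] - gapExt);
        --j;
        if (!cont) state = 0;
        if (j == 0) break;
      } else {
        ++len; run = 0;
        cells.push_back(std::make_pair(i, -1));
        double f = F[r + j];
        bool cont = (f == F[p + j] - gapExt);
        --i;
        if (!cont) state = 0;
        if (i == 0) break;
      }
    }
    int startAi = n + 1, startBj = m + 1;
    for (size_t k = 0; k < cells.size(); ++k) {
      int ci = cells[k].first, cj = cells[k].second;
      if (ci > 0) { maskA[ci - 1] = 1; if (ci < startAi) startAi = ci; }
      if (cj > 0) { maskB[cj - 1] = 1; if (cj < startBj) startBj = cj; }
    }
    if (startAi > n) startAi = endAi;   // degenerate safety
    if (startBj > m) startBj = endBj;

    sA.push_back(startAi); eA.push_back(endAi);
    sB.push_back(startBj); eB.push_back(endBj);
    sc.push_back(best); alen.push_back(len); mrun.push_back(maxRun);
  }

  return DataFrame::create(_["startA"] = sA, _["endA"] = eA,
                           _["startB"] = sB, _["endB"] = eB,
                           _["score"] = sc, _["length"] = alen,
                           _["maxRun"] = mrun);
}
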