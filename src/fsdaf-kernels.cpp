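#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Fraction of same-class pixels in a (2*radius+1)^2 window (window clipped
// at image edges). Used as the homogeneity term of the residual-guidance
// score.
// [[Rcpp::export(name = ".cpp_homogeneity")]]
NumericMatrix cpp_homogeneity(IntegerMatrix labels, int radius) {
  int nr = labels.nrow(), nc = labels.ncol();
  NumericMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i) {
    int i0 = std::max(0, i - radius), i1 = std::min(nr - 1, i + radius);
    for (int j = 0; j < nc; ++j) {
      int j0 = std::max(0, j - radius), j1 = std::min(nc - 1, j + radius);
      int same = 0, tot = 0, lab = labels(i, j);
      for (int a = i0; a <= i1; ++a)
        for (int b = j0; b <= j1; ++b) {
          ++tot;
          if (labels(a, b) == lab) ++same;
        }
      out(i, j) = (double)same / (double)tot;
    }
  }
  return out;
}

struct Cand {
  double sdist;  // spectral distance |f1[j] - f1[i]|
  double gdist;  // geometric distance in pixels
  int idx;       // row-major order for deterministic tie-break
  double change; // preliminary change at the candidate
};

static bool cand_less(const Cand &a, const Cand &b) {
  if (a.sdist != b.sdist) return a.sdist < b.sdist;
  if (a.gdist != b.gdist) return a.gdist < b.gdist;
  return a.idx < b.idx;
}

// Neighborhood refinement: for every pixel select up to n_similar
// spectrally similar pixels (smallest |fine_t1 difference|, ties broken by
// spatial proximity then row-major order) inside a square window of
// half-width `radius`, and average their preliminary changes with
// inverse-distance weights w = 1 / (1 + d). Returns the refined change.
// [[Rcpp::export(name = ".cpp_refine")]]
NumericMatrix cpp_refine(NumericMatrix prelim_change, NumericMatrix fine_t1,
                         int n_similar, int radius) {
  int nr = prelim_change.nrow(), nc = prelim_change.ncol();
  NumericMatrix out(nr, nc);
  std::vector<Cand> cands;
  cands.reserve((2 * radius + 1) * (2 * radius + 1));
  for (int i = 0; i < nr; ++i) {
    int i0 = std::max(0, i - radius), i1 = std::min(nr - 1, i + radius);
    for (int j = 0; j < nc; ++j) {
      int j0 = std::max(0, j - radius), j1 = std::min(nc - 1, j + radius);
      double center = fine_t1(i, j);
      if (!R_finite(center)) { out(i, j) = prelim_change(i, j); continue; }
      cands.clear();
      for (int a = i0; a <= i1; ++a)
        for (int b = j0; b <= j1; ++b) {
          double f = fine_t1(a, b), ch = prelim_change(a, b);
          if (!R_finite(f) || !R_finite(ch)) continue;
          Cand c;
          c.sdist = std::fabs(f - center);
          double di = a - i, dj = b - j;
          c.gdist = std::sqrt(di * di + dj * dj);
          c.idx = a * nc + b;
          c.change = ch;
          cands.push_back(c);
        }
      if (cands.empty()) { out(i, j) = prelim_change(i, j); continue; }
      int k = std::min((int)cands.size(), n_similar);
      std::partial_sort(cands.begin(), cands.begin() + k, cands.end(), cand_less);
      double wsum = 0.0, acc = 0.0;
      for (int s = 0; s < k; ++s) {
        double w = 1.0 / (1.0 + cands[s].gdist);
        wsum += w;
        acc += w * cands[s].change;
      }
      out(i, j) = acc / wsum;
    }
  }
  return out;
}
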