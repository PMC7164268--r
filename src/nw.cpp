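#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with linear gap cost.
// Tie-breaking at both fill and traceback is fixed to diagonal > up > left
// ("up" consumes a residue of `a`), so the alignment is fully deterministic.
// Returns 0-based residue indices per aligned column, -1 marking a gap.
// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch, double gap) {
  const int la = a.size(), lb = b.size();
  std::vector<double> S((la + 1) * (lb + 1));
  std::vector<unsigned char> M((la + 1) * (lb + 1)); // 0 diag, 1 up, 2 left
  const int W = lb + 1;
  S[0] = 0.0;
  for (int i = 1; i <= la; ++i) { S[i * W] = i * gap; M[i * W] = 1; }
  for (int j = 1; j <= lb; ++j) { S[j] = j * gap; M[j] = 2; }
  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      double d = S[(i - 1) * W + (j - 1)] +
                 (a[i - 1] == b[j - 1] ? match : mismatch);
      double u = S[(i - 1) * W + j] + gap;
      double l = S[i * W + (j - 1)] + gap;
      double best; unsigned char mv;
      if (d >= u && d >= l)      { best = d; mv = 0; }
      else if (u >= l)           { best = u; mv = 1; }
      else                       { best = l; mv = 2; }
      S[i * W + j] = best;
      M[i * W + j] = mv;
    }
  }
  std::vector<int> ai, bi;
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    unsigned char mv = M[i * W + j];
    if (i > 0 && j > 0 && mv == 0)      { ai.push_back(i - 1); bi.push_back(j - 1); --i; --j; }
    else if (i > 0 && (mv == 1 || j == 0)) { ai.push_back(i - 1); bi.push_back(-1); --i; }
    else                                 { ai.push_back(-1); bi.push_back(j - 1); --j; }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["score"] = S[la * W + lb],
                      _["ai"] = IntegerVector(ai.begin(), ai.end()),
                      _["bi"] = IntegerVector(bi.begin(), bi.end()));
}
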