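#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Weighted Nussinov base-pair maximization with a minimum hairpin loop.
// Pair weights: G:C = 3, A:U(T) = 2, G:U(T) = 1, else unpairable.
// min_loop unpaired bases required between any pair (i, j): j - i > min_loop.

static inline int pair_w(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
  if ((a == 'A' && (b == 'T' || b == 'U')) || ((a == 'T' || a == 'U') && b == 'A')) return 2;
  if ((a == 'G' && (b == 'T' || b == 'U')) || ((a == 'T' || a == 'U') && b == 'G')) return 1;
  return 0;
}

// [[Rcpp::export(name = ".nussinov_cpp")]]
List nussinov_cpp(std::string seq, int min_loop) {
  const int n = seq.size();
  std::vector<std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = M[i + 1][j];                       // i unpaired
      if (M[i][j - 1] > best) best = M[i][j - 1];   // j unpaired
      int w = pair_w(seq[i], seq[j]);
      if (w > 0) {
        int v = w + (i + 1 <= j - 1 ? M[i + 1][j - 1] : 0);
        if (v > best) best = v;
      }
      for (int k = i + 1; k < j; ++k) {             // bifurcation
        int v = M[i][k] + M[k + 1][j];
        if (v > best) best = v;
      }
      M[i][j] = best;
    }
  }
  // traceback (iterative stack); deterministic case order matches the fill
  IntegerVector pt(n, 0); // 1-based partner, 0 = unpaired
  std::vector<std::pair<int,int> > stack;
  if (n > 1) stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i <= min_loop) continue;
    if (M[i][j] == M[i + 1][j]) { stack.push_back(std::make_pair(i + 1, j)); continue; }
    if (M[i][j] == M[i][j - 1]) { stack.push_back(std::make_pair(i, j - 1)); continue; }
    int w = pair_w(seq[i], seq[j]);
    if (w > 0 && M[i][j] == w + (i + 1 <= j - 1 ? M[i + 1][j - 1] : 0)) {
      pt[i] = j + 1; pt[j] = i + 1;
      stack.push_back(std::make_pair(i + 1, j - 1));
      continue;
    }
    for (int k = i + 1; k < j; ++k) {
      if (M[i][j] == M[i][k] + M[k + 1][j]) {
        stack.push_back(std::make_pair(i, k));
        stack.push_back(std::make_pair(k + 1, j));
        break;
      }
    }
  }
  return List::create(_["score"] = (n > 1 ? M[0][n - 1] : 0),
                      _["pair_table"] = pt);
}
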