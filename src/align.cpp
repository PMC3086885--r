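#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Gotoh affine-gap Smith-Waterman over {A,C,G,T,N}; 'N' and the mask
// sentinel 'X' never match anything (scored as mismatch).
// Gap of length L costs gap_open + gap_extend * L.

static inline int sub_score(char a, char b, int match, int mismatch) {
  if (a == b && a != 'N' && a != 'X') return match;
  return mismatch;
}

struct Hsp {
  int qs, qe, ss, se;   // 0-based half-open
  int score;
  int matches, length;
};

// One optimal local alignment on (possibly masked) subject.
// Returns score 0 if nothing aligns.
static Hsp sw_one(const std::string &q, const std::string &s,
                  int match, int mismatch, int gap_open, int gap_extend) {
  const int n = q.size(), m = s.size();
  const int NEG = -1000000000;
  // full matrices with traceback; desk-scale sequences only
  std::vector<int> H((n + 1) * (m + 1), 0), E((n + 1) * (m + 1), NEG),
      F((n + 1) * (m + 1), NEG);
  std::vector<unsigned char> TB((n + 1) * (m + 1), 0); // 0 stop,1 diag,2 up(E:gap in subject),3 left(F:gap in query)
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int idx = i * (m + 1) + j;
      const int up = idx - (m + 1), left = idx - 1, diag = up - 1;
      int e = std::max(H[up] - gap_open - gap_extend, E[up] - gap_extend);
      int f = std::max(H[left] - gap_open - gap_extend, F[left] - gap_extend);
      int d = H[diag] + sub_score(q[i - 1], s[j - 1], match, mismatch);
      int h = 0; unsigned char tb = 0;
      if (d >= h) { h = d; tb = 1; }
      if (e > h) { h = e; tb = 2; }
      if (f > h) { h = f; tb = 3; }
      if (h <= 0) { h = 0; tb = 0; }
      H[idx] = h; E[idx] = e; F[idx] = f; TB[idx] = tb;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  Hsp out{0, 0, 0, 0, 0, 0, 0};
  if (best <= 0) return out;
  // traceback
  int i = bi, j = bj, matches = 0, len = 0;
  int state = 0; // 0 in H, 1 in E, 2 in F
  while (true) {
    const int idx = i * (m + 1) + j;
    if (state == 0) {
      unsigned char tb = TB[idx];
      if (tb == 0 || H[idx] == 0) break;
      if (tb == 1) {
        if (q[i - 1] == s[j - 1] && q[i - 1] != 'N' && q[i - 1] != 'X') ++matches;
        ++len; --i; --j;
      } else if (tb == 2) state = 1;
      else state = 2;
    } else if (state == 1) { // gap in subject: consume query
      const int up = idx - (m + 1);
      ++len;
      if (E[idx] == E[up] - gap_extend && E[up] > H[up] - gap_open) { --i; }
      else { --i; state = 0; }
    } else { // gap in query: consume subject
      const int left = idx - 1;
      ++len;
      if (F[idx] == F[left] - gap_extend && F[left] > H[left] - gap_open) { --j; }
      else { --j; state = 0; }
    }
  }
  out.qs = i; out.qe = bi; out.ss = j; out.se = bj;
  out.score = best; out.matches = matches; out.length = len;
  return out;
}

// [[Rcpp::export(name = ".sw_hsps_cpp")]]
DataFrame sw_hsps_cpp(std::string query, std::string subject,
                      int match, int mismatch, int gap_open, int gap_extend,
                      int min_score, int max_hsps) {
  std::vector<int> qs, qe, ss, se, score;
  std::vector<double> ident;
  std::string sub = subject;
  for (int k = 0; k < max_hsps; ++k) {
    Hsp h = sw_one(query, sub, match, mismatch, gap_open, gap_extend);
    if (h.score < min_score || h.score <= 0) break;
    qs.push_back(h.qs); qe.push_back(h.qe);
    ss.push_back(h.ss); se.push_back(h.se);
    score.push_back(h.score);
    ident.push_back(h.length > 0 ? (double)h.matches / h.length : 0.0);
    for (int j = h.ss; j < h.se; ++j) sub[j] = 'X'; // mask and re-search
  }
  return DataFrame::create(_["q_start"] = qs, _["q_end"] = qe,
                           _["s_start"] = ss, _["s_end"] = se,
                           _["raw_score"] = score,
                           _["identity_fraction"] = ident);
}

// Plain optimal local score (no HSP extraction); used for quick scans.
// [[Rcpp::export(name = ".sw_score_cpp")]]
int sw_score_cpp(std::string query, std::string subject,
                 int match, int mismatch, int gap_open, int gap_extend) {
  Hsp h = sw_one(query, subject, match, mismatch, gap_open, gap_extend);
  return h.score;
}
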