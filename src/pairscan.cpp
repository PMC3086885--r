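#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>
using namespace Rcpp;

// Plant small-RNA target-site scoring (TargetFinder/Allen-style penalties).
// The sRNA pairs antiparallel to the cDNA: sRNA position 1 (5' end) pairs the
// 3'-most base of the site. Penalties: mismatch 1, G:U 0.5, bulge 2 (either
// strand, at most one per strand), all doubled at sRNA positions core_start..
// core_end from the 5' end. Score is the minimized total penalty.

// pair type: 0 = WC, 1 = GU, 2 = mismatch (DNA letters; T plays U)
static inline int pair_type(char a, char b) {
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A') ||
      (a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 0;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return 1;
  return 2;
}

struct ScanHit {
  double score;
  int k_used;        // target bases consumed
  int cleave_off;    // offset k of the base paired to sRNA pos 10, -1 if bulged
  std::string path;  // ops 5'->3' on sRNA: W,G,X (pairs), S (sRNA bulge), T (target bulge)
};

// DP anchored at cdna position p (paired with sRNA pos 1), extending to
// lower cdna coordinates. Bulges forbidden at either terminus.
static bool scan_anchor(const std::string &srna, const std::string &cdna, int p,
                        double mismatch_pen, double gu_pen, double bulge_pen,
                        int core_start, int core_end, ScanHit &out) {
  const int m = srna.size();
  if (p < m - 2) return false;
  const double INF = 1e18;
  // state [i][k][bs][bt]: i sRNA consumed, k target consumed
  const int KMAX = m + 1;
  std::vector<double> D((m + 1) * (KMAX + 1) * 4, INF);
  std::vector<int> P((m + 1) * (KMAX + 1) * 4, -1); // packed parent op: 0..4, -1 none
  auto idx = [&](int i, int k, int bs, int bt) {
    return ((i * (KMAX + 1) + k) * 2 + bs) * 2 + bt;
  };
  D[idx(0, 0, 0, 0)] = 0.0;
  for (int i = 0; i <= m; ++i) {
    for (int k = 0; k <= KMAX; ++k) {
      for (int bs = 0; bs < 2; ++bs) for (int bt = 0; bt < 2; ++bt) {
        double cur = D[idx(i, k, bs, bt)];
        if (cur >= INF) continue;
        double mult = (i + 1 >= core_start && i + 1 <= core_end) ? 2.0 : 1.0;
        // pair sRNA pos i+1 with cdna[p - k]
        if (i < m && k < KMAX && p - k >= 0) {
          int t = pair_type(srna[i], cdna[p - k]);
          double pen = (t == 0) ? 0.0 : (t == 1 ? gu_pen * mult : mismatch_pen * mult);
          double v = cur + pen;
          int to = idx(i + 1, k + 1, bs, bt);
          if (v < D[to]) { D[to] = v; P[to] = t; } // op 0/1/2
        }
        // sRNA bulge (skip sRNA base), only interior
        if (i > 0 && i < m - 1 && bs == 0) {
          double v = cur + bulge_pen * mult;
          int to = idx(i + 1, k, 1, bt);
          if (v < D[to]) { D[to] = v; P[to] = 3; }
        }
        // target bulge (extra target base), only interior
        if (i > 0 && i < m && k < KMAX && p - k >= 0 && bt == 0) {
          double v = cur + bulge_pen * mult;
          int to = idx(i, k + 1, bs, 1);
          if (v < D[to]) { D[to] = v; P[to] = 4; }
        }
      }
    }
  }
  double best = INF; int bk = -1, bbs = 0, bbt = 0;
  for (int k = m - 1; k <= KMAX; ++k) {
    if (k > p + 1) continue;
    for (int bs = 0; bs < 2; ++bs) for (int bt = 0; bt < 2; ++bt) {
      double v = D[idx(m, k, bs, bt)];
      if (v < best) { best = v; bk = k; bbs = bs; bbt = bt; }
    }
  }
  if (bk < 0 || best >= INF) return false;
  // traceback
  std::string path;
  int i = m, k = bk, bs = bbs, bt = bbt, cleave = -1;
  while (i > 0 || k > 0) {
    int op = P[idx(i, k, bs, bt)];
    if (op < 0) break;
    if (op <= 2) {
      path.push_back(op == 0 ? 'W' : (op == 1 ? 'G' : 'X'));
      if (i == 10) cleave = k - 1; // sRNA pos 10 paired cdna[p-(k-1)]
      --i; --k;
    } else if (op == 3) { path.push_back('S'); --i; bs = 0; }
    else { path.push_back('T'); --k; bt = 0; }
  }
  std::reverse(path.begin(), path.end());
  out.score = best;
  out.k_used = bk;
  out.cleave_off = cleave;
  out.path = path;
  return true;
}

// [[Rcpp::export(name = ".scan_sites_cpp")]]
DataFrame scan_sites_cpp(std::string srna, std::string cdna,
                         double mismatch_pen, double gu_pen, double bulge_pen,
                         int core_start, int core_end, double score_keep_max) {
  const int m = srna.size(), L = cdna.size();
  std::vector<int> start, end, cleav;
  std::vector<double> sc;
  std::vector<std::string> paths;
  for (int p = m - 2; p < L; ++p) {
    ScanHit h;
    if (!scan_anchor(srna, cdna, p, mismatch_pen, gu_pen, bulge_pen,
                     core_start, core_end, h)) continue;
    if (h.score > score_keep_max) continue;
    start.push_back(p - h.k_used + 1);
    end.push_back(p + 1);
    sc.push_back(h.score);
    cleav.push_back(h.cleave_off >= 0 ? p - h.cleave_off : -1);
    paths.push_back(h.path);
  }
  return DataFrame::create(_["site_start"] = start, _["site_end"] = end,
                           _["score"] = sc, _["cleavage_pos"] = cleav,
                           _["path"] = paths,
                           _["stringsAsFactors"] = false);
}
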