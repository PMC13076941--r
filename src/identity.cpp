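#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment identity: match +1, mismatch 0,
// linear gap -1. Ties broken toward fewer gaps (secondary DP objective),
// then toward the diagonal move on traceback, so the result is deterministic
// and symmetric. Identity = exact matches / alignment length.

namespace {

struct Cell {
  int score;
  int gaps; // minimal gap count among max-score alignments ending here
};

inline bool better(int s1, int g1, int s2, int g2) {
  // is (s1, g1) strictly better than (s2, g2)?
  return s1 > s2 || (s1 == s2 && g1 < g2);
}

double nw_identity(const std::string& a, const std::string& b) {
  const int n = a.size(), m = b.size();
  // DP over two rows; traceback needs full move matrix (bytes).
  std::vector<Cell> prev(m + 1), cur(m + 1);
  std::vector<unsigned char> move((n + 1) * (m + 1)); // 0=diag,1=up,2=left
  prev[0] = {0, 0};
  for (int j = 1; j <= m; ++j) {
    prev[j] = {-j, j};
    move[j] = 2;
  }
  for (int i = 1; i <= n; ++i) {
    cur[0] = {-i, i};
    move[i * (m + 1)] = 1;
    for (int j = 1; j <= m; ++j) {
      int ds = prev[j - 1].score + (a[i - 1] == b[j - 1] ? 1 : 0);
      int dg = prev[j - 1].gaps;
      int us = prev[j].score - 1, ug = prev[j].gaps + 1;
      int ls = cur[j - 1].score - 1, lg = cur[j - 1].gaps + 1;
      int bs = ds, bg = dg;
      unsigned char bm = 0;
      if (better(us, ug, bs, bg)) { bs = us; bg = ug; bm = 1; }
      if (better(ls, lg, bs, bg)) { bs = ls; bg = lg; bm = 2; }
      cur[j] = {bs, bg};
      move[i * (m + 1) + j] = bm;
    }
    std::swap(prev, cur);
  }
  // traceback counting matches and alignment length
  int i = n, j = m, matches = 0, len = 0;
  while (i > 0 || j > 0) {
    unsigned char mv = move[i * (m + 1) + j];
    if (i > 0 && j > 0 && mv == 0) {
      if (a[i - 1] == b[j - 1]) ++matches;
      --i; --j;
    } else if (i > 0 && mv == 1) {
      --i;
    } else {
      --j;
    }
    ++len;
  }
  return static_cast<double>(matches) / static_cast<double>(len);
}

} // namespace

// [[Rcpp::export(name = ".nw_identity_cpp")]]
double nw_identity_cpp(std::string a, std::string b) {
  if (a.empty() || b.empty())
    stop("sequences must be non-empty");
  return nw_identity(a, b);
}

// Identity of one query against many references; used by the greedy
// clustering inner loop. Stops early and returns the index (1-based) of the
// first reference with identity >= threshold, or 0 if none. A length-ratio
// bound (identity <= min_len / max_len) prunes hopeless comparisons.
// [[Rcpp::export(name = ".nw_first_hit_cpp")]]
int nw_first_hit_cpp(std::string query, CharacterVector refs, double threshold) {
  const int nq = query.size();
  if (nq == 0) stop("sequences must be non-empty");
  for (int k = 0; k < refs.size(); ++k) {
    std::string r = as<std::string>(refs[k]);
    int nr = r.size();
    int lo = std::min(nq, nr), hi = std::max(nq, nr);
    if (static_cast<double>(lo) / hi < threshold) continue;
    if (nw_identity(query, r) >= threshold) return k + 1;
  }
  return 0;
}

// Maximum identity over the full cross product of two sequence sets.
// [[Rcpp::export(name = ".nw_max_cross_cpp")]]
double nw_max_cross_cpp(CharacterVector xs, CharacterVector ys) {
  double best = 0.0;
  for (int i = 0; i < xs.size(); ++i) {
    std::string a = as<std::string>(xs[i]);
    for (int j = 0; j < ys.size(); ++j) {
      std::string b = as<std::string>(ys[j]);
      double id = nw_identity(a, b);
      if (id > best) best = id;
    }
  }
  return best;
}
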