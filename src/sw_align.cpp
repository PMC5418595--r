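#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <climits>
using namespace Rcpp;

// Local alignment (Smith-Waterman, Gotoh affine gaps) in two passes:
// a fast score-only forward pass locating the best-scoring end cell, then a
// bounded reverse pass from that cell to recover the start. Linear memory.
//
// Scoring: match/mismatch as given; a gap of length k costs
// gap_open + (k-1)*gap_ext (gap_open = existence + first extension, so
// gap_open = 2, gap_ext = 1 mirrors lastal -a1 with unit extension cost).

static int sw_score_pass(const char *a, int n, const char *b, int m,
                         int match, int mismatch, int gap_open, int gap_ext,
                         int *best_i, int *best_j) {
  std::vector<int> H(m + 1, 0), F(m + 1, 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const char ai = a[i - 1];
    int diag = 0, e = 0, hleft = 0;
    int *Hp = H.data(), *Fp = F.data();
    for (int j = 1; j <= m; ++j) {
      const int hup = Hp[j];
      int f = std::max(hup - gap_open, Fp[j] - gap_ext);
      Fp[j] = f;
      e = std::max(hleft - gap_open, e - gap_ext);
      int h = diag + (ai == b[j - 1] ? match : mismatch);
      if (h < e) h = e;
      if (h < f) h = f;
      if (h < 0) h = 0;
      diag = hup;
      Hp[j] = h;
      hleft = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  *best_i = bi; *best_j = bj;
  return best;
}

// Reverse pass anchored at the forward best end cell: alignments must start
// at (0,0) of the reversed prefixes (free end), so the recovered start is
// guaranteed to belong to an alignment ending at the forward best cell.
// Along the optimal forward path every suffix scores positive, so dropping
// the zero floor loses nothing.
static int sw_anchored_pass(const char *a, int n, const char *b, int m,
                            int match, int mismatch, int gap_open,
                            int gap_ext, int *best_i, int *best_j) {
  const int NEG = INT_MIN / 4;
  std::vector<int> H(m + 1), F(m + 1, NEG);
  H[0] = 0;
  for (int j = 1; j <= m; ++j) H[j] = -(gap_open + (j - 1) * gap_ext);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const char ai = a[i - 1];
    int diag = H[0], e = NEG;
    int hleft = H[0] = -(gap_open + (i - 1) * gap_ext);
    int *Hp = H.data(), *Fp = F.data();
    for (int j = 1; j <= m; ++j) {
      const int hup = Hp[j];
      int f = std::max(hup - gap_open, Fp[j] - gap_ext);
      Fp[j] = f;
      e = std::max(hleft - gap_open, e - gap_ext);
      int h = diag + (ai == b[j - 1] ? match : mismatch);
      if (h < e) h = e;
      if (h < f) h = f;
      diag = hup;
      Hp[j] = h;
      hleft = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  *best_i = bi; *best_j = bj;
  return best;
}

// [[Rcpp::export]]
IntegerVector sw_align_cpp(std::string read, std::string ref,
                           int match, int mismatch,
                           int gap_open, int gap_ext,
                           int min_score = 0) {
  const int n = (int)read.size(), m = (int)ref.size();
  int bi = 0, bj = 0;
  int best = sw_score_pass(read.c_str(), n, ref.c_str(), m,
                           match, mismatch, gap_open, gap_ext, &bi, &bj);
  if (best <= 0 || best < min_score)
    return IntegerVector::create(_["score"] = best, _["read_start"] = 0,
                                 _["read_end"] = 0, _["ref_start"] = 0,
                                 _["ref_end"] = 0);
  // reverse pass over the prefixes ending at (bi, bj); the read span of a
  // score-s alignment cannot exceed twice the ref span, which bounds the
  // window we must revisit
  int rwin = std::min(bi, 2 * bj + 8);
  std::string ra(read.rbegin() + (n - bi), read.rbegin() + (n - bi) + rwin);
  std::string rb(ref.rbegin() + (m - bj), ref.rend());
  int ri = 0, rj = 0;
  int rbest = sw_anchored_pass(ra.c_str(), (int)ra.size(), rb.c_str(),
                               (int)rb.size(), match, mismatch, gap_open,
                               gap_ext, &ri, &rj);
  if (rbest != best) Rcpp::stop("sw_align_cpp: reverse pass mismatch");
  return IntegerVector::create(
      _["score"] = best,
      _["read_start"] = bi - ri, _["read_end"] = bi,
      _["ref_start"] = bj - rj, _["ref_end"] = bj);
}
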