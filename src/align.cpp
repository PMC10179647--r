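#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <climits>
using namespace Rcpp;

// Gotoh affine-gap alignment of a read against a reference with free end
// gaps on the reference side (fitting alignment).  The read is aligned
// globally.  Gap of length L costs gap_open + L * gap_extend.
// Traceback is deterministic: at ties the state priority is
// diagonal > deletion (gap in read) > insertion (gap in reference), and the
// alignment end is the leftmost reference column attaining the maximum.
// Ops: '=' match, 'X' mismatch, 'I' insertion (read base absent from
// reference), 'D' deletion (reference base absent from read).

static const int NEG = INT_MIN / 4;

// [[Rcpp::export(name = ".affine_align_cpp")]]
List affine_align_cpp(std::string read, std::string ref,
                      int match, int mismatch, int gap_open, int gap_extend) {
  int m = read.size(), n = ref.size();
  // state matrices: M diag, X gap-in-ref (consumes read), Y gap-in-read
  std::vector<int> M((m + 1) * (n + 1), NEG), X((m + 1) * (n + 1), NEG),
      Y((m + 1) * (n + 1), NEG);
  auto at = [n](int i, int j) { return i * (n + 1) + j; };
  for (int j = 0; j <= n; ++j) M[at(0, j)] = 0;  // free leading ref gap
  for (int i = 1; i <= m; ++i) X[at(i, 0)] = gap_open + i * gap_extend;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int best_prev = std::max(M[at(i - 1, j - 1)],
                               std::max(X[at(i - 1, j - 1)], Y[at(i - 1, j - 1)]));
      int s = (read[i - 1] == ref[j - 1]) ? match : mismatch;
      M[at(i, j)] = (best_prev == NEG) ? NEG : best_prev + s;
      int xo = std::max(M[at(i - 1, j)], Y[at(i - 1, j)]);
      int xn = (xo == NEG) ? NEG : xo + gap_open + gap_extend;
      int xe = (X[at(i - 1, j)] == NEG) ? NEG : X[at(i - 1, j)] + gap_extend;
      X[at(i, j)] = std::max(xn, xe);
      int yo = std::max(M[at(i, j - 1)], X[at(i, j - 1)]);
      int yn = (yo == NEG) ? NEG : yo + gap_open + gap_extend;
      int ye = (Y[at(i, j - 1)] == NEG) ? NEG : Y[at(i, j - 1)] + gap_extend;
      Y[at(i, j)] = std::max(yn, ye);
    }
  }
  // end: best over reference columns at i = m (free trailing ref gap)
  int best = NEG, bj = 0, bs = 0;  // bs: 0=M 1=Y 2=X
  for (int j = 0; j <= n; ++j) {
    int cand[3] = {M[at(m, j)], Y[at(m, j)], X[at(m, j)]};
    for (int s = 0; s < 3; ++s) {
      if (cand[s] > best) { best = cand[s]; bj = j; bs = s; }
    }
  }
  // traceback
  std::string ops;
  int i = m, j = bj, st = bs;
  while (i > 0 || (st != 0 && j > 0)) {
    if (st == 0) {  // M
      if (i == 0) break;
      char o = (read[i - 1] == ref[j - 1]) ? '=' : 'X';
      int s = (o == '=') ? match : mismatch;
      int prev = M[at(i, j)] - s;
      // priority among predecessors: M > Y > X
      if (M[at(i - 1, j - 1)] == prev) st = 0;
      else if (Y[at(i - 1, j - 1)] == prev) st = 1;
      else st = 2;
      ops.push_back(o);
      --i; --j;
      if (i == 0 && st == 0) break;
    } else if (st == 1) {  // Y: deletion, consumes ref
      ops.push_back('D');
      int cur = Y[at(i, j)];
      if (j > 1 && Y[at(i, j - 1)] != NEG && Y[at(i, j - 1)] + gap_extend == cur)
        st = 1;
      else if (M[at(i, j - 1)] != NEG && M[at(i, j - 1)] + gap_open + gap_extend == cur)
        st = 0;
      else st = 2;
      --j;
      if (i == 0 && st == 0) break;
    } else {  // X: insertion, consumes read
      ops.push_back('I');
      int cur = X[at(i, j)];
      if (i > 1 && X[at(i - 1, j)] != NEG && X[at(i - 1, j)] + gap_extend == cur)
        st = 2;
      else if (M[at(i - 1, j)] != NEG && M[at(i - 1, j)] + gap_extend + gap_open == cur)
        st = 0;
      else st = 1;
      --i;
      if (i == 0 && st == 0) break;
    }
  }
  std::reverse(ops.begin(), ops.end());
  // run-length encode
  std::vector<std::string> op_out;
  std::vector<int> len_out;
  for (size_t k = 0; k < ops.size();) {
    size_t k2 = k;
    while (k2 < ops.size() && ops[k2] == ops[k]) ++k2;
    op_out.push_back(std::string(1, ops[k]));
    len_out.push_back(k2 - k);
    k = k2;
  }
  return List::create(_["score"] = best, _["ref_start"] = j,
                      _["op"] = op_out, _["len"] = len_out);
}

// Minimum Levenshtein distance between `pattern` and any substring of
// `text` (semi-global DP), with the start/end (0-based, half-open) of the
// best-scoring window.  Ties resolve to the smallest end, then the largest
// start (shortest window).
// [[Rcpp::export(name = ".infix_edit_cpp")]]
List infix_edit_cpp(std::string pattern, std::string text) {
  int m = pattern.size(), n = text.size();
  std::vector<int> d(m + 1), dn(m + 1), st(m + 1), stn(m + 1);
  int best = m, bend = 0, bstart = 0;
  for (int i = 0; i <= m; ++i) { d[i] = i; st[i] = 0; }
  if (m <= best) { best = m; bend = 0; bstart = 0; }
  for (int j = 1; j <= n; ++j) {
    dn[0] = 0; stn[0] = j;
    for (int i = 1; i <= m; ++i) {
      int sub = d[i - 1] + (pattern[i - 1] == text[j - 1] ? 0 : 1);
      int del = d[i] + 1;      // skip text char
      int ins = dn[i - 1] + 1; // skip pattern char
      int v = sub, s = st[i - 1];
      if (del < v) { v = del; s = st[i]; }
      else if (del == v && st[i] > s) { s = st[i]; }
      if (ins < v) { v = ins; s = stn[i - 1]; }
      else if (ins == v && stn[i - 1] > s) { s = stn[i - 1]; }
      dn[i] = v; stn[i] = s;
    }
    if (dn[m] < best) { best = dn[m]; bend = j; bstart = stn[m]; }
    std::swap(d, dn); std::swap(st, stn);
  }
  return List::create(_["dist"] = best, _["start"] = bstart, _["end"] = bend);
}

// Best overlap between the tail of s1 and the head of s2 (s2 already
// reverse-complemented by the caller).  Considers overlap lengths
// min_overlap..min(len1, len2); returns the length minimizing the mismatch
// fraction (ties -> longest overlap) and its mismatch count.
// [[Rcpp::export(name = ".best_overlap_cpp")]]
List best_overlap_cpp(std::string s1, std::string s2, int min_overlap) {
  int n1 = s1.size(), n2 = s2.size();
  int maxL = std::min(n1, n2);
  int bestL = -1, bestMm = 0;
  double bestFrac = 2.0;
  for (int L = min_overlap; L <= maxL; ++L) {
    int mm = 0;
    int off = n1 - L;
    for (int k = 0; k < L; ++k)
      if (s1[off + k] != s2[k]) ++mm;
    double frac = (double)mm / L;
    if (frac < bestFrac || (frac == bestFrac && L > bestL)) {
      bestFrac = frac; bestL = L; bestMm = mm;
    }
  }
  return List::create(_["len"] = bestL, _["mismatches"] = bestMm,
                      _["frac"] = (bestL > 0 ? bestFrac : NA_REAL));
}
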