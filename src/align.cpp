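#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstring>
#include <limits>
using namespace Rcpp;

// Global (end-to-end) pairwise alignment with affine gap penalties, Gotoh
// three-state recursion over a diagonal band. A gap of length L costs
// gap_open + L * gap_extend, both supplied as positive numbers. The band is
// widened by the sequence length difference, so for band >= max(n, m) the
// recursion is the exhaustive DP; narrow bands are appropriate for
// full-length amplicon reads, whose optimal path stays near the diagonal.
//
// States: M = read base against ref base; X = gap in reference (insertion in
// the read); Y = gap in the read (deletion of reference bases).
//
// Band-compressed storage: cell (i, j) lives at column k = j - i + bl of row
// i, where bl/bh are the down/up band half-widths. Diagonal moves keep k,
// read-consuming moves map to k+1 in the row above, ref-consuming moves to
// k-1 in the same row.

static const int NEG_INF = std::numeric_limits<int>::min() / 4;

// [[Rcpp::export(name = ".align_global_cpp")]]
List align_global_cpp(std::string read, std::string ref,
                      int match, int mismatch,
                      int gap_open, int gap_extend,
                      int band = -1, bool score_only = false) {
  const int n = (int) read.size();   // rows: read
  const int m = (int) ref.size();    // cols: reference
  if (n == 0 || m == 0)
    stop("align_global_cpp: empty sequence");
  if (band < 0) band = std::max(n, m);  // exhaustive

  const int go = gap_open, ge = gap_extend;
  const int bl = std::min(n, band + std::max(0, n - m));
  const int bh = std::min(m, band + std::max(0, m - n));
  const int W = bl + bh + 1;
  const size_t cells = (size_t)(n + 1) * W;

  std::vector<int> M(cells, NEG_INF), X(cells, NEG_INF), Y(cells, NEG_INF);
  std::vector<unsigned char> tbM, tbX, tbY;
  if (!score_only) {
    tbM.assign(cells, 0); tbX.assign(cells, 0); tbY.assign(cells, 0);
  }
  // k index of cell (i, j): j - i + bl
  M[bl] = 0;                               // (0, 0)
  for (int j = 1; j <= bh && j <= m; ++j) { // leading deletions along row 0
    Y[bl + j] = -(go + ge * j);
    if (!score_only) tbY[bl + j] = 2;
  }
  for (int i = 1; i <= bl && i <= n; ++i) { // leading insertions, column 0
    const size_t c = (size_t)i * W + (0 - i + bl);
    X[c] = -(go + ge * i);
    if (!score_only) tbX[c] = 1;
  }

  for (int i = 1; i <= n; ++i) {
    const char rb = read[i - 1];
    const int jlo = std::max(1, i - bl), jhi = std::min(m, i + bh);
    const size_t row = (size_t)i * W, prow = (size_t)(i - 1) * W;
    for (int j = jlo; j <= jhi; ++j) {
      const int k = j - i + bl;
      const int s = (rb == ref[j - 1]) ? match : mismatch;
      // M: diagonal (i-1, j-1) -> same k in previous row
      const size_t pd = prow + k;
      int bm = M[pd], st = 0;
      if (X[pd] > bm) { bm = X[pd]; st = 1; }
      if (Y[pd] > bm) { bm = Y[pd]; st = 2; }
      M[row + k] = (bm <= NEG_INF) ? NEG_INF : bm + s;
      if (!score_only) tbM[row + k] = (unsigned char) st;
      // X: (i-1, j) -> k+1 in previous row
      int bx = NEG_INF, stx = 0;
      if (k + 1 < W) {
        const size_t pu = prow + k + 1;
        bx = M[pu] - (go + ge); stx = 0;
        if (X[pu] - ge > bx) { bx = X[pu] - ge; stx = 1; }
        if (Y[pu] - (go + ge) > bx) { bx = Y[pu] - (go + ge); stx = 2; }
      }
      X[row + k] = bx;
      if (!score_only) tbX[row + k] = (unsigned char) stx;
      // Y: (i, j-1) -> k-1 in this row
      int by = NEG_INF, sty = 0;
      if (k - 1 >= 0) {
        const size_t pl = row + k - 1;
        by = M[pl] - (go + ge); sty = 0;
        if (X[pl] - (go + ge) > by) { by = X[pl] - (go + ge); sty = 1; }
        if (Y[pl] - ge > by) { by = Y[pl] - ge; sty = 2; }
      }
      Y[row + k] = by;
      if (!score_only) tbY[row + k] = (unsigned char) sty;
    }
  }

  const size_t endc = (size_t)n * W + (m - n + bl);
  int best = M[endc], endState = 0;
  if (X[endc] > best) { best = X[endc]; endState = 1; }
  if (Y[endc] > best) { best = Y[endc]; endState = 2; }

  if (score_only)
    return List::create(_["score"] = best,
                        _["cigar"] = CharacterVector::create(NA_STRING));

  std::string ops;
  ops.reserve((size_t)(n + m));
  int i = n, j = m, st = endState;
  while (i > 0 || j > 0) {
    const size_t c = (size_t)i * W + (j - i + bl);
    if (st == 0) {
      ops.push_back(read[i - 1] == ref[j - 1] ? '=' : 'X');
      st = tbM[c]; --i; --j;
    } else if (st == 1) {
      ops.push_back('I');
      st = tbX[c]; --i;
    } else {
      ops.push_back('D');
      st = tbY[c]; --j;
    }
  }
  std::reverse(ops.begin(), ops.end());

  std::string cigar;
  size_t k2, k = 0;
  while (k < ops.size()) {
    k2 = k;
    while (k2 < ops.size() && ops[k2] == ops[k]) ++k2;
    cigar += std::to_string(k2 - k);
    cigar.push_back(ops[k]);
    k = k2;
  }
  return List::create(_["score"] = best, _["cigar"] = cigar);
}
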