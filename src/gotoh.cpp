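#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Global (Needleman-Wunsch/Gotoh) alignment with affine gaps.
// Gap of length L costs open + (L-1)*extend, i.e. the opening penalty
// includes the first gapped base.
//
// Tie-breaks (deterministic): diagonal (match/mismatch) preferred over
// deletion (gap in read), deletion preferred over insertion (gap in
// reference); within a gap run the traceback prefers to keep extending,
// which pushes equivalent gaps to the leftmost reference position.
//
// Ops emitted per alignment column: '=' match, 'X' mismatch,
// 'D' reference base absent from read, 'I' read base absent from reference.

static inline double subscore(char a, char b, double match, double mismatch) {
  if (a == 'N' || b == 'N') return mismatch; // N matches nothing
  return (a == b) ? match : mismatch;
}

// [[Rcpp::export]]
List gotoh_align(std::string read, std::string ref,
                 double match = 2.0, double mismatch = -3.0,
                 double gap_open = -6.0, double gap_extend = -1.0) {
  const int n = read.size(); // rows: read
  const int m = ref.size();  // cols: reference
  const double NEG = -std::numeric_limits<double>::infinity();

  // M: align read[i-1] to ref[j-1]; D: gap in read (consumes ref);
  // I: gap in ref (consumes read).
  std::vector<double> M((n + 1) * (m + 1), NEG), D((n + 1) * (m + 1), NEG),
      I((n + 1) * (m + 1), NEG);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int j = 1; j <= m; ++j) D[at(0, j)] = gap_open + (j - 1) * gap_extend;
  for (int i = 1; i <= n; ++i) I[at(i, 0)] = gap_open + (i - 1) * gap_extend;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = subscore(read[i - 1], ref[j - 1], match, mismatch);
      double dM = M[at(i - 1, j - 1)], dD = D[at(i - 1, j - 1)],
             dI = I[at(i - 1, j - 1)];
      double best = dM;
      if (dD > best) best = dD;
      if (dI > best) best = dI;
      M[at(i, j)] = (best == NEG) ? NEG : best + s;

      double openD = std::max(M[at(i, j - 1)], I[at(i, j - 1)]) + gap_open;
      double extD = D[at(i, j - 1)] + gap_extend;
      D[at(i, j)] = std::max(openD, extD);

      double openI = std::max(M[at(i - 1, j)], D[at(i - 1, j)]) + gap_open;
      double extI = I[at(i - 1, j)] + gap_extend;
      I[at(i, j)] = std::max(openI, extI);
    }
  }

  double sM = M[at(n, m)], sD = D[at(n, m)], sI = I[at(n, m)];
  double score = std::max(sM, std::max(sD, sI));

  // Traceback. State preference at equal score: M > D > I; inside a gap
  // run prefer extension over closing the gap (leftmost placement).
  std::string ops;
  ops.reserve(n + m);
  int i = n, j = m;
  char state;
  if (sM == score) state = 'M';
  else if (sD == score) state = 'D';
  else state = 'I';

  while (i > 0 || j > 0) {
    if (state == 'M') {
      double s = subscore(read[i - 1], ref[j - 1], match, mismatch);
      ops.push_back(read[i - 1] == ref[j - 1] && read[i - 1] != 'N' ? '=' : 'X');
      double target = M[at(i, j)] - s;
      --i; --j;
      if (M[at(i, j)] == target) state = 'M';
      else if (D[at(i, j)] == target) state = 'D';
      else state = 'I';
    } else if (state == 'D') {
      ops.push_back('D');
      double ext = D[at(i, j - 1)] + gap_extend;
      double cur = D[at(i, j)];
      --j;
      if (ext == cur && j > 0) state = 'D';
      else if (M[at(i, j)] + gap_open == cur) state = 'M';
      else if (D[at(i, j)] + gap_extend == cur) state = 'D';
      else state = 'I';
    } else { // 'I'
      ops.push_back('I');
      double ext = I[at(i - 1, j)] + gap_extend;
      double cur = I[at(i, j)];
      --i;
      if (ext == cur && i > 0) state = 'I';
      else if (M[at(i, j)] + gap_open == cur) state = 'M';
      else if (D[at(i, j)] + gap_extend == cur) state = 'D';
      else state = 'I';
    }
    if (i == 0 && j == 0) break;
    if (i == 0 && state != 'D') state = 'D';
    if (j == 0 && state != 'I') state = 'I';
  }
  std::reverse(ops.begin(), ops.end());

  return List::create(_["score"] = score, _["ops"] = ops);
}
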