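#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Gotoh global affine-gap alignment over pre-encoded sequences.
//
// Gap model: a run of L consecutive gap positions costs
//   gap_open + (L - 1) * gap_extend
// i.e. the first position of a run carries the full opening penalty and each
// further position the extension penalty. Terminal gaps are penalized like
// internal gaps (true global alignment).
//
// a, b: 1-based indices into the rows/columns of S.
// Returns the optimal score and one optimal traceback; ties are broken by
// preferring match/mismatch over a gap in `a` over a gap in `b`.

static const double NEG = -std::numeric_limits<double>::infinity();

// [[Rcpp::export]]
List gotoh_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix S,
                     double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const int W = m + 1;
  // state 0 = M (diagonal), 1 = Ia (gap in a, consumes b), 2 = Ib (gap in b)
  std::vector<double> M((n + 1) * W, NEG), Ia((n + 1) * W, NEG),
      Ib((n + 1) * W, NEG);
  M[0] = 0.0;
  for (int j = 1; j <= m; ++j) Ia[j] = gap_open + (j - 1) * gap_extend;
  for (int i = 1; i <= n; ++i) Ib[i * W] = gap_open + (i - 1) * gap_extend;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int ij = i * W + j;
      const int dg = (i - 1) * W + (j - 1);
      const int lf = i * W + (j - 1);
      const int up = (i - 1) * W + j;
      double best = M[dg];
      if (Ia[dg] > best) best = Ia[dg];
      if (Ib[dg] > best) best = Ib[dg];
      M[ij] = S(a[i - 1] - 1, b[j - 1] - 1) + best;

      double ia = M[lf] + gap_open;
      if (Ia[lf] + gap_extend > ia) ia = Ia[lf] + gap_extend;
      if (Ib[lf] + gap_open > ia) ia = Ib[lf] + gap_open;
      Ia[ij] = ia;

      double ib = M[up] + gap_open;
      if (Ia[up] + gap_open > ib) ib = Ia[up] + gap_open;
      if (Ib[up] + gap_extend > ib) ib = Ib[up] + gap_extend;
      Ib[ij] = ib;
    }
  }

  const int end = n * W + m;
  int state = 0;  // priority M > Ia > Ib at equal score
  double score = M[end];
  if (Ia[end] > score) { score = Ia[end]; state = 1; }
  if (Ib[end] > score) { score = Ib[end]; state = 2; }
  if (n == 0 && m == 0) { score = 0.0; state = 0; }

  // traceback; moves: 1 = diagonal, 2 = consume b only (gap in a),
  // 3 = consume a only (gap in b)
  std::vector<int> moves;
  moves.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int ij = i * W + j;
    if (state == 0) {
      const int dg = (i - 1) * W + (j - 1);
      const double need = M[ij] - S(a[i - 1] - 1, b[j - 1] - 1);
      moves.push_back(1);
      if (M[dg] == need) state = 0;
      else if (Ia[dg] == need) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) {
      const int lf = i * W + (j - 1);
      moves.push_back(2);
      if (M[lf] + gap_open == Ia[ij]) state = 0;
      else if (Ia[lf] + gap_extend == Ia[ij]) state = 1;
      else state = 2;
      --j;
    } else {
      const int up = (i - 1) * W + j;
      moves.push_back(3);
      if (M[up] + gap_open == Ib[ij]) state = 0;
      else if (Ia[up] + gap_open == Ib[ij]) state = 1;
      else state = 2;
      --i;
    }
  }
  std::reverse(moves.begin(), moves.end());
  return List::create(_["score"] = score,
                      _["moves"] = IntegerVector(moves.begin(), moves.end()));
}
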