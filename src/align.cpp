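#include <Rcpp.h>
#include <string>
#include <vector>

using namespace Rcpp;

// Overlap (free-end-gap) pairwise alignment with linear gap costs.
//
// Read indexes rows (i), reference indexes columns (j).  End gaps on both
// sequences are free: the first row and column are initialised to zero and
// the alignment ends at the best-scoring cell on the last row or column.
// Interior gaps cost `gap` per base.  Traceback tie-break order is
// diagonal > up (gap in read, i.e. deletion) > left (gap in reference,
// i.e. insertion); left-normalization downstream fixes the canonical indel
// position regardless of this order.
//
// Returns the aligned core only: terminal free gaps are reported as the
// unaligned ref/read flanks via the span fields, never as gap columns.

static inline int subst_score(char a, char b, int match, int mismatch) {
  // N (either case) never matches anything, including another N
  if (a == 'N' || a == 'n' || b == 'N' || b == 'n') return mismatch;
  char ua = (a >= 'a') ? a - 32 : a;
  char ub = (b >= 'a') ? b - 32 : b;
  return (ua == ub) ? match : mismatch;
}

// [[Rcpp::export(name = ".overlap_align_cpp")]]
List overlap_align_cpp(std::string read, std::string ref,
                       int match, int mismatch, int gap) {
  const int n = (int) read.size();  // rows
  const int m = (int) ref.size();   // cols
  if (n == 0 || m == 0) stop("empty sequence");

  // score matrix, (n+1) x (m+1), row-major
  std::vector<int> S((size_t)(n + 1) * (m + 1), 0);
  auto at = [m](int i, int j) { return (size_t) i * (m + 1) + j; };

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int d = S[at(i - 1, j - 1)] + subst_score(read[i - 1], ref[j - 1], match, mismatch);
      int u = S[at(i - 1, j)] + gap;   // consume read base: gap in ref (insertion)
      int l = S[at(i, j - 1)] + gap;   // consume ref base: gap in read (deletion)
      int best = d;
      if (u > best) best = u;
      if (l > best) best = l;
      S[at(i, j)] = best;
    }
  }

  // End cell: best score on last row or last column; ties resolved toward
  // the longest alignment (largest i, then largest j) so less is trimmed.
  int bi = 0, bj = m, bscore = S[at(0, m)];
  for (int i = 0; i <= n; ++i) {
    if (S[at(i, m)] >= bscore) { bscore = S[at(i, m)]; bi = i; bj = m; }
  }
  for (int j = 0; j <= m; ++j) {
    if (S[at(n, j)] >= bscore) { bscore = S[at(n, j)]; bi = n; bj = j; }
  }

  // Traceback to the first row or column.
  std::string ar, arf;  // aligned read, aligned ref (reversed during build)
  int i = bi, j = bj;
  int matches = 0, columns = 0;
  while (i > 0 && j > 0) {
    int cur = S[at(i, j)];
    int d = S[at(i - 1, j - 1)] + subst_score(read[i - 1], ref[j - 1], match, mismatch);
    if (cur == d) {
      ar.push_back(read[i - 1]);
      arf.push_back(ref[j - 1]);
      if (subst_score(read[i - 1], ref[j - 1], match, mismatch) == match &&
          match > mismatch)
        ++matches;
      --i; --j; ++columns;
      continue;
    }
    int l = S[at(i, j - 1)] + gap;  // deletion: gap in read
    if (cur == l) {
      ar.push_back('-');
      arf.push_back(ref[j - 1]);
      --j; ++columns;
      continue;
    }
    // insertion: gap in ref
    ar.push_back(read[i - 1]);
    arf.push_back('-');
    --i; ++columns;
  }
  std::reverse(ar.begin(), ar.end());
  std::reverse(arf.begin(), arf.end());

  return List::create(
    _["score"] = bscore,
    _["read_start"] = i,        // 0-based, half-open spans
    _["read_end"] = bi,
    _["ref_start"] = j,
    _["ref_end"] = bj,
    _["aligned_read"] = ar,
    _["aligned_ref"] = arf,
    _["n_match"] = matches,
    _["n_columns"] = columns);
}
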