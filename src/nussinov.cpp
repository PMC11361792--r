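#include <Rcpp.h>
#include <vector>
#include <string>

// Maximum-base-pairing (Nussinov) dynamic program with a hairpin-loop
// minimum, used as the dependency-free fallback secondary-structure folder.
// Allowed pairs: AU, GC and the GU wobble. N pairs with nothing.

static inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

// [[Rcpp::export]]
std::string nussinov_db_cpp(std::string seq, int min_loop) {
  const int L = (int) seq.size();
  std::string db(L, '.');
  if (L < min_loop + 2) return db;

  std::vector< std::vector<int> > M(L, std::vector<int>(L, 0));
  for (int span = min_loop + 1; span < L; ++span) {
    for (int i = 0; i + span < L; ++i) {
      const int j = i + span;
      int best = M[i + 1][j];  // position i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!can_pair(seq[i], seq[k])) continue;
        const int inner = (k > i + 1) ? M[i + 1][k - 1] : 0;
        const int right = (k < j) ? M[k + 1][j] : 0;
        const int v = inner + right + 1;
        if (v > best) best = v;
      }
      M[i][j] = best;
    }
  }

  // Deterministic traceback: prefer leaving i unpaired, otherwise pair i
  // with the smallest admissible partner k achieving the optimum.
  std::vector< std::pair<int, int> > work;
  work.push_back(std::make_pair(0, L - 1));
  while (!work.empty()) {
    const int i = work.back().first;
    const int j = work.back().second;
    work.pop_back();
    if (i >= j || j - i <= min_loop) continue;
    if (M[i][j] == M[i + 1][j]) {
      work.push_back(std::make_pair(i + 1, j));
      continue;
    }
    for (int k = i + min_loop + 1; k <= j; ++k) {
      if (!can_pair(seq[i], seq[k])) continue;
      const int inner = (k > i + 1) ? M[i + 1][k - 1] : 0;
      const int right = (k < j) ? M[k + 1][j] : 0;
      if (inner + right + 1 == M[i][j]) {
        db[i] = '(';
        db[k] = ')';
        if (k < j) work.push_back(std::make_pair(k + 1, j));
        if (k > i + 1) work.push_back(std::make_pair(i + 1, k - 1));
        break;
      }
    }
  }
  return db;
}
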