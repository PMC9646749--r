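#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// canonical pairs on the DNA alphabet (incl. the G-T wobble)
static inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'T') || (a == 'T' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'T') || (a == 'T' && b == 'G');
}

// Nussinov-style base-pair maximisation with a minimum hairpin gap.
// dp(i,j) = max(dp(i+1,j), max over k>i pairing with i of
//               dp(i+1,k-1) + 1 + dp(k+1,j)).
// Traceback prefers pairing (leftmost partner) over leaving i unpaired,
// which makes the returned structure deterministic.
// [[Rcpp::export(name = ".nussinov_fold")]]
List nussinov_fold(std::string seq, int min_hairpin) {
  const int n = (int) seq.size();
  std::string db(n, '.');
  if (n == 0) return List::create(_["structure"] = db, _["pairs"] = 0);

  std::vector<int> dp((size_t) n * n, 0);
  auto at = [&](int i, int j) -> int& { return dp[(size_t) i * n + j]; };

  for (int len = min_hairpin + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = at(i + 1, j);
      for (int k = i + min_hairpin + 1; k <= j; ++k) {
        if (!can_pair(seq[(size_t) i], seq[(size_t) k])) continue;
        int inner = (k - 1 >= i + 1) ? at(i + 1, k - 1) : 0;
        int right = (k + 1 <= j) ? at(k + 1, j) : 0;
        int v = inner + 1 + right;
        if (v > best) best = v;
      }
      at(i, j) = best;
    }
  }

  int pairs = 0;
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j - i < min_hairpin + 1) continue;
    int target = at(i, j);
    if (target == 0) continue;
    bool paired = false;
    for (int k = i + min_hairpin + 1; k <= j; ++k) {
      if (!can_pair(seq[(size_t) i], seq[(size_t) k])) continue;
      int inner = (k - 1 >= i + 1) ? at(i + 1, k - 1) : 0;
      int right = (k + 1 <= j) ? at(k + 1, j) : 0;
      if (inner + 1 + right == target) {
        db[(size_t) i] = '(';
        db[(size_t) k] = ')';
        ++pairs;
        if (k - 1 > i + 1) stack.push_back(std::make_pair(i + 1, k - 1));
        if (k + 1 < j) stack.push_back(std::make_pair(k + 1, j));
        paired = true;
        break;
      }
    }
    if (!paired) stack.push_back(std::make_pair(i + 1, j));
  }

  return List::create(_["structure"] = db, _["pairs"] = pairs);
}
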