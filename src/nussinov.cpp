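#include <Rcpp.h>
#include <vector>
#include <string>
#include <stack>

using namespace Rcpp;

// Pair energies (kcal/mol by convention): G:C -3, A:U -2, G:U -1.
// T is treated as U so DNA-alphabet input folds identically.
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'U': case 'u': case 'T': case 't': return 3;
  default: return -1; // N and friends: unpairable
  }
}

static inline double pair_energy(int a, int b) {
  if (a < 0 || b < 0) return 0.0;
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return -3.0; // G:C
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return -2.0; // A:U
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return -1.0; // G:U
  return 0.0;
}

// Energy-minimizing Nussinov-style DP over pseudoknot-free structures with a
// minimum hairpin loop of `min_loop` unpaired bases. Ties prefer leaving the
// 5'-most base unpaired, then the smallest pairing partner (deterministic).
// [[Rcpp::export(name = ".c_nussinov")]]
List c_nussinov(std::string seq, int min_loop = 3) {
  int n = (int) seq.size();
  if (n == 0) stop("sequence must be non-empty");
  if (n > 1000) stop("sequence longer than 1000 nt not supported");

  std::vector<int> code(n);
  for (int i = 0; i < n; ++i) code[i] = base_code(seq[i]);

  // E[i][j], 0-based inclusive, j >= i; stored as flat n*n (n <= 1000 guard
  // keeps this under 8 MB).
  std::vector<double> E((size_t) n * n, 0.0);
  auto idx = [n](int i, int j) { return (size_t) i * n + j; };

  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      double best = E[idx(i + 1, j)]; // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        double e = pair_energy(code[i], code[k]);
        if (e >= 0.0) continue;
        double inner = (k - i - 1 > min_loop) ? E[idx(i + 1, k - 1)] : 0.0;
        double right = (k + 1 <= j) ? E[idx(k + 1, j)] : 0.0;
        double cand = e + inner + right;
        if (cand < best) best = cand;
      }
      E[idx(i, j)] = best;
    }
  }

  // Traceback.
  std::string db(n, '.');
  std::stack<std::pair<int, int> > todo;
  if (n > 1) todo.push(std::make_pair(0, n - 1));
  while (!todo.empty()) {
    int i = todo.top().first, j = todo.top().second;
    todo.pop();
    if (j - i < min_loop + 1) continue;
    double target = E[idx(i, j)];
    if (target == E[idx(i + 1, j)]) { // tie rule: i unpaired wins
      todo.push(std::make_pair(i + 1, j));
      continue;
    }
    bool found = false;
    for (int k = i + min_loop + 1; k <= j && !found; ++k) {
      double e = pair_energy(code[i], code[k]);
      if (e >= 0.0) continue;
      double inner = (k - i - 1 > min_loop) ? E[idx(i + 1, k - 1)] : 0.0;
      double right = (k + 1 <= j) ? E[idx(k + 1, j)] : 0.0;
      if (e + inner + right == target) {
        db[i] = '(';
        db[k] = ')';
        if (k - i - 1 > min_loop) todo.push(std::make_pair(i + 1, k - 1));
        if (k + 1 <= j) todo.push(std::make_pair(k + 1, j));
        found = true;
      }
    }
    if (!found) stop("internal error: traceback failed"); // should not happen
  }

  double mfe = (n > 1) ? E[idx(0, n - 1)] : 0.0;
  return List::create(_["structure"] = db, _["mfe"] = mfe);
}
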