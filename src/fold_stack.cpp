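#include <Rcpp.h>
#include <string>
#include <vector>
#include <stack>

// Weighted Nussinov base-pair maximisation with a minimum hairpin loop of 3
// unpaired bases. Pair weights reflect relative pair stability (G:C 3,
// A:U 2, G:U 1). Used as the built-in "stackmax" folding engine; the default
// engine is a thermodynamic folder, so this only needs to produce sensible
// stems on designed fixtures, not calibrated energies.

static inline int pair_weight(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return 2;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return 1;
  return 0;
}

// [[Rcpp::export(name = ".nussinov_fold")]]
Rcpp::List nussinov_fold(std::string seq, int min_loop = 3) {
  const int n = (int)seq.size();
  if (n < 1) Rcpp::stop("empty sequence");
  std::vector<std::vector<int>> M(n, std::vector<int>(n, 0));

  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = M[i + 1][j];                    // i unpaired
      int w = pair_weight(seq[i], seq[j]);
      if (w > 0) {
        int inner = (i + 1 <= j - 1) ? M[i + 1][j - 1] : 0;
        if (inner + w > best) best = inner + w;  // i pairs j
      }
      for (int k = i + 1; k < j; ++k) {          // bifurcation
        int v = M[i][k] + M[k + 1][j];
        if (v > best) best = v;
      }
      M[i][j] = best;
    }
  }

  // iterative traceback
  std::string db(n, '.');
  std::stack<std::pair<int, int>> todo;
  todo.push({0, n - 1});
  while (!todo.empty()) {
    int i = todo.top().first, j = todo.top().second;
    todo.pop();
    if (i >= j || j - i <= min_loop) continue;
    if (M[i][j] == M[i + 1][j]) {
      todo.push({i + 1, j});
      continue;
    }
    int w = pair_weight(seq[i], seq[j]);
    if (w > 0) {
      int inner = (i + 1 <= j - 1) ? M[i + 1][j - 1] : 0;
      if (M[i][j] == inner + w) {
        db[i] = '(';
        db[j] = ')';
        todo.push({i + 1, j - 1});
        continue;
      }
    }
    bool split = false;
    for (int k = i + 1; k < j; ++k) {
      if (M[i][j] == M[i][k] + M[k + 1][j]) {
        todo.push({i, k});
        todo.push({k + 1, j});
        split = true;
        break;
      }
    }
    if (!split) todo.push({i + 1, j});
  }

  return Rcpp::List::create(Rcpp::Named("dotbracket") = db,
                            Rcpp::Named("score") = M[0][n - 1]);
}
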