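#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Degree-preserving double-edge-swap randomisation (the randmio-style
// null). `attempts` swap attempts are made; invalid picks (shared
// endpoints or already-present target edges) are skipped, so graphs with
// no valid swap (e.g. stars) come back unchanged. Uses the R RNG.
// [[Rcpp::export]]
List rewire_cpp(IntegerMatrix adj, int attempts) {
  int n = adj.nrow();
  std::vector<int> A(n * n);
  std::vector<int> ei, ej;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      A[i * n + j] = adj(i, j);
      if (j > i && adj(i, j)) { ei.push_back(i); ej.push_back(j); }
    }
  int m = (int)ei.size();
  int swaps = 0;
  if (m >= 2) {
    RNGScope scope;
    for (int t = 0; t < attempts; ++t) {
      int e1 = (int)(unif_rand() * m); if (e1 == m) e1 = m - 1;
      int e2 = (int)(unif_rand() * m); if (e2 == m) e2 = m - 1;
      if (e1 == e2) continue;
      int a = ei[e1], b = ej[e1], c = ei[e2], d = ej[e2];
      if (unif_rand() < 0.5) { int tmp = c; c = d; d = tmp; }
      // proposed: (a,c) and (b,d)
      if (a == c || a == d || b == c || b == d) continue;
      if (A[a * n + c] || A[b * n + d]) continue;
      A[a * n + b] = A[b * n + a] = 0;
      A[c * n + d] = A[d * n + c] = 0;
      A[a * n + c] = A[c * n + a] = 1;
      A[b * n + d] = A[d * n + b] = 1;
      ei[e1] = a < c ? a : c; ej[e1] = a < c ? c : a;
      ei[e2] = b < d ? b : d; ej[e2] = b < d ? d : b;
      ++swaps;
    }
  }
  IntegerMatrix out(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) out(i, j) = A[i * n + j];
  return List::create(_["adjacency"] = out, _["swaps"] = swaps);
}
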