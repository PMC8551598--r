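#include <Rcpp.h>
using namespace Rcpp;

// Maslov-Sneppen double-edge swaps on an undirected weighted edge list.
// Degrees are preserved exactly; weights travel with their edge slot, so the
// weight multiset is preserved exactly. Uses R's RNG so results are a pure
// function of the caller's seed.
//
// ei, ej: 1-based endpoints (i < j); n: node count; nSwap: target number of
// accepted swaps; maxTries: attempt cap.
// [[Rcpp::export]]
List rewire_swaps(IntegerVector ei, IntegerVector ej, int n, int nSwap,
                  int maxTries) {
  int m = ei.size();
  std::vector<int> a(ei.begin(), ei.end()), b(ej.begin(), ej.end());
  // adjacency lookup
  std::vector<bool> adj((size_t)n * n, false);
  for (int e = 0; e < m; ++e) {
    adj[(size_t)(a[e] - 1) * n + (b[e] - 1)] = true;
    adj[(size_t)(b[e] - 1) * n + (a[e] - 1)] = true;
  }
  int done = 0;
  long tries = 0;
  GetRNGstate();
  while (done < nSwap && tries < maxTries) {
    ++tries;
    int e1 = (int)(unif_rand() * m);
    int e2 = (int)(unif_rand() * m);
    if (e1 == e2) continue;
    int x1 = a[e1], y1 = b[e1], x2 = a[e2], y2 = b[e2];
    if (x1 == x2 || x1 == y2 || y1 == x2 || y1 == y2) continue;
    // with prob 0.5 flip the second edge's orientation
    if (unif_rand() < 0.5) { int t = x2; x2 = y2; y2 = t; }
    // proposed new edges: (x1, y2) and (x2, y1)
    if (adj[(size_t)(x1 - 1) * n + (y2 - 1)] ||
        adj[(size_t)(x2 - 1) * n + (y1 - 1)]) continue;
    adj[(size_t)(x1 - 1) * n + (y1 - 1)] = false;
    adj[(size_t)(y1 - 1) * n + (x1 - 1)] = false;
    adj[(size_t)(x2 - 1) * n + (y2 - 1)] = false;
    adj[(size_t)(y2 - 1) * n + (x2 - 1)] = false;
    adj[(size_t)(x1 - 1) * n + (y2 - 1)] = true;
    adj[(size_t)(y2 - 1) * n + (x1 - 1)] = true;
    adj[(size_t)(x2 - 1) * n + (y1 - 1)] = true;
    adj[(size_t)(y1 - 1) * n + (x2 - 1)] = true;
    a[e1] = std::min(x1, y2); b[e1] = std::max(x1, y2);
    a[e2] = std::min(x2, y1); b[e2] = std::max(x2, y1);
    ++done;
  }
  PutRNGstate();
  return List::create(_["ei"] = IntegerVector(a.begin(), a.end()),
                      _["ej"] = IntegerVector(b.begin(), b.end()),
                      _["accepted"] = done);
}
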