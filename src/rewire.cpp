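#include <Rcpp.h>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

// Undirected edge key; nodes are 1-based vertex indices.
static inline long long ekey(int a, int b, long long span) {
  if (a > b) std::swap(a, b);
  return (long long)a * span + b;
}

// Degree-preserving edge rewiring (Maslov-Sneppen). Picks two distinct
// edges per attempt and exchanges endpoints; attempts that would create a
// self-loop or a multi-edge are rejected and leave the graph unchanged.
// Attempts (not successes) count toward n_attempts. Uses R's RNG so results
// are reproducible under set.seed().
// [[Rcpp::export]]
List ms_rewire_cpp(IntegerVector from, IntegerVector to,
                   int n_nodes, double n_attempts) {
  int m = from.size();
  std::vector<int> u(from.begin(), from.end());
  std::vector<int> v(to.begin(), to.end());
  long long span = (long long)n_nodes + 1;
  std::unordered_set<long long> edges;
  edges.reserve((size_t)m * 2);
  for (int i = 0; i < m; ++i) edges.insert(ekey(u[i], v[i], span));

  long long attempts = (long long)n_attempts;
  long long success = 0;
  for (long long t = 0; t < attempts; ++t) {
    int i = (int)(unif_rand() * m); if (i >= m) i = m - 1;
    int j = (int)(unif_rand() * m); if (j >= m) j = m - 1;
    if (i == j) continue;
    int a = u[i], b = v[i], c = u[j], d = v[j];
    // two possible endpoint pairings; pick one uniformly
    if (unif_rand() < 0.5) std::swap(c, d);
    // proposal: {a,d} and {b,c}
    if (a == d || b == c) continue;              // self-loop
    long long ko1 = ekey(u[i], v[i], span);
    long long ko2 = ekey(u[j], v[j], span);
    long long kn1 = ekey(a, d, span);
    long long kn2 = ekey(b, c, span);
    if (kn1 == kn2) continue;                    // would duplicate
    if ((kn1 == ko1 && kn2 == ko2) ||
        (kn1 == ko2 && kn2 == ko1)) continue;    // no-op pairing
    edges.erase(ko1);
    edges.erase(ko2);
    if (edges.count(kn1) || edges.count(kn2)) {  // multi-edge
      edges.insert(ko1);
      edges.insert(ko2);
      continue;
    }
    edges.insert(kn1);
    edges.insert(kn2);
    u[i] = a; v[i] = d;
    u[j] = b; v[j] = c;
    ++success;
  }

  return List::create(_["from"] = IntegerVector(u.begin(), u.end()),
                      _["to"] = IntegerVector(v.begin(), v.end()),
                      _["successes"] = (double)success);
}
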