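#include <Rcpp.h>
using namespace Rcpp;

// Degree-preserving double-edge (Maslov-Sneppen) swaps constrained by
// distance bins: a swap replacing edges (a,b),(c,d) with (a,d),(c,b) is
// accepted only if each replacement edge falls in the same distance bin as
// the edge it replaces, so the distance profile of the edge set is
// preserved bin-exactly. Because an accepted swap keeps every edge in its
// own bin, candidate pairs are proposed within a bin, which raises the
// acceptance rate on geometric graphs without changing the constraint set.
// Edge endpoints are 0-based. Uses R's RNG, so results are reproducible
// under set.seed().
// [[Rcpp::export]]
List rewire_edges(IntegerVector ei, IntegerVector ej, IntegerVector ebin,
                  IntegerMatrix binmat, int n_nodes, int n_attempts) {
  int E = ei.size();
  std::vector<char> adj((size_t)n_nodes * n_nodes, 0);
  std::vector<int> a_(E), b_(E);
  int max_bin = 0;
  for (int e = 0; e < E; ++e) {
    a_[e] = ei[e]; b_[e] = ej[e];
    adj[(size_t)a_[e] * n_nodes + b_[e]] = 1;
    adj[(size_t)b_[e] * n_nodes + a_[e]] = 1;
    if (ebin[e] > max_bin) max_bin = ebin[e];
  }
  // static per-bin edge lists (edge bins are invariant under accepted swaps)
  std::vector< std::vector<int> > bins(max_bin + 1);
  for (int e = 0; e < E; ++e) bins[ebin[e]].push_back(e);
  // sample the first edge uniformly; the partner comes from the same bin
  int accepted = 0;
  for (int t = 0; t < n_attempts; ++t) {
    int e1 = (int)(unif_rand() * E);
    const std::vector<int>& peers = bins[ebin[e1]];
    if (peers.size() < 2) continue;
    int e2 = peers[(int)(unif_rand() * peers.size())];
    if (e1 == e2) continue;
    int a = a_[e1], b = b_[e1];
    int c = a_[e2], d = b_[e2];
    if (unif_rand() < 0.5) { int tmp = c; c = d; d = tmp; }
    if (a == d || c == b || a == c || b == d) continue;
    if (adj[(size_t)a * n_nodes + d] || adj[(size_t)c * n_nodes + b]) continue;
    if (binmat(a, d) != ebin[e1] || binmat(c, b) != ebin[e2]) continue;
    // accept: (a,b),(c,d) -> (a,d),(c,b)
    adj[(size_t)a * n_nodes + b] = 0; adj[(size_t)b * n_nodes + a] = 0;
    adj[(size_t)c * n_nodes + d] = 0; adj[(size_t)d * n_nodes + c] = 0;
    adj[(size_t)a * n_nodes + d] = 1; adj[(size_t)d * n_nodes + a] = 1;
    adj[(size_t)c * n_nodes + b] = 1; adj[(size_t)b * n_nodes + c] = 1;
    b_[e1] = d;
    a_[e2] = c; b_[e2] = b;
    ++accepted;
  }
  return List::create(Named("i") = IntegerVector(a_.begin(), a_.end()),
                      Named("j") = IntegerVector(b_.begin(), b_.end()),
                      Named("accepted") = accepted);
}
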