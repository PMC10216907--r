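#include <Rcpp.h>
using namespace Rcpp;

// Discrete-time SIR with recovery probability 1: every infected node is
// infectious for exactly one synchronous generation. Each susceptible
// neighbour of the current frontier is attempted independently with
// probability beta (short-circuited once a node is infected: the success
// probability for m attackers is 1 - (1-beta)^m either way). Uses R's RNG,
// so results are reproducible under set.seed().
//
// adj: 1-based adjacency list; returns the recovered count of each run.

// [[Rcpp::export]]
IntegerVector sir_runs_cpp(const List& adj, int n, int seed_node,
                           double beta, int sn) {
  std::vector<std::vector<int> > nb(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = adj[i];
    nb[i].assign(v.begin(), v.end());
  }
  IntegerVector out(sn);
  std::vector<int> state(n), frontier, nxt;
  frontier.reserve(n);
  nxt.reserve(n);
  const int seed0 = seed_node - 1;
  for (int r = 0; r < sn; ++r) {
    std::fill(state.begin(), state.end(), 0);
    frontier.clear();
    frontier.push_back(seed0);
    state[seed0] = 1;
    int nr = 1;
    while (!frontier.empty()) {
      for (size_t k = 0; k < frontier.size(); ++k) state[frontier[k]] = 2;
      nxt.clear();
      if (beta > 0.0) {
        for (size_t k = 0; k < frontier.size(); ++k) {
          const std::vector<int>& nbs = nb[frontier[k]];
          for (size_t q = 0; q < nbs.size(); ++q) {
            const int v = nbs[q] - 1;
            if (state[v] == 0 && unif_rand() < beta) {
              state[v] = 1;
              ++nr;
              nxt.push_back(v);
            }
          }
        }
      }
      frontier.swap(nxt);
    }
    out[r] = nr;
  }
  return out;
}
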