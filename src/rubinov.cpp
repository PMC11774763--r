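#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Rank-matched weight placement onto a fixed undirected topology.
// ei/ej: 0-based endpoints of the scaffold edges; w_desc: the original weight
// magnitudes sorted in descending order; s_target: empirical strengths (per
// sign class for signed networks); tiekey: per-edge random keys breaking ties
// in the expected-magnitude ranking.
//
// Each step picks an unassigned scaffold edge uniformly at random, ranks it
// among the unassigned edges by expected magnitude
//   e_ij = (s_i - sum_u A_iu)(s_j - sum_u A_ju),
// assigns it the remaining original weight of the same rank, and updates the
// two touched residual strengths.
// [[Rcpp::export]]
NumericVector cpp_rs_place(int n, IntegerVector ei, IntegerVector ej,
                           NumericVector w_desc, NumericVector s_target,
                           NumericVector tiekey) {
  int E = ei.size();
  std::vector<double> resid(s_target.begin(), s_target.end());
  std::vector<double> remaining(w_desc.begin(), w_desc.end());
  std::vector<int> unassigned(E);
  for (int e = 0; e < E; ++e) unassigned[e] = e;
  NumericVector out(E);
  int m = E;
  while (m > 0) {
    int p;
    do {
      p = (int)(unif_rand() * m);
    } while (p >= m);
    int u = unassigned[p];
    double eu = resid[ei[u]] * resid[ej[u]];
    double ku = tiekey[u];
    int rank = 0;
    for (int q = 0; q < m; ++q) {
      int v = unassigned[q];
      if (v == u) continue;
      double ev = resid[ei[v]] * resid[ej[v]];
      if (ev > eu || (ev == eu && tiekey[v] > ku)) ++rank;
    }
    double w = remaining[rank];
    remaining.erase(remaining.begin() + rank);
    out[u] = w;
    resid[ei[u]] -= w;
    resid[ej[u]] -= w;
    unassigned[p] = unassigned[m - 1];
    unassigned.pop_back();
    --m;
  }
  return out;
}
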