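#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// objectives
#define OBJ_UND 0
#define OBJ_DIR 1
#define OBJ_SIGNED 2
#define OBJ_DIR_ALT 3

static inline int rand_int(int m) {
  int r;
  do {
    r = (int)(unif_rand() * m);
  } while (r >= m);
  return r;
}

// mean squared error between current and target strength vectors, as a sum
// of squared deviations (divided by n on use)
static double sq_err(const std::vector<double>& cur, const double* tgt, int n) {
  double acc = 0;
  for (int i = 0; i < n; ++i) {
    double d = cur[i] - tgt[i];
    acc += d * d;
  }
  return acc;
}

// Strength sequence-preserving weight permutation by simulated annealing.
//
// The scaffold topology (ei, ej, initial weights w) is fixed; proposals swap
// two edge weights and are accepted by the Metropolis criterion
// r < exp(-(E' - E)/T) with E the mean squared error between the target
// (empirical) and current strength sequences. Objectives:
//   und:     E = mse(strength)                      t1 = s
//   dir:     E = mse(in) + mse(out)                 t1 = s_in, t2 = s_out
//   signed:  E = mse(pos) + mse(neg magnitudes)     t1 = s_pos, t2 = s_neg
//   dir_alt: E = mse(in); proposals swap two outgoing weights of one node,
//            so the out-strength sequence is preserved exactly.
// The temperature is multiplied by `cool` at the end of each stage; with
// `thr > 0` the run halts at the first stage end where E <= thr (up to
// `max_stages`), otherwise it runs exactly `n_stages` stages.
//
// Energy is updated incrementally per swap (only the touched node strengths
// change) and recomputed in full at each stage end; a drift beyond
// 1e-9 * n aborts.
// [[Rcpp::export]]
List cpp_sa(int objective, int n, IntegerVector ei, IntegerVector ej,
            NumericVector w_init, NumericVector t1, NumericVector t2,
            int n_stages, int iters, double T0, double cool, double thr,
            int max_stages) {
  int E = ei.size();
  std::vector<double> w(w_init.begin(), w_init.end());

  // current strength state; meaning depends on objective
  std::vector<double> s1(n, 0.0), s2(n, 0.0);
  // edge -> sign class (signed objective); per-class edge index lists
  std::vector<int> pos_idx, neg_idx;
  // dir_alt: out-edge lists per node, nodes with >= 2 outgoing edges
  std::vector<std::vector<int> > out_edges;
  std::vector<int> eligible;

  for (int e = 0; e < E; ++e) {
    double we = w[e];
    int a = ei[e], b = ej[e];
    switch (objective) {
    case OBJ_UND:
      s1[a] += we; s1[b] += we;
      break;
    case OBJ_DIR:
      s1[b] += we;  // in
      s2[a] += we;  // out
      break;
    case OBJ_SIGNED:
      if (we > 0) {
        s1[a] += we; s1[b] += we;
        pos_idx.push_back(e);
      } else {
        s2[a] -= we; s2[b] -= we;
        neg_idx.push_back(e);
      }
      break;
    case OBJ_DIR_ALT:
      s1[b] += we;
      break;
    }
  }
  if (objective == OBJ_DIR_ALT) {
    out_edges.assign(n, std::vector<int>());
    for (int e = 0; e < E; ++e) out_edges[ei[e]].push_back(e);
    for (int i = 0; i < n; ++i) {
      if (out_edges[i].size() >= 2) eligible.push_back(i);
    }
    if (eligible.empty()) {
      stop("no node has two or more outgoing edges; nothing to permute");
    }
  }

  bool two_part = (objective == OBJ_DIR || objective == OBJ_SIGNED);
  double energy = sq_err(s1, t1.begin(), n) / n;
  if (two_part) energy += sq_err(s2, t2.begin(), n) / n;
  double initial_energy = energy;
  double best_energy = energy;

  int total_stages = (thr > 0) ? max_stages : n_stages;
  std::vector<double> stage_energies;
  std::vector<int> accepted;
  stage_energies.reserve(total_stages);
  accepted.reserve(total_stages);
  double T = T0;
  int stages_run = 0;

  // scratch for affected nodes: index into s-vector (node id + part offset)
  int touch_node[4];
  int touch_part[4];
  double touch_delta[4];

  for (int stage = 0; stage < total_stages; ++stage) {
    int acc = 0;
    for (int it = 0; it < iters; ++it) {
      int e1, e2;
      if (objective == OBJ_SIGNED) {
        e1 = rand_int(E);
        const std::vector<int>& cls = (w[e1] > 0) ? pos_idx : neg_idx;
        if ((int)cls.size() < 2) { unif_rand(); continue; }
        e2 = cls[rand_int((int)cls.size())];
      } else if (objective == OBJ_DIR_ALT) {
        int u = eligible[rand_int((int)eligible.size())];
        const std::vector<int>& oe = out_edges[u];
        int p1 = rand_int((int)oe.size());
        int p2 = rand_int((int)oe.size());
        e1 = oe[p1]; e2 = oe[p2];
      } else {
        e1 = rand_int(E);
        e2 = rand_int(E);
      }
      double u_var = unif_rand();  // Metropolis variate, one per proposal
      if (e1 == e2 || w[e1] == w[e2]) {
        // swapping identical weights (or an edge with itself) leaves the
        // configuration unchanged; it is a trivially accepted proposal
        if (e1 != e2) ++acc;
        continue;
      }
      double d = w[e2] - w[e1];
      int nt = 0;
      int part1 = 0, part2 = 0;  // which strength vector each endpoint hits
      switch (objective) {
      case OBJ_UND:
        touch_node[nt] = ei[e1]; touch_part[nt] = 0; touch_delta[nt++] = d;
        touch_node[nt] = ej[e1]; touch_part[nt] = 0; touch_delta[nt++] = d;
        touch_node[nt] = ei[e2]; touch_part[nt] = 0; touch_delta[nt++] = -d;
        touch_node[nt] = ej[e2]; touch_part[nt] = 0; touch_delta[nt++] = -d;
        break;
      case OBJ_DIR:
        touch_node[nt] = ej[e1]; touch_part[nt] = 0; touch_delta[nt++] = d;
        touch_node[nt] = ej[e2]; touch_part[nt] = 0; touch_delta[nt++] = -d;
        touch_node[nt] = ei[e1]; touch_part[nt] = 1; touch_delta[nt++] = d;
        touch_node[nt] = ei[e2]; touch_part[nt] = 1; touch_delta[nt++] = -d;
        break;
      case OBJ_SIGNED:
        part1 = (w[e1] > 0) ? 0 : 1;
        part2 = part1;  // same sign class
        {
          double dm = std::fabs(w[e2]) - std::fabs(w[e1]);
          touch_node[nt] = ei[e1]; touch_part[nt] = part1; touch_delta[nt++] = dm;
          touch_node[nt] = ej[e1]; touch_part[nt] = part1; touch_delta[nt++] = dm;
          touch_node[nt] = ei[e2]; touch_part[nt] = part2; touch_delta[nt++] = -dm;
          touch_node[nt] = ej[e2]; touch_part[nt] = part2; touch_delta[nt++] = -dm;
        }
        break;
      case OBJ_DIR_ALT:
        touch_node[nt] = ej[e1]; touch_part[nt] = 0; touch_delta[nt++] = d;
        touch_node[nt] = ej[e2]; touch_part[nt] = 0; touch_delta[nt++] = -d;
        break;
      }
      // energy change restricted to the touched strengths; duplicate nodes
      // are handled by applying deltas sequentially
      double dE = 0;
      for (int q = 0; q < nt; ++q) {
        std::vector<double>& sv = touch_part[q] ? s2 : s1;
        const double* tv = touch_part[q] ? t2.begin() : t1.begin();
        int v = touch_node[q];
        double before = sv[v] - tv[v];
        sv[v] += touch_delta[q];
        double after = sv[v] - tv[v];
        dE += (after * after - before * before) / n;
      }
      bool ok = (dE < 0) || (u_var < std::exp(-dE / T));
      if (ok) {
        double tmp = w[e1]; w[e1] = w[e2]; w[e2] = tmp;
        energy += dE;
        ++acc;
      } else {
        for (int q = nt - 1; q >= 0; --q) {
          std::vector<double>& sv = touch_part[q] ? s2 : s1;
          sv[touch_node[q]] -= touch_delta[q];
        }
      }
    }
    // stage end: full recomputation guards against incremental drift
    std::fill(s1.begin(), s1.end(), 0.0);
    std::fill(s2.begin(), s2.end(), 0.0);
    for (int e = 0; e < E; ++e) {
      double we = w[e];
      int a = ei[e], b = ej[e];
      switch (objective) {
      case OBJ_UND: s1[a] += we; s1[b] += we; break;
      case OBJ_DIR: s1[b] += we; s2[a] += we; break;
      case OBJ_SIGNED:
        if (we > 0) { s1[a] += we; s1[b] += we; }
        else { s2[a] -= we; s2[b] -= we; }
        break;
      case OBJ_DIR_ALT: s1[b] += we; break;
      }
    }
    double full = sq_err(s1, t1.begin(), n) / n;
    if (two_part) full += sq_err(s2, t2.begin(), n) / n;
    if (std::fabs(full - energy) > 1e-9 * n) {
      stop("incremental energy drifted from full recomputation");
    }
    energy = full;
    if (energy < best_energy) best_energy = energy;
    stage_energies.push_back(energy);
    accepted.push_back(acc);
    ++stages_run;
    if (thr > 0 && energy <= thr) break;
    T *= cool;
  }

  return List::create(
    _["weights"] = NumericVector(w.begin(), w.end()),
    _["stage_energies"] = NumericVector(stage_energies.begin(), stage_energies.end()),
    _["accepted_per_stage"] = IntegerVector(accepted.begin(), accepted.end()),
    _["initial_energy"] = initial_energy,
    _["final_energy"] = energy,
    _["best_energy"] = best_energy,
    _["stages_run"] = stages_run);
}
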