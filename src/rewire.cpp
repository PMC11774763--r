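#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// adjacency kept twice: a presence matrix for O(1) existence checks and
// neighbor lists for breadth-first reachability
struct Adj {
  int n;
  std::vector<char> present;            // row-major u * n + v
  std::vector<std::vector<int> > nb;    // out-neighbors (und: both ways)
  std::vector<char> vis;
  std::vector<int> queue;

  explicit Adj(int n_) : n(n_), present((size_t)n_ * n_, 0), nb(n_), vis(n_) {
    queue.reserve(n_);
  }
  bool has(int u, int v) const { return present[(size_t)u * n + v] != 0; }
  void add(int u, int v) {
    present[(size_t)u * n + v] = 1;
    nb[u].push_back(v);
  }
  void remove(int u, int v) {
    present[(size_t)u * n + v] = 0;
    std::vector<int>& L = nb[u];
    for (size_t q = 0; q < L.size(); ++q) {
      if (L[q] == v) {
        L[q] = L.back();
        L.pop_back();
        break;
      }
    }
  }
  // is dst reachable from src? early-exit BFS
  bool reach(int src, int dst) {
    if (src == dst || has(src, dst)) return true;
    std::fill(vis.begin(), vis.end(), 0);
    queue.clear();
    queue.push_back(src);
    vis[src] = 1;
    for (size_t h = 0; h < queue.size(); ++h) {
      const std::vector<int>& L = nb[queue[h]];
      for (size_t q = 0; q < L.size(); ++q) {
        int v = L[q];
        if (v == dst) return true;
        if (!vis[v]) {
          vis[v] = 1;
          queue.push_back(v);
        }
      }
    }
    return false;
  }
};

static inline int rand_int(int m) {
  int r;
  do {
    r = (int)(unif_rand() * m);
  } while (r >= m);
  return r;
}

// Degree-preserving double-edge swaps on an undirected unsigned network.
// Each of `rounds` swap rounds proposes up to `max_tries` candidate swaps;
// weights travel with the endpoint they keep. The guarded variant reverts a
// swap unless the severed endpoint pairs (a,b) and (c,d) remain mutually
// reachable, which is equivalent to the whole graph staying connected when
// the input is connected.
// [[Rcpp::export]]
List cpp_ms_und(NumericMatrix W, int rounds, bool guard, int max_tries) {
  int n = W.nrow();
  std::vector<int> ei, ej;
  std::vector<double> ew;
  Adj adj(n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (W(i, j) != 0) {
        ei.push_back(i);
        ej.push_back(j);
        ew.push_back(W(i, j));
        adj.add(i, j);
        adj.add(j, i);
      }
    }
  }
  int E = (int)ei.size();
  long attempted = 0, effected = 0;
  for (int r = 0; r < rounds; ++r) {
    for (int t = 0; t < max_tries; ++t) {
      ++attempted;
      int e1 = rand_int(E), e2 = rand_int(E);
      if (e1 == e2) continue;
      int a = ei[e1], b = ej[e1], c = ei[e2], d = ej[e2];
      if (a == c || a == d || b == c || b == d) continue;
      // two admissible reconnections, chosen uniformly
      int na1, nb1, na2, nb2;
      if (unif_rand() < 0.5) {
        na1 = a; nb1 = d; na2 = c; nb2 = b;  // {a,d}, {c,b}
      } else {
        na1 = a; nb1 = c; na2 = b; nb2 = d;  // {a,c}, {b,d}
      }
      if (adj.has(na1, nb1) || adj.has(na2, nb2)) continue;
      adj.remove(a, b); adj.remove(b, a);
      adj.remove(c, d); adj.remove(d, c);
      adj.add(na1, nb1); adj.add(nb1, na1);
      adj.add(na2, nb2); adj.add(nb2, na2);
      if (guard && !(adj.reach(a, b) && adj.reach(c, d))) {
        adj.remove(na1, nb1); adj.remove(nb1, na1);
        adj.remove(na2, nb2); adj.remove(nb2, na2);
        adj.add(a, b); adj.add(b, a);
        adj.add(c, d); adj.add(d, c);
        continue;
      }
      ei[e1] = std::min(na1, nb1); ej[e1] = std::max(na1, nb1);
      ei[e2] = std::min(na2, nb2); ej[e2] = std::max(na2, nb2);
      ++effected;
      break;
    }
  }
  NumericMatrix out(n, n);
  for (int e = 0; e < E; ++e) {
    out(ei[e], ej[e]) = ew[e];
    out(ej[e], ei[e]) = ew[e];
  }
  return List::create(_["weights"] = out, _["attempted"] = (double)attempted,
                      _["effected"] = (double)effected);
}

// Directed double-edge swaps: a->b, c->d become a->d, c->b, so in-/out-degree
// sequences and the out-strength sequence are preserved (weights stay in
// their source row). The guard requires b reachable from a and d from c
// after the swap, which preserves strong connectivity.
// [[Rcpp::export]]
List cpp_ms_dir(NumericMatrix W, int rounds, bool guard, int max_tries) {
  int n = W.nrow();
  std::vector<int> ei, ej;
  std::vector<double> ew;
  Adj adj(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (i != j && W(i, j) != 0) {
        ei.push_back(i);
        ej.push_back(j);
        ew.push_back(W(i, j));
        adj.add(i, j);
      }
    }
  }
  int E = (int)ei.size();
  long attempted = 0, effected = 0;
  for (int r = 0; r < rounds; ++r) {
    for (int t = 0; t < max_tries; ++t) {
      ++attempted;
      int e1 = rand_int(E), e2 = rand_int(E);
      if (e1 == e2) continue;
      int a = ei[e1], b = ej[e1], c = ei[e2], d = ej[e2];
      if (a == c || a == d || b == c || b == d) continue;
      if (adj.has(a, d) || adj.has(c, b)) continue;
      adj.remove(a, b);
      adj.remove(c, d);
      adj.add(a, d);
      adj.add(c, b);
      if (guard && !(adj.reach(a, b) && adj.reach(c, d))) {
        adj.remove(a, d);
        adj.remove(c, b);
        adj.add(a, b);
        adj.add(c, d);
        continue;
      }
      ej[e1] = d;
      ej[e2] = b;
      ++effected;
      break;
    }
  }
  NumericMatrix out(n, n);
  for (int e = 0; e < E; ++e) out(ei[e], ej[e]) = ew[e];
  return List::create(_["weights"] = out, _["attempted"] = (double)attempted,
                      _["effected"] = (double)effected);
}

// Signed connection switching: swaps are proposed within a sign class so the
// positive and negative degree sequences are both preserved. No
// connectedness guarantee.
// [[Rcpp::export]]
List cpp_switch_signed(NumericMatrix W, int rounds, int max_tries) {
  int n = W.nrow();
  std::vector<int> ei, ej;
  std::vector<double> ew;
  Adj adj(n);
  std::vector<int> pos_idx, neg_idx;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (W(i, j) != 0) {
        int e = (int)ei.size();
        ei.push_back(i);
        ej.push_back(j);
        ew.push_back(W(i, j));
        adj.add(i, j);
        adj.add(j, i);
        if (W(i, j) > 0) pos_idx.push_back(e); else neg_idx.push_back(e);
      }
    }
  }
  int E = (int)ei.size();
  long attempted = 0, effected = 0;
  for (int r = 0; r < rounds; ++r) {
    for (int t = 0; t < max_tries; ++t) {
      ++attempted;
      int e1 = rand_int(E);
      const std::vector<int>& cls = (ew[e1] > 0) ? pos_idx : neg_idx;
      if ((int)cls.size() < 2) continue;
      int e2 = cls[rand_int((int)cls.size())];
      if (e1 == e2) continue;
      int a = ei[e1], b = ej[e1], c = ei[e2], d = ej[e2];
      if (a == c || a == d || b == c || b == d) continue;
      int na1, nb1, na2, nb2;
      if (unif_rand() < 0.5) {
        na1 = a; nb1 = d; na2 = c; nb2 = b;
      } else {
        na1 = a; nb1 = c; na2 = b; nb2 = d;
      }
      if (adj.has(na1, nb1) || adj.has(na2, nb2)) continue;
      adj.remove(a, b); adj.remove(b, a);
      adj.remove(c, d); adj.remove(d, c);
      adj.add(na1, nb1); adj.add(nb1, na1);
      adj.add(na2, nb2); adj.add(nb2, na2);
      ei[e1] = std::min(na1, nb1); ej[e1] = std::max(na1, nb1);
      ei[e2] = std::min(na2, nb2); ej[e2] = std::max(na2, nb2);
      ++effected;
      break;
    }
  }
  NumericMatrix out(n, n);
  for (int e = 0; e < E; ++e) {
    out(ei[e], ej[e]) = ew[e];
    out(ej[e], ei[e]) = ew[e];
  }
  return List::create(_["weights"] = out, _["attempted"] = (double)attempted,
                      _["effected"] = (double)effected);
}
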