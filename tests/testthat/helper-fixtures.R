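# small deterministic fixtures and brute-force oracles used across tests

net_from_edges <- function(n, edges, directed = FALSE, signed = FALSE) {
  # edges: list of c(i, j, w)
  w <- matrix(0, n, n)
  for (e in edges) {
    w[e[1], e[2]] <- e[3]
    if (!directed) w[e[2], e[1]] <- e[3]
  }
  weighted_network(w, directed = directed, signed = signed)
}

triangle_net <- function(w12 = 1, w13 = 1, w23 = 1) {
  net_from_edges(3, list(c(1, 2, w12), c(1, 3, w13), c(2, 3, w23)))
}

star_net <- function(n_leaves = 3, w = 1) {
  net_from_edges(n_leaves + 1,
                 lapply(seq_len(n_leaves) + 1, function(j) c(1, j, w)))
}

path_net <- function(n, w = 1) {
  net_from_edges(n, lapply(seq_len(n - 1), function(i) c(i, i + 1, w)))
}

complete_net <- function(n, seed = 1) {
  set.seed(seed)
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  w[ut] <- runif(sum(ut), 0.5, 2)
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  weighted_network(w)
}

# random small connected undirected fixture for oracle comparisons
random_small_net <- function(n = 8, density = 0.5, seed = 1) {
  generate_synthetic(n, density, weight_dist = "uniform",
                     dist_params = list(min = 0.1, max = 1),
                     connected = TRUE, seed = seed)
}

# ---- brute-force oracles -------------------------------------------------

oracle_strengths <- function(w) {
  n <- nrow(w)
  s <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) s[i] <- s[i] + w[i, j]
  s
}

oracle_clustering <- function(w) {
  # explicit triple enumeration of Eq-style triangle intensity
  wn <- w / max(w)
  n <- nrow(wn)
  k <- rowSums(wn != 0)
  cc <- numeric(n)
  for (u in seq_len(n)) {
    if (k[u] < 2) next
    acc <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i < j && wn[u, i] > 0 && wn[u, j] > 0 && wn[i, j] > 0) {
        acc <- acc + (wn[u, i] * wn[i, j] * wn[j, u])^(1 / 3)
      }
    }
    cc[u] <- 2 * acc / (k[u] * (k[u] - 1))
  }
  cc
}

oracle_cpl <- function(len) {
  # Floyd-Warshall all-pairs shortest paths on a length matrix
  n <- nrow(len)
  d <- len
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  mean(d[upper.tri(d)])
}

oracle_assortativity <- function(net) {
  # Pearson correlation over edge-endpoint strength pairs, both orientations
  et <- edge_table(net)
  s <- rowSums(net$weights)
  x <- c(s[et$i], s[et$j])
  y <- c(s[et$j], s[et$i])
  stats::cor(x, y)
}

# all set partitions of 1..n (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  grow <- function(labels, max_lab) {
    if (length(labels) == n) {
      out[[length(out) + 1]] <<- labels
      return(invisible())
    }
    for (lab in seq_len(max_lab + 1)) {
      grow(c(labels, lab), max(max_lab, lab))
    }
  }
  grow(integer(0), 0L)
  out
}

oracle_modularity_quality <- function(w, membership) {
  # explicit double loop over ordered node pairs
  n <- nrow(w)
  s <- rowSums(w)
  two_m <- sum(s)
  acc <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (membership[i] == membership[j]) {
      acc <- acc + w[i, j] - s[i] * s[j] / two_m
    }
  }
  acc / two_m
}

oracle_cles <- function(a, b) {
  wins <- 0
  for (x in a) for (y in b) {
    wins <- wins + (x > y) + 0.5 * (x == y)
  }
  100 * wins / (length(a) * length(b))
}

oracle_ks <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}

sorted_weights <- function(net) {
  w <- net$weights
  if (net$directed) sort(w[w != 0]) else sort(w[upper.tri(w) & w != 0])
}
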