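#' Metric configuration
#'
#' @param length_mapping weight-to-length transform used for shortest paths:
#'   `"inverse"` (1/w; any positive weights) or `"neg_log"` (-ln w; weights
#'   must lie in (0, 1], the convention for connectomes rescaled to unit
#'   maximum).
#' @param modularity_runs number of randomized Louvain runs averaged by
#'   [modularity()] (default 250).
#' @param seed integer seed for the randomized runs.
#' @return A `metric_config` list.
#' @export
metric_config <- function(length_mapping = c("inverse", "neg_log"),
                          modularity_runs = 250, seed = NULL) {
  length_mapping <- match.arg(length_mapping)
  stopifnot(modularity_runs >= 1)
  structure(list(length_mapping = length_mapping,
                 modularity_runs = as.integer(modularity_runs), seed = seed),
            class = "metric_config")
}

#' Weighted clustering coefficient
#'
#' Mean triangle intensity around each node,
#' \deqn{C_u = \frac{2}{k_u(k_u - 1)} \sum_{ij} (w_{ui} w_{ij} w_{ju})^{1/3},}
#' with weights first scaled to `[0, 1]` by the largest weight in the network
#' and the sum running over the unordered neighbor pairs that close a
#' triangle through `u`. Nodes with degree below 2 have `C_u = 0`.
#'
#' @inheritParams n_nodes
#' @return A tibble with columns `node` and `clustering`.
#' @export
clustering_coefficient <- function(network) {
  .check_kind(network, directed = FALSE, signed = FALSE,
              what = "clustering_coefficient()")
  w <- network$weights / max(network$weights)
  w3 <- w^(1 / 3)
  cyc3 <- diag(w3 %*% w3 %*% w3)  # ordered pairs: twice the unordered sum
  k <- rowSums(w != 0)
  cc <- ifelse(k < 2, 0, cyc3 / (k * (k - 1)))
  tibble::tibble(node = seq_along(cc), clustering = as.numeric(cc))
}

#' @rdname clustering_coefficient
#' @return `mean_clustering()`: the average of `C_u` over all nodes
#'   (zero-clustering nodes included).
#' @export
mean_clustering <- function(network) {
  mean(clustering_coefficient(network)$clustering)
}

#' Map edge weights to lengths
#'
#' A monotonically decreasing transform from edge weight (importance) to edge
#' length (traversal cost): `-log(w)` (`neg_log`, for weights in (0, 1]) or
#' `1/w` (`inverse`, for any positive weights). Absent edges get infinite
#' length; the diagonal is zero.
#'
#' @inheritParams n_nodes
#' @param mapping `"neg_log"` or `"inverse"`.
#' @return An n-by-n matrix of lengths.
#' @export
weight_to_length <- function(network, mapping = c("inverse", "neg_log")) {
  mapping <- match.arg(mapping)
  .check_kind(network, signed = FALSE, what = "weight_to_length()")
  w <- network$weights
  present <- w != 0
  if (mapping == "neg_log" && any(w[present] > 1)) {
    stop("neg_log length mapping requires weights in (0, 1]; ",
         "rescale the weights (e.g. divide by the maximum) first",
         call. = FALSE)
  }
  len <- matrix(Inf, nrow(w), ncol(w))
  len[present] <- if (mapping == "neg_log") -log(w[present]) else 1 / w[present]
  diag(len) <- 0
  len
}

#' Weighted characteristic path length
#'
#' Shortest path lengths (Dijkstra) on the length-transformed network,
#' averaged over all pairs of distinct nodes.
#'
#' @inheritParams n_nodes
#' @param config a [metric_config()]; only `length_mapping` is used.
#' @return The mean shortest path length (scalar).
#' @export
characteristic_path_length <- function(network, config = metric_config()) {
  .check_kind(network, directed = FALSE, signed = FALSE,
              what = "characteristic_path_length()")
  len <- weight_to_length(network, config$length_mapping)
  et <- edge_table(network)
  g <- igraph::graph_from_data_frame(
    data.frame(from = et$i, to = et$j),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n_nodes(network)))
  )
  d <- igraph::distances(g, weights = len[cbind(et$i, et$j)],
                         algorithm = "dijkstra")
  off <- d[upper.tri(d)]
  if (any(!is.finite(off))) {
    comp <- igraph::components(.as_igraph_binary(network))
    stop("network is disconnected (", comp$no, " components; smallest has ",
         min(comp$csize), " node(s)): characteristic path length is undefined",
         call. = FALSE)
  }
  mean(off)
}

#' Strength assortativity coefficient
#'
#' Pearson correlation between the strengths of connected nodes,
#' \deqn{r = \frac{M^{-1}\sum_i s_i t_i - [M^{-1}\sum_i \tfrac12 (s_i+t_i)]^2}
#'  {M^{-1}\sum_i \tfrac12 (s_i^2+t_i^2) - [M^{-1}\sum_i \tfrac12 (s_i+t_i)]^2},}
#' where \eqn{s_i, t_i} are the strengths at the two ends of the i-th edge
#' and each undirected edge contributes once (the symmetric form makes the
#' orientation irrelevant).
#'
#' @inheritParams n_nodes
#' @return Scalar in `[-1, 1]`.
#' @export
assortativity <- function(network) {
  .check_kind(network, directed = FALSE, signed = FALSE,
              what = "assortativity()")
  et <- edge_table(network)
  if (nrow(et) < 2) stop("assortativity needs at least 2 edges", call. = FALSE)
  s <- strengths(network)$strength
  si <- s[et$i]
  ti <- s[et$j]
  M <- nrow(et)
  mu <- mean((si + ti) / 2)
  num <- mean(si * ti) - mu^2
  den <- mean((si^2 + ti^2) / 2) - mu^2
  if (den <= .Machine$double.eps * max(1, mu^2)) {
    stop("degenerate strength variance: all edge-endpoint strengths are equal",
         call. = FALSE)
  }
  num / den
}

#' Modularity via repeated Louvain maximization
#'
#' Runs Louvain community detection `modularity_runs` times with a randomized
#' node visiting order (the node order is shuffled per run), evaluates each
#' returned partition with [modularity_quality()] and reports the average
#' optimized modularity.
#'
#' @inheritParams n_nodes
#' @param config a [metric_config()]; uses `modularity_runs` and `seed`.
#' @return A list with `mean` (average optimized Q) and `q_runs` (per-run Q).
#' @export
modularity <- function(network, config = metric_config()) {
  .check_kind(network, directed = FALSE, signed = FALSE, what = "modularity()")
  runs <- config$modularity_runs
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- n_nodes(network)
  q <- numeric(runs)
  for (r in seq_len(runs)) {
    perm <- sample.int(n)  # randomized visiting order via node relabeling
    wp <- network$weights[perm, perm]
    g <- igraph::graph_from_adjacency_matrix(wp, mode = "undirected",
                                             weighted = TRUE)
    memb_p <- igraph::membership(igraph::cluster_louvain(g))
    memb <- integer(n)
    memb[perm] <- as.integer(memb_p)
    q[r] <- modularity_quality(network, memb)
  }
  list(mean = mean(q), q_runs = q)
}

#' Modularity quality of a partition
#'
#' Evaluates
#' \deqn{Q = \frac{1}{2m}\sum_{ij}\left(w_{ij} - \frac{s_i s_j}{2m}\right)
#'   \delta(c_i, c_j)}
#' for a given community assignment, where `m` is the total edge weight.
#' The all-in-one-community partition scores exactly zero.
#'
#' @inheritParams n_nodes
#' @param membership integer community labels, one per node.
#' @return Scalar Q.
#' @export
modularity_quality <- function(network, membership) {
  .check_kind(network, directed = FALSE, signed = FALSE,
              what = "modularity_quality()")
  w <- network$weights
  stopifnot(length(membership) == nrow(w))
  two_m <- sum(w)
  # community-wise grouping of the double sum; W_c and S_c reduce to the
  # identical full-matrix sum for the single-community partition, which
  # therefore telescopes to exactly zero
  q <- 0
  for (cm in unique(membership)) {
    idx <- membership == cm
    w_c <- sum(w[idx, idx, drop = FALSE])
    s_c <- sum(w[idx, , drop = FALSE])
    q <- q + w_c / two_m - (s_c / two_m)^2
  }
  q
}
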