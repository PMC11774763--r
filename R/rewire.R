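#' Degree-preserving randomization (Maslov-Sneppen rewiring)
#'
#' Randomly swaps pairs of edges, disrupting the topology of the network while
#' preserving its size, density and degree sequence. Weights are carried with
#' their respective edges, so the weight multiset is conserved exactly but the
#' strength sequence is not. `maslov_sneppen_und()` handles undirected
#' unsigned networks, optionally guaranteeing that the rewired network remains
#' connected; `maslov_sneppen_dir()` handles directed networks, preserving the
#' in- and out-degree sequences and (because weights stay in their source row)
#' the out-strength sequence, with an optional strong-connectivity guard;
#' `switch_signed()` handles undirected signed networks by switching
#' connections within each sign class, preserving the positive and negative
#' degree sequences (connectedness is not guaranteed).
#'
#' Each swap round proposes up to ten candidate edge pairs; proposals that
#' would create a self-loop or multi-edge, or (for the guarded variants)
#' disconnect the graph, are rejected. Rejections count toward
#' `swaps_attempted` but not `swaps_effected`.
#'
#' @param network a [weighted_network()] of the matching kind.
#' @param swaps_per_edge target number of swap rounds per logical edge
#'   (default 10, i.e. approximately ten swaps per edge).
#' @param preserve_connectedness keep the rewired network connected
#'   (undirected) or strongly connected (directed). Requires a connected
#'   input.
#' @param seed integer seed for the swap sequence.
#' @return A `rewire_result`: list with elements `network`
#'   (the rewired [weighted_network()]), `swaps_attempted` and
#'   `swaps_effected`.
#' @examples
#' net <- generate_synthetic(30, 0.2, seed = 1)
#' rw <- maslov_sneppen_und(net, seed = 2)
#' all.equal(sort(net$weights), sort(rw$network$weights))
#' @export
maslov_sneppen_und <- function(network, swaps_per_edge = 10,
                               preserve_connectedness = TRUE, seed = NULL) {
  .check_kind(network, directed = FALSE, signed = FALSE,
              what = "maslov_sneppen_und()")
  if (preserve_connectedness && !is_connected(network)) {
    stop("input network is disconnected but `preserve_connectedness = TRUE`",
         call. = FALSE)
  }
  E <- edge_count(network)
  if (E < 4) {
    warning("fewer than 4 edges: no valid swap exists, returning the input unchanged")
    return(.rewire_result(network, 0, 0))
  }
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_ms_und(network$weights, round(swaps_per_edge * E),
                    preserve_connectedness, 10L)
  .rewire_result(
    weighted_network(res$weights, directed = FALSE, signed = FALSE,
                     labels = network$labels),
    res$attempted, res$effected
  )
}

#' @rdname maslov_sneppen_und
#' @export
maslov_sneppen_dir <- function(network, swaps_per_edge = 10,
                               preserve_connectedness = TRUE, seed = NULL) {
  .check_kind(network, directed = TRUE, signed = FALSE,
              what = "maslov_sneppen_dir()")
  if (preserve_connectedness && !is_connected(network)) {
    stop("input network is not strongly connected but `preserve_connectedness = TRUE`",
         call. = FALSE)
  }
  E <- edge_count(network)
  if (E < 4) {
    warning("fewer than 4 edges: no valid swap exists, returning the input unchanged")
    return(.rewire_result(network, 0, 0))
  }
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_ms_dir(network$weights, round(swaps_per_edge * E),
                    preserve_connectedness, 10L)
  .rewire_result(
    weighted_network(res$weights, directed = TRUE, signed = FALSE,
                     labels = network$labels),
    res$attempted, res$effected
  )
}

#' @rdname maslov_sneppen_und
#' @export
switch_signed <- function(network, swaps_per_edge = 10, seed = NULL) {
  .check_kind(network, directed = FALSE, signed = TRUE,
              what = "switch_signed()")
  E <- edge_count(network)
  if (E < 4) {
    warning("fewer than 4 edges: no valid swap exists, returning the input unchanged")
    return(.rewire_result(network, 0, 0))
  }
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_switch_signed(network$weights, round(swaps_per_edge * E), 10L)
  .rewire_result(
    weighted_network(res$weights, directed = FALSE, signed = TRUE,
                     labels = network$labels),
    res$attempted, res$effected
  )
}

.rewire_result <- function(network, attempted, effected) {
  stopifnot(effected <= attempted)
  structure(list(network = network,
                 swaps_attempted = as.numeric(attempted),
                 swaps_effected = as.numeric(effected)),
            class = "rewire_result")
}

#' @export
print.rewire_result <- function(x, ...) {
  cat(sprintf("<rewire_result: %s of %s proposed swaps effected>\n",
              format(x$swaps_effected), format(x$swaps_attempted)))
  print(x$network)
  invisible(x)
}

#' Is a network connected?
#'
#' Undirected networks are connected when the binary graph has a single
#' component; directed networks must be strongly connected (every node
#' reachable from every other along edge directions), so that no node is
#' disconnected under reachability in either direction.
#'
#' @inheritParams n_nodes
#' @return Logical scalar.
#' @export
is_connected <- function(network) {
  stopifnot(is_weighted_network(network))
  g <- .as_igraph_binary(network)
  mode <- if (network$directed) "strong" else "weak"
  igraph::components(g, mode = mode)$no == 1
}

.as_igraph_binary <- function(network) {
  igraph::graph_from_adjacency_matrix(
    (network$weights != 0) * 1,
    mode = if (network$directed) "directed" else "undirected"
  )
}
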