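#' Weighted network objects
#'
#' A `weighted_network` wraps a square numeric weight matrix together with
#' directedness and signedness flags. It is the universal currency of the
#' package: every randomizer, metric and benchmark takes and/or returns one.
#'
#' Invariants enforced at construction:
#' * the diagonal is exactly zero (no self-loops),
#' * undirected networks have symmetric matrices,
#' * unsigned networks have nonnegative entries,
#' * all entries are finite and at least one is nonzero.
#'
#' An exact zero encodes "no edge"; signed networks therefore cannot carry
#' zero-weight edges (the usual adjacency-matrix convention).
#'
#' @param weights square numeric matrix of edge weights.
#' @param directed logical; is the network directed?
#' @param signed logical; may the network carry negative weights?
#' @param labels optional character vector of node names (length `n`).
#' @return An object of class `weighted_network`.
#' @examples
#' w <- matrix(0, 3, 3)
#' w[1, 2] <- w[2, 1] <- 2
#' w[2, 3] <- w[3, 2] <- 3
#' net <- weighted_network(w)
#' strengths(net)
#' @export
weighted_network <- function(weights, directed = FALSE, signed = FALSE,
                             labels = NULL) {
  if (!is.matrix(weights) || !is.numeric(weights)) {
    stop("`weights` must be a numeric matrix", call. = FALSE)
  }
  n <- nrow(weights)
  if (ncol(weights) != n) {
    stop("`weights` must be square; got ", n, " x ", ncol(weights),
         call. = FALSE)
  }
  if (any(!is.finite(weights))) {
    stop("`weights` contains NaN or infinite entries", call. = FALSE)
  }
  if (any(diag(weights) != 0)) {
    stop("nonzero diagonal: self-loops are not allowed", call. = FALSE)
  }
  if (!directed && !isTRUE(all(weights == t(weights)))) {
    stop("matrix is not symmetric but `directed = FALSE`", call. = FALSE)
  }
  if (!signed && any(weights < 0)) {
    stop("negative weight found but `signed = FALSE`", call. = FALSE)
  }
  if (all(weights == 0)) {
    stop("network has no edges (all weights zero)", call. = FALSE)
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != n) {
      stop("`labels` must have length ", n, call. = FALSE)
    }
  }
  dimnames(weights) <- NULL
  structure(
    list(weights = weights, directed = isTRUE(directed),
         signed = isTRUE(signed), labels = labels),
    class = "weighted_network"
  )
}

#' @export
print.weighted_network <- function(x, ...) {
  kind <- if (x$signed) "signed" else if (x$directed) "directed" else "undirected"
  cat(sprintf("<weighted_network: %d nodes, %d edges, %s>\n",
              n_nodes(x), edge_count(x), kind))
  invisible(x)
}

#' @rdname weighted_network
#' @param x object to test or coerce.
#' @export
is_weighted_network <- function(x) inherits(x, "weighted_network")

#' Number of nodes in a network
#' @param network a [weighted_network()].
#' @return Integer node count.
#' @export
n_nodes <- function(network) {
  stopifnot(is_weighted_network(network))
  nrow(network$weights)
}

#' Number of logical edges in a network
#'
#' Undirected edges are counted once (upper triangle); directed edges are
#' ordered pairs.
#' @inheritParams n_nodes
#' @return Integer edge count.
#' @export
edge_count <- function(network) {
  stopifnot(is_weighted_network(network))
  w <- network$weights
  if (network$directed) sum(w != 0) else sum(w[upper.tri(w)] != 0)
}

#' Binary edge density
#' @inheritParams n_nodes
#' @return Fraction of possible (off-diagonal) edges present.
#' @export
network_density <- function(network) {
  n <- n_nodes(network)
  possible <- if (network$directed) n * (n - 1) else n * (n - 1) / 2
  edge_count(network) / possible
}

## internal: plain-vector strengths/degrees used throughout the package
.strength_vec <- function(w) rowSums(w)

.check_kind <- function(network, directed = NULL, signed = NULL, what = "this operation") {
  stopifnot(is_weighted_network(network))
  if (!is.null(directed) && network$directed != directed) {
    stop(what, " requires a ", if (directed) "directed" else "undirected",
         " network", call. = FALSE)
  }
  if (!is.null(signed) && network$signed != signed) {
    stop(what, " requires a", if (signed) " signed" else "n unsigned",
         " network", call. = FALSE)
  }
  invisible(network)
}

#' Node strength sequence
#'
#' Strength (weighted degree) is the sum of edge weights incident on a node.
#' The populated columns follow the network kind: undirected unsigned networks
#' get `strength`; directed networks get `s_in` (column sums) and `s_out`
#' (row sums); signed networks get `s_pos` (sum of positive incident weights)
#' and `s_neg` (sum of the magnitudes of negative incident weights).
#'
#' @inheritParams n_nodes
#' @return A tibble with one row per node.
#' @export
strengths <- function(network) {
  stopifnot(is_weighted_network(network))
  w <- network$weights
  node <- seq_len(nrow(w))
  if (network$signed) {
    tibble::tibble(node = node,
                   s_pos = rowSums(w * (w > 0)),
                   s_neg = rowSums(-w * (w < 0)))
  } else if (network$directed) {
    tibble::tibble(node = node, s_in = colSums(w), s_out = rowSums(w))
  } else {
    tibble::tibble(node = node, strength = rowSums(w))
  }
}

#' Node degree sequence
#'
#' Degree is the number of edges incident on a node, counted per sign class
#' for signed networks and per direction for directed networks.
#'
#' @inheritParams n_nodes
#' @return A tibble with one row per node.
#' @export
degrees <- function(network) {
  stopifnot(is_weighted_network(network))
  w <- network$weights
  node <- seq_len(nrow(w))
  if (network$signed) {
    tibble::tibble(node = node,
                   k_pos = rowSums(w > 0),
                   k_neg = rowSums(w < 0))
  } else if (network$directed) {
    tibble::tibble(node = node, k_in = colSums(w != 0), k_out = rowSums(w != 0))
  } else {
    tibble::tibble(node = node, degree = rowSums(w != 0))
  }
}

#' Edge table of a network
#'
#' Each logical edge on one row: undirected edges appear once with `i < j`,
#' directed edges as ordered (source, target) pairs.
#'
#' @inheritParams n_nodes
#' @return A tibble with columns `i`, `j`, `weight`.
#' @export
edge_table <- function(network) {
  stopifnot(is_weighted_network(network))
  w <- network$weights
  idx <- if (network$directed) which(w != 0, arr.ind = TRUE) else {
    m <- upper.tri(w) & w != 0
    which(m, arr.ind = TRUE)
  }
  tibble::tibble(i = as.integer(idx[, 1]), j = as.integer(idx[, 2]),
                 weight = w[idx])
}
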