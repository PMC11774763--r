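#' Generate a synthetic weighted network
#'
#' Produces connectome-like synthetic fixtures: a random binary topology at a
#' requested density with i.i.d. edge weights from a uniform, log-normal or
#' Pareto distribution. Heavy-tailed weights (log-normal by default) emulate
#' the right-skewed weight distributions typical of structural connectivity
#' data.
#'
#' Connectivity, when requested, is enforced constructively: undirected graphs
#' are seeded with a uniform random spanning tree (random Pruefer sequence)
#' and directed graphs with a random Hamiltonian cycle (guaranteeing strong
#' connectivity), after which the remaining edges are drawn uniformly without
#' replacement from the unused node pairs.
#'
#' @param n number of nodes.
#' @param density fraction in (0, 1] of possible edges present.
#' @param weight_dist `"lognormal"`, `"uniform"` or `"pareto"`.
#' @param dist_params named list of distribution parameters. Defaults:
#'   log-normal `meanlog = 0, sdlog = 1`; uniform `min = 0, max = 1`
#'   (shifted away from exact zero); Pareto `xmin = 1, alpha = 2`.
#' @param directed,signed network kind flags.
#' @param neg_fraction fraction of edges given negative weights when
#'   `signed = TRUE` (default 0.3).
#' @param connected enforce a connected (directed: strongly connected) binary
#'   topology. Defaults to `TRUE` for unsigned networks.
#' @param seed integer seed; the generator is deterministic given the seed.
#' @return A [weighted_network()].
#' @examples
#' net <- generate_synthetic(30, 0.2, seed = 1)
#' network_density(net)
#' @export
generate_synthetic <- function(n, density,
                               weight_dist = c("lognormal", "uniform", "pareto"),
                               dist_params = list(),
                               directed = FALSE, signed = FALSE,
                               neg_fraction = 0.3,
                               connected = !signed,
                               seed = NULL) {
  weight_dist <- match.arg(weight_dist)
  stopifnot(n >= 2, density > 0, density <= 1)
  if (!is.null(seed)) set.seed(seed)
  possible <- if (directed) n * (n - 1) else n * (n - 1) / 2
  m <- max(1L, round(density * possible))
  min_m <- if (directed) n else n - 1L
  if (connected && m < min_m) {
    stop("density too low to admit a connected graph: need at least ",
         min_m, " edges, requested density gives ", m, call. = FALSE)
  }

  pairs <- .sample_topology(n, m, directed, connected)
  w <- .draw_weights(m, weight_dist, dist_params)
  if (signed) {
    n_neg <- round(neg_fraction * m)
    if (n_neg > 0) {
      neg_idx <- sample.int(m, n_neg)
      w[neg_idx] <- -w[neg_idx]
    }
  }
  mat <- matrix(0, n, n)
  mat[cbind(pairs[, 1], pairs[, 2])] <- w
  if (!directed) mat[cbind(pairs[, 2], pairs[, 1])] <- w
  weighted_network(mat, directed = directed, signed = signed)
}

.draw_weights <- function(m, dist, params) {
  p <- function(name, default) if (is.null(params[[name]])) default else params[[name]]
  switch(dist,
    lognormal = stats::rlnorm(m, meanlog = p("meanlog", 0), sdlog = p("sdlog", 1)),
    uniform = {
      lo <- p("min", 0); hi <- p("max", 1)
      u <- stats::runif(m, lo, hi)
      # exact zero means "no edge": nudge any zero draw into the open interval
      u[u == lo & lo == 0] <- (hi - lo) * .Machine$double.eps
      u
    },
    pareto = {
      xmin <- p("xmin", 1); alpha <- p("alpha", 2)
      xmin / stats::runif(m)^(1 / alpha)
    }
  )
}

# Binary topology as an m x 2 matrix of node pairs (i, j); undirected pairs
# have i < j. Pair indices are sampled without replacement so the realized
# density equals the request exactly.
.sample_topology <- function(n, m, directed, connected) {
  if (!connected) {
    idx <- sample.int(if (directed) n * (n - 1) else n * (n - 1) / 2, m)
    return(.pairs_from_index(idx, n, directed))
  }
  if (directed) {
    perm <- sample.int(n)
    seedp <- cbind(perm, c(perm[-1], perm[1]))  # Hamiltonian cycle
  } else {
    seedp <- .random_spanning_tree(n)
  }
  seed_idx <- .index_from_pairs(seedp, n, directed)
  all_m <- if (directed) n * (n - 1) else n * (n - 1) / 2
  rest <- setdiff(seq_len(all_m), seed_idx)
  extra <- m - nrow(seedp)
  if (extra < 0) stop("requested density below the connectivity seed size",
                      call. = FALSE)
  idx <- c(seed_idx, sample(rest, extra))
  .pairs_from_index(idx, n, directed)
}

# uniform random labeled tree via a random Pruefer sequence
.random_spanning_tree <- function(n) {
  if (n == 2) return(cbind(1L, 2L))
  prufer <- sample.int(n, n - 2, replace = TRUE)
  degree <- rep(1L, n)
  for (v in prufer) degree[v] <- degree[v] + 1L
  edges <- matrix(0L, n - 1, 2)
  ptr <- 1L
  leaves <- sort(which(degree == 1L))
  for (i in seq_along(prufer)) {
    leaf <- leaves[1]
    v <- prufer[i]
    edges[ptr, ] <- c(min(leaf, v), max(leaf, v)); ptr <- ptr + 1L
    leaves <- leaves[-1]
    degree[leaf] <- 0L  # consumed
    degree[v] <- degree[v] - 1L
    if (degree[v] == 1L) leaves <- sort(c(leaves, v))
  }
  last <- which(degree == 1L)
  edges[ptr, ] <- c(min(last), max(last))
  edges
}

# linear indexing of off-diagonal pairs (directed) / upper-triangle pairs
.pairs_from_index <- function(idx, n, directed) {
  if (directed) {
    i <- (idx - 1L) %/% (n - 1L) + 1L
    r <- (idx - 1L) %% (n - 1L) + 1L
    j <- ifelse(r >= i, r + 1L, r)
    cbind(as.integer(i), as.integer(j))
  } else {
    ut <- which(upper.tri(matrix(0, n, n)))
    pos <- ut[idx]
    j <- (pos - 1L) %/% n + 1L
    i <- (pos - 1L) %% n + 1L
    cbind(as.integer(i), as.integer(j))
  }
}

.index_from_pairs <- function(pairs, n, directed) {
  i <- pairs[, 1]; j <- pairs[, 2]
  if (directed) {
    r <- ifelse(j > i, j - 1L, j)
    (i - 1L) * (n - 1L) + r
  } else {
    ii <- pmin(i, j); jj <- pmax(i, j)
    pos <- (jj - 1L) * n + ii
    ut <- which(upper.tri(matrix(0, n, n)))
    match(pos, ut)
  }
}
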