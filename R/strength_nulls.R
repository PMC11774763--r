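#' Annealing schedule configuration
#'
#' Defaults follow the standard schedule for strength sequence-preserving
#' annealing: 100 stages of 10,000 weight-pair permutations, starting at
#' temperature 1,000, halved at each stage. Setting `energy_threshold`
#' switches to the thresholded stopping rule: the run halts at the first stage
#' end where the energy falls to the threshold or below, up to `max_stages`
#' stages (the participant-level convention uses `energy_threshold = 1e-4`
#' and `max_stages = 1000`).
#'
#' @param n_stages number of annealing stages when no threshold is set.
#' @param iters_per_stage weight-swap proposals per stage.
#' @param T0 initial temperature (> 0).
#' @param cooling_factor multiplier applied to the temperature at each stage
#'   end; must lie in (0, 1).
#' @param energy_threshold optional energy stopping threshold (> 0).
#' @param max_stages stage cap used when `energy_threshold` is set.
#' @param objective one of `"und"`, `"dir"`, `"dir_alt"`, `"signed"`, or
#'   `NULL` to infer it from the network kind.
#' @param seed integer seed for the proposal/acceptance stream.
#' @return An `annealing_config` list.
#' @export
annealing_config <- function(n_stages = 100, iters_per_stage = 10000,
                             T0 = 1000, cooling_factor = 0.5,
                             energy_threshold = NULL, max_stages = 1000,
                             objective = NULL, seed = NULL) {
  stopifnot(n_stages >= 1, iters_per_stage >= 1, T0 > 0,
            cooling_factor > 0, cooling_factor < 1, max_stages >= 1)
  if (!is.null(energy_threshold) && energy_threshold <= 0) {
    stop("`energy_threshold` must be positive when set", call. = FALSE)
  }
  if (!is.null(objective)) {
    objective <- match.arg(objective, c("und", "dir", "dir_alt", "signed"))
  }
  structure(list(n_stages = as.integer(n_stages),
                 iters_per_stage = as.integer(iters_per_stage),
                 T0 = T0, cooling_factor = cooling_factor,
                 energy_threshold = energy_threshold,
                 max_stages = as.integer(max_stages),
                 objective = objective, seed = seed),
            class = "annealing_config")
}

#' Mean squared error between strength sequences
#'
#' The annealing energy: the mean squared error between a target (empirical)
#' and a current (randomized) strength sequence,
#' \deqn{E = \frac{1}{n}\sum_{i=1}^n (s_i - \hat s_i)^2.}
#' For the directed objective the in- and out-strength errors are computed
#' separately and summed; for the signed objective the positive- and
#' negative-strength errors are summed; the `dir_alt` objective uses the
#' in-strength error only.
#'
#' @param s_target,s_current strength tables as returned by [strengths()]
#'   (matching columns and lengths).
#' @param objective `NULL` to infer from the populated columns, or
#'   `"dir_alt"` to restrict a directed pair to the in-strength error.
#' @return A nonnegative scalar.
#' @examples
#' mse <- mse_energy(
#'   tibble::tibble(node = 1:3, strength = c(3, 1, 2)),
#'   tibble::tibble(node = 1:3, strength = c(1, 3, 2))
#' )
#' mse  # 8/3
#' @export
mse_energy <- function(s_target, s_current, objective = NULL) {
  if (nrow(s_target) != nrow(s_current)) {
    stop("strength sequences have different lengths", call. = FALSE)
  }
  n <- nrow(s_target)
  mse <- function(col) {
    if (is.null(s_target[[col]]) || is.null(s_current[[col]])) {
      stop("strength column `", col, "` missing for this objective",
           call. = FALSE)
    }
    mean((s_target[[col]] - s_current[[col]])^2)
  }
  has <- function(col) !is.null(s_target[[col]]) && !is.null(s_current[[col]])
  if (is.null(objective)) {
    objective <- if (has("strength")) "und"
      else if (has("s_pos")) "signed"
      else if (has("s_in")) "dir"
      else stop("unrecognized strength table columns", call. = FALSE)
  }
  switch(objective,
    und = mse("strength"),
    dir = mse("s_in") + mse("s_out"),
    signed = mse("s_pos") + mse("s_neg"),
    dir_alt = mse("s_in"),
    stop("unknown objective: ", objective, call. = FALSE)
  )
}

#' Metropolis acceptance criterion
#'
#' A proposed reconfiguration with energy `E_prime` replacing one with energy
#' `E` at temperature `T` is accepted if it lowers the energy, or with
#' probability `exp(-(E_prime - E)/T)` otherwise, i.e. when the uniform
#' variate `u` satisfies `u < exp(-(E_prime - E)/T)`.
#'
#' @param E,E_prime current and proposed energies.
#' @param T temperature (> 0).
#' @param u uniform variate in `[0, 1)`.
#' @return Logical: accept the proposal?
#' @export
metropolis_accept <- function(E, E_prime, T, u) {
  if (T <= 0) stop("temperature must be positive", call. = FALSE)
  if (E_prime < E) TRUE else u < exp(-(E_prime - E) / T)
}

#' Rank-matched strength-preserving weight reassignment (Rubinov-Sporns)
#'
#' Reassigns the reference network's weights onto a degree-matched rewired
#' scaffold so as to approximate the reference strength sequence. Starting
#' from an all-zero assignment, the remaining original weights are ranked by
#' magnitude and the unassigned scaffold edges by expected magnitude
#' \eqn{\hat e_{ij} \propto (s_i - \sum_u \hat A_{iu})(s_j - \sum_u \hat
#' A_{ju})}; a random unassigned edge then receives the original weight of
#' matching rank, residual strengths are updated, and the procedure repeats
#' until every edge is assigned. For unsigned networks the procedure runs on
#' all edges at once; for signed networks it is applied separately to the
#' positive and negative edges.
#'
#' @param reference the empirical [weighted_network()].
#' @param scaffold a degree-matched rewired version of `reference` (e.g. from
#'   [maslov_sneppen_und()] or [switch_signed()]).
#' @param seed integer seed for edge selection and tie-breaking.
#' @return A [weighted_network()] with the scaffold's topology and the
#'   reference's exact weight multiset.
#' @export
rubinov_sporns <- function(reference, scaffold, seed = NULL) {
  .check_scaffold(reference, scaffold, directed_ok = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- n_nodes(reference)
  out <- matrix(0, n, n)
  if (reference$signed) {
    st <- strengths(reference)
    for (sign_class in c("pos", "neg")) {
      sgn <- if (sign_class == "pos") 1 else -1
      ref_w <- reference$weights[upper.tri(reference$weights)]
      ref_w <- ref_w[sgn * ref_w > 0]
      mask <- upper.tri(scaffold$weights) & (sgn * scaffold$weights > 0)
      idx <- which(mask, arr.ind = TRUE)
      if (nrow(idx) == 0) next
      s_tgt <- if (sign_class == "pos") st$s_pos else st$s_neg
      placed <- cpp_rs_place(n, idx[, 1] - 1L, idx[, 2] - 1L,
                             sort(abs(ref_w), decreasing = TRUE),
                             s_tgt, stats::runif(nrow(idx)))
      out[idx] <- sgn * placed
    }
  } else {
    et <- edge_table(scaffold)
    ref_w <- sort(reference$weights[upper.tri(reference$weights)][
      reference$weights[upper.tri(reference$weights)] != 0],
      decreasing = TRUE)
    s_tgt <- strengths(reference)$strength
    placed <- cpp_rs_place(n, et$i - 1L, et$j - 1L, ref_w, s_tgt,
                           stats::runif(nrow(et)))
    out[cbind(et$i, et$j)] <- placed
  }
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  weighted_network(out, directed = FALSE, signed = reference$signed,
                   labels = reference$labels)
}

# reference R implementation of the rank-matching placement; used as the
# oracle for the C++ path in the tests. Consumes one uniform variate per
# pick (as the compiled path does), so the two agree exactly under a shared
# seed.
.rs_place_reference <- function(n, ei, ej, w_desc, s_target, tiekey) {
  resid <- s_target
  remaining <- w_desc
  unassigned <- seq_along(ei)
  out <- numeric(length(ei))
  while (length(unassigned) > 0) {
    m <- length(unassigned)
    pos <- floor(stats::runif(1) * m) + 1
    pick <- unassigned[pos]
    ehat <- resid[ei[unassigned]] * resid[ej[unassigned]]
    ord <- unassigned[order(-ehat, -tiekey[unassigned])]
    rank <- match(pick, ord)
    out[pick] <- remaining[rank]
    remaining <- remaining[-rank]
    resid[ei[pick]] <- resid[ei[pick]] - out[pick]
    resid[ej[pick]] <- resid[ej[pick]] - out[pick]
    # drop by swap-with-last, matching the compiled path's pick order
    unassigned[pos] <- unassigned[m]
    unassigned <- unassigned[-m]
  }
  out
}

.check_scaffold <- function(reference, scaffold, directed_ok = TRUE) {
  stopifnot(is_weighted_network(reference), is_weighted_network(scaffold))
  if (reference$directed != scaffold$directed ||
      reference$signed != scaffold$signed) {
    stop("reference and scaffold have different network kinds", call. = FALSE)
  }
  if (!directed_ok && reference$directed) {
    stop("this operation supports undirected networks only", call. = FALSE)
  }
  if (n_nodes(reference) != n_nodes(scaffold)) {
    stop("reference and scaffold have different sizes", call. = FALSE)
  }
  dr <- degrees(reference)
  ds <- degrees(scaffold)
  if (!isTRUE(all.equal(as.data.frame(dr), as.data.frame(ds)))) {
    stop("scaffold degree sequence does not match the reference", call. = FALSE)
  }
  wr <- sort(.weight_multiset(reference))
  ws <- sort(.weight_multiset(scaffold))
  if (length(wr) != length(ws) || !all(wr == ws)) {
    stop("scaffold weight multiset does not match the reference", call. = FALSE)
  }
  invisible(TRUE)
}

.weight_multiset <- function(network) {
  w <- network$weights
  v <- if (network$directed) w[w != 0] else w[upper.tri(w) & w != 0]
  as.numeric(v)
}

#' Strength sequence-preserving randomization by simulated annealing
#'
#' Permutes the weights of a rewired scaffold so that its strength sequence
#' approximates the reference network's. At each iteration two randomly
#' selected edge weights are swapped; the swap is kept if it lowers the
#' energy (the mean squared error between target and current strength
#' sequences, see [mse_energy()]) or if it meets the probabilistic Metropolis
#' criterion. The temperature is multiplied by the cooling factor at each
#' stage end. The topology and weight multiset of the scaffold are untouched;
#' only the weight-to-edge assignment changes.
#'
#' For directed networks the objective is the sum of the in- and out-strength
#' errors and any two edge weights may be swapped.
#' [simulated_annealing_dir_alt()] instead picks a random node and swaps two
#' weights among its outgoing connections only, preserving the out-strength
#' sequence exactly while minimizing the in-strength error. For signed
#' networks weight pairs are swapped within a sign class, so the positive and
#' negative degree sequences stay exact while both strength sequences are
#' approximated.
#'
#' @inheritParams rubinov_sporns
#' @param config an [annealing_config()].
#' @return A list with elements `network` (the annealed [weighted_network()])
#'   and `trace` (an `energy_trace` with `stage_energies`,
#'   `accepted_per_stage`, `initial_energy`, `final_energy`, `best_energy`,
#'   `stages_run`).
#' @examples
#' ref <- generate_synthetic(30, 0.2, seed = 1)
#' sc <- maslov_sneppen_und(ref, seed = 2)$network
#' fit <- simulated_annealing(ref, sc, annealing_config(n_stages = 20, seed = 3))
#' fit$trace$final_energy <= fit$trace$initial_energy
#' @export
simulated_annealing <- function(reference, scaffold, config = annealing_config()) {
  stopifnot(inherits(config, "annealing_config"))
  .check_scaffold(reference, scaffold)
  objective <- config$objective
  if (is.null(objective)) {
    objective <- if (reference$signed) "signed"
      else if (reference$directed) "dir" else "und"
  }
  if (objective == "dir_alt" && !reference$directed) {
    stop("`dir_alt` objective requires a directed network", call. = FALSE)
  }
  if (objective %in% c("dir", "dir_alt") && !reference$directed ||
      objective == "und" && (reference$directed || reference$signed) ||
      objective == "signed" && !reference$signed) {
    stop("objective `", objective, "` does not match the network kind",
         call. = FALSE)
  }
  .run_sa(reference, scaffold, config, objective)
}

#' @rdname simulated_annealing
#' @export
simulated_annealing_dir_alt <- function(reference, scaffold,
                                        config = annealing_config()) {
  stopifnot(inherits(config, "annealing_config"))
  .check_kind(reference, directed = TRUE, signed = FALSE,
              what = "simulated_annealing_dir_alt()")
  .check_scaffold(reference, scaffold)
  so <- strengths(reference)$s_out
  ss <- strengths(scaffold)$s_out
  if (!isTRUE(all.equal(so, ss))) {
    stop("scaffold out-strength sequence does not match the reference ",
         "(use maslov_sneppen_dir() to build the scaffold)", call. = FALSE)
  }
  .run_sa(reference, scaffold, config, "dir_alt")
}

.run_sa <- function(reference, scaffold, config, objective) {
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- n_nodes(reference)
  et <- edge_table(scaffold)
  st <- strengths(reference)
  obj_code <- match(objective, c("und", "dir", "signed", "dir_alt")) - 1L
  t1 <- switch(objective, und = st$strength, dir = st$s_in,
               signed = st$s_pos, dir_alt = st$s_in)
  t2 <- switch(objective, und = numeric(n), dir = st$s_out,
               signed = st$s_neg, dir_alt = numeric(n))
  thr <- if (is.null(config$energy_threshold)) -1 else config$energy_threshold
  res <- cpp_sa(obj_code, n, et$i - 1L, et$j - 1L, et$weight, t1, t2,
                config$n_stages, config$iters_per_stage, config$T0,
                config$cooling_factor, thr, config$max_stages)
  out <- matrix(0, n, n)
  out[cbind(et$i, et$j)] <- res$weights
  if (!scaffold$directed) out[cbind(et$j, et$i)] <- res$weights
  trace <- structure(
    list(stage_energies = res$stage_energies,
         accepted_per_stage = res$accepted_per_stage,
         initial_energy = res$initial_energy,
         final_energy = res$final_energy,
         best_energy = res$best_energy,
         stages_run = res$stages_run),
    class = "energy_trace"
  )
  list(
    network = weighted_network(out, directed = scaffold$directed,
                               signed = scaffold$signed,
                               labels = reference$labels),
    trace = trace
  )
}

#' @export
print.energy_trace <- function(x, ...) {
  cat(sprintf(
    "<energy_trace: %d stages, E %.6g -> %.6g (best %.6g)>\n",
    x$stages_run, x$initial_energy, x$final_energy, x$best_energy))
  invisible(x)
}

#' Derive a per-null seed from a master seed
#'
#' Deterministic integer mixing of the master seed, the null index and a
#' stream id, kept below 2^31. Because each null's seed depends only on its
#' index, ensembles are reproducible regardless of generation order or
#' parallel scheduling.
#'
#' @param master_seed integer master seed.
#' @param index null index (1-based).
#' @param stream stream id separating the rewiring and weight-assignment
#'   stages of one null.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, index, stream = 0) {
  m <- 2147483647
  mix <- function(a, b) ((a %% m) * 48271 + b + 1) %% m
  h <- mix(mix(mix(abs(master_seed), index), stream), 97)
  as.integer(h %% (m - 1) + 1)
}

#' Generate an ensemble of randomized null networks
#'
#' Builds `n_nulls` independent nulls from a reference network. Rewired
#' scaffolds are generated first (Maslov-Sneppen for unsigned networks,
#' connection switching for signed ones); the strength-preserving procedures
#' (`"rs"`, `"sa"`, `"sa_dir_alt"`) are then applied to each scaffold
#' individually. Because the scaffold seed for null *i* depends only on the
#' master seed and *i*, ensembles generated with different algorithms but the
#' same master seed share their binary topologies null-by-null; only the
#' weight assignments differ.
#'
#' @param reference the empirical [weighted_network()].
#' @param algorithm `"ms"` (degree-preserving rewiring only), `"rs"`
#'   (Rubinov-Sporns rank matching), `"sa"` (simulated annealing) or
#'   `"sa_dir_alt"` (directed, out-strength-exact annealing variant).
#' @param n_nulls ensemble size.
#' @param swaps_per_edge rewiring intensity for the scaffolds.
#' @param preserve_connectedness passed to the rewiring step (unsigned
#'   networks only).
#' @param annealing an [annealing_config()] for the `"sa"` variants; its
#'   `seed` field is ignored in favor of per-null derived seeds.
#' @param seed master seed.
#' @return A `null_ensemble`: list with `networks`, `algorithm`, `config`,
#'   `master_seed`, `seeds` (per-null derived seeds) and, for annealing
#'   algorithms, `traces`.
#' @export
generate_ensemble <- function(reference,
                              algorithm = c("ms", "rs", "sa", "sa_dir_alt"),
                              n_nulls, swaps_per_edge = 10,
                              preserve_connectedness = !reference$signed,
                              annealing = annealing_config(), seed = 1) {
  algorithm <- match.arg(algorithm)
  stopifnot(is_weighted_network(reference), n_nulls >= 1)
  if (algorithm %in% c("rs") && reference$directed) {
    stop("the rank-matching algorithm supports undirected networks only",
         call. = FALSE)
  }
  if (algorithm == "sa_dir_alt" && !reference$directed) {
    stop("`sa_dir_alt` requires a directed network", call. = FALSE)
  }
  networks <- vector("list", n_nulls)
  traces <- if (algorithm %in% c("sa", "sa_dir_alt")) vector("list", n_nulls)
  seeds <- data.frame(null = seq_len(n_nulls),
                      rewire_seed = vapply(seq_len(n_nulls), derive_seed,
                                           integer(1), master_seed = seed,
                                           stream = 0),
                      weight_seed = vapply(seq_len(n_nulls), derive_seed,
                                           integer(1), master_seed = seed,
                                           stream = 1))
  for (i in seq_len(n_nulls)) {
    scaffold <- .make_scaffold(reference, swaps_per_edge,
                               preserve_connectedness, seeds$rewire_seed[i])
    if (algorithm == "ms") {
      networks[[i]] <- scaffold
    } else if (algorithm == "rs") {
      networks[[i]] <- rubinov_sporns(reference, scaffold,
                                      seed = seeds$weight_seed[i])
    } else {
      cfg <- annealing
      cfg$seed <- seeds$weight_seed[i]
      fit <- if (algorithm == "sa") {
        simulated_annealing(reference, scaffold, cfg)
      } else {
        simulated_annealing_dir_alt(reference, scaffold, cfg)
      }
      networks[[i]] <- fit$network
      traces[[i]] <- fit$trace
    }
  }
  structure(
    list(networks = networks, algorithm = algorithm,
         config = list(swaps_per_edge = swaps_per_edge,
                       preserve_connectedness = preserve_connectedness,
                       annealing = if (algorithm %in% c("sa", "sa_dir_alt"))
                         unclass(annealing)[setdiff(names(annealing), "seed")]),
         master_seed = seed, seeds = seeds, traces = traces),
    class = "null_ensemble"
  )
}

.make_scaffold <- function(reference, swaps_per_edge, preserve_connectedness,
                           seed) {
  if (reference$signed) {
    switch_signed(reference, swaps_per_edge, seed = seed)$network
  } else if (reference$directed) {
    maslov_sneppen_dir(reference, swaps_per_edge,
                       preserve_connectedness, seed = seed)$network
  } else {
    maslov_sneppen_und(reference, swaps_per_edge,
                       preserve_connectedness, seed = seed)$network
  }
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble: %d nulls, algorithm \"%s\", master seed %s>\n",
              length(x$networks), x$algorithm, format(x$master_seed)))
  invisible(x)
}
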