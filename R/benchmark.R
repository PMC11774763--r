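#' Per-null Spearman correlation of strength sequences
#'
#' For each null network, the Spearman rank-order correlation (average-rank
#' tie handling) between the empirical strength vector and the null's
#' strength vector. A constant strength vector makes the correlation
#' undefined (NA, with a warning).
#'
#' @param reference the empirical [weighted_network()].
#' @param ensemble a `null_ensemble` of matching size.
#' @return A tibble with columns `null` and `rho`.
#' @export
strength_spearman <- function(reference, ensemble) {
  vecs <- .strength_vectors(reference, ensemble)
  rho <- vapply(vecs$nulls, function(s) {
    if (stats::sd(s) == 0 || stats::sd(vecs$ref) == 0) {
      warning("constant strength vector: Spearman correlation undefined")
      return(NA_real_)
    }
    stats::cor(vecs$ref, s, method = "spearman")
  }, numeric(1))
  tibble::tibble(null = seq_along(rho), rho = rho)
}

#' Per-null Kolmogorov-Smirnov statistic of strength distributions
#'
#' Two-sample KS statistic (the maximum distance between the empirical
#' cumulative strength distributions) between the reference network's
#' strengths and each null's strengths.
#'
#' @inheritParams strength_spearman
#' @return A tibble with columns `null` and `ks`.
#' @export
strength_ks <- function(reference, ensemble) {
  vecs <- .strength_vectors(reference, ensemble)
  ks <- vapply(vecs$nulls, function(s) {
    unname(suppressWarnings(stats::ks.test(vecs$ref, s)$statistic))
  }, numeric(1))
  tibble::tibble(null = seq_along(ks), ks = ks)
}

.strength_vectors <- function(reference, ensemble) {
  stopifnot(is_weighted_network(reference), inherits(ensemble, "null_ensemble"))
  if (n_nodes(ensemble$networks[[1]]) != n_nodes(reference)) {
    stop("ensemble and reference network sizes differ", call. = FALSE)
  }
  svec <- function(net) {
    st <- strengths(net)
    if (!is.null(st$strength)) st$strength else
      if (!is.null(st$s_in)) st$s_in + st$s_out else st$s_pos - st$s_neg
  }
  list(ref = svec(reference), nulls = lapply(ensemble$networks, svec))
}

#' Mann-Whitney U test with common-language effect size
#'
#' Two-sided Mann-Whitney U rank test between two groups (exact enumeration
#' for small tie-free samples, normal approximation with tie correction
#' otherwise) plus the common-language effect size
#' `CLES = 100 * (#\{a > b\} + 0.5 #\{a = b\}) / (n_a n_b)`, the percentage
#' of cross-group pairs in which the first group's value is larger. CLES and
#' U are linked by `CLES = 100 * U / (n_a n_b)`.
#'
#' @param group_a,group_b numeric vectors (both nonempty).
#' @return One-row tibble with columns `u`, `p`, `cles`.
#' @export
mwu_cles <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  na <- length(group_a)
  nb <- length(group_b)
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- !ties && na <= 20 && nb <= 20
  ht <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = TRUE)
  )
  u <- unname(ht$statistic)  # counts a-over-b wins plus half-ties
  tibble::tibble(u = u, p = ht$p.value, cles = 100 * u / (na * nb))
}

#' Morphospace of a null ensemble
#'
#' Embeds each null network (and the reference) in the two-dimensional space
#' spanned by characteristic path length and mean clustering, and summarizes
#' the ensemble by the mean and (unbiased) variance of each coordinate.
#'
#' @inheritParams strength_spearman
#' @param config a [metric_config()] controlling the length mapping.
#' @return A `morphospace` object: list with `points` (tibble `null`, `cpl`,
#'   `clustering`), `reference` (one-row tibble) and `summary` (one-row
#'   tibble of ensemble means/variances).
#' @export
morphospace <- function(reference, ensemble, config = metric_config()) {
  stopifnot(is_weighted_network(reference), inherits(ensemble, "null_ensemble"))
  one_point <- function(net) {
    c(cpl = characteristic_path_length(net, config),
      clustering = mean_clustering(net))
  }
  pts <- t(vapply(ensemble$networks, one_point, numeric(2)))
  ref <- one_point(reference)
  points <- tibble::tibble(null = seq_len(nrow(pts)),
                           cpl = pts[, "cpl"], clustering = pts[, "clustering"])
  summary <- tibble::tibble(
    ensemble_mean_cpl = mean(points$cpl),
    ensemble_var_cpl = stats::var(points$cpl),
    ensemble_mean_clu = mean(points$clustering),
    ensemble_var_clu = stats::var(points$clustering)
  )
  structure(
    list(points = points,
         reference = tibble::tibble(cpl = ref[["cpl"]],
                                    clustering = ref[["clustering"]]),
         summary = summary),
    class = "morphospace"
  )
}

#' @export
print.morphospace <- function(x, ...) {
  cat(sprintf("<morphospace: %d nulls; mean CPL %.4g, mean clustering %.4g>\n",
              nrow(x$points), x$summary$ensemble_mean_cpl,
              x$summary$ensemble_mean_clu))
  invisible(x)
}

#' Subsample convergence of morphospace statistics
#'
#' Quantifies how many nulls are needed to approximate the full-ensemble
#' morphospace statistics. For each subsample size, `n_resamples` subsamples
#' are drawn without replacement; for each of the four statistics (mean and
#' variance of mean clustering and of characteristic path length) the
#' relative difference `|stat_sub - stat_full| / |stat_full|` is averaged
#' over resamples, with a 95% bootstrap interval (2.5/97.5 percentiles of
#' the resampled values). At the full ensemble size the relative difference
#' is exactly zero.
#'
#' @param summary a [morphospace()] result.
#' @param sample_sizes integer subsample sizes (each at most the ensemble
#'   size).
#' @param n_resamples random subsamples per size (default 1000).
#' @param seed integer seed.
#' @param signed report signed relative differences
#'   (`(stat_sub - stat_full) / |stat_full|`) instead of magnitudes.
#' @return A `convergence_trajectory` tibble with columns `statistic`,
#'   `sample_size`, `rel_diff`, `ci_lo`, `ci_hi`.
#' @export
subsample_convergence <- function(summary, sample_sizes, n_resamples = 1000,
                                  seed = NULL, signed = FALSE) {
  stopifnot(inherits(summary, "morphospace"))
  pts <- summary$points
  n_full <- nrow(pts)
  if (any(sample_sizes > n_full)) {
    stop("subsample size exceeds the ensemble size (", n_full, ")",
         call. = FALSE)
  }
  full <- c(mean_clustering = mean(pts$clustering),
            var_clustering = stats::var(pts$clustering),
            mean_cpl = mean(pts$cpl),
            var_cpl = stats::var(pts$cpl))
  if (any(full == 0)) {
    stop("a full-ensemble statistic is zero: relative difference undefined",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (size in sample_sizes) {
    reldiff <- matrix(0, n_resamples, 4,
                      dimnames = list(NULL, names(full)))
    for (r in seq_len(n_resamples)) {
      idx <- sample.int(n_full, size)
      sub <- c(mean(pts$clustering[idx]), stats::var(pts$clustering[idx]),
               mean(pts$cpl[idx]), stats::var(pts$cpl[idx]))
      d <- (sub - full) / abs(full)
      reldiff[r, ] <- if (signed) d else abs(d)
    }
    for (stat in names(full)) {
      v <- reldiff[, stat]
      ci <- stats::quantile(v, c(0.025, 0.975), names = FALSE)
      rows[[length(rows) + 1]] <- tibble::tibble(
        statistic = stat, sample_size = size, rel_diff = mean(v),
        ci_lo = ci[1], ci_hi = ci[2])
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("convergence_trajectory", class(out)),
            n_resamples = n_resamples, signed = signed)
}

#' Benchmark several null ensembles against a reference network
#'
#' Computes per-null strength Spearman correlations and KS statistics for
#' each ensemble, plus pairwise Mann-Whitney comparisons (with CLES) of the
#' per-null Spearman and KS distributions between every pair of ensembles.
#'
#' @param reference the empirical [weighted_network()].
#' @param ensembles named list of `null_ensemble` objects generated from
#'   `reference`.
#' @return A `benchmark_report`: list with `per_null` (tibble `algorithm`,
#'   `null`, `rho`, `ks`) and `pairwise` (tibble `a`, `b`, `metric`, `u`,
#'   `p`, `cles`).
#' @export
compare_ensembles <- function(reference, ensembles) {
  stopifnot(is.list(ensembles), length(ensembles) >= 1)
  if (is.null(names(ensembles)) || any(!nzchar(names(ensembles)))) {
    names(ensembles) <- vapply(ensembles, function(e) e$algorithm,
                               character(1))
  }
  per_null <- dplyr::bind_rows(lapply(names(ensembles), function(nm) {
    e <- ensembles[[nm]]
    dplyr::mutate(
      dplyr::inner_join(strength_spearman(reference, e),
                        strength_ks(reference, e), by = "null"),
      algorithm = nm, .before = 1)
  }))
  pairs <- utils::combn(names(ensembles), 2, simplify = FALSE)
  if (length(ensembles) < 2) pairs <- list()
  pairwise <- dplyr::bind_rows(lapply(pairs, function(pr) {
    dplyr::bind_rows(lapply(c("rho", "ks"), function(metric) {
      va <- per_null[[metric]][per_null$algorithm == pr[1]]
      vb <- per_null[[metric]][per_null$algorithm == pr[2]]
      dplyr::mutate(mwu_cles(stats::na.omit(va), stats::na.omit(vb)),
                    a = pr[1], b = pr[2], metric = metric, .before = 1)
    }))
  }))
  structure(list(per_null = per_null, pairwise = pairwise),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("<benchmark_report>\n")
  means <- dplyr::summarise(
    dplyr::group_by(x$per_null, .data$algorithm),
    mean_rho = mean(.data$rho, na.rm = TRUE),
    mean_ks = mean(.data$ks, na.rm = TRUE))
  print(as.data.frame(means), row.names = FALSE)
  invisible(x)
}
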