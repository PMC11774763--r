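#' Exponential reference right-tail probability
#'
#' For any exponential distribution, the probability of exceeding
#' `Q3 + 3 * IQR` is the same regardless of rate: with quartiles
#' `Q1 = ln(4/3)/lambda`, `Q3 = ln(4)/lambda`, the threshold is
#' `(ln 4 + 3 ln 3)/lambda` and the exceedance probability
#' `exp(-(ln 4 + 3 ln 3)) = 1/108`, approximately 0.009. Empirical
#' distributions with right-tail mass above this constant are flagged as
#' heavy-tailed (subexponential tail decay).
#'
#' @return The constant `1/108`, computed in closed form.
#' @export
exp_right_tail_p <- function() {
  exp(-(log(4) + 3 * log(3)))
}

#' Nonparametric right-tailedness of a distribution
#'
#' Computes the empirical first and third quartiles (linear interpolation of
#' the empirical distribution), the Tukey-style far-outlier threshold
#' `Q3 + 3 * IQR`, and the right-tailedness
#' `p_R = P(X > Q3 + 3 * IQR)` as the fraction of observations strictly
#' exceeding the threshold. The distribution is declared heavy-tailed when
#' `p_R` exceeds the exponential reference value [exp_right_tail_p()].
#'
#' @param values numeric vector (at least 4 values).
#' @return A `hub_report`: list with `q1`, `q3`, `iqr`, `outlier_threshold`,
#'   `p_R`, `heavy_tailed` and `hub_indices` (indices of the outliers).
#' @examples
#' right_tailedness(rexp(1000))
#' @export
right_tailedness <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 4) {
    stop("right_tailedness() needs at least 4 values", call. = FALSE)
  }
  qs <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  q1 <- qs[1]
  q3 <- qs[2]
  iqr <- q3 - q1
  thr <- q3 + 3 * iqr
  hubs <- which(values > thr)
  p_r <- length(hubs) / length(values)
  structure(
    list(q1 = q1, q3 = q3, iqr = iqr, outlier_threshold = thr,
         p_R = p_r, heavy_tailed = p_r > exp_right_tail_p(),
         hub_indices = hubs),
    class = "hub_report"
  )
}

#' Identify strength hubs of a network
#'
#' Applies [right_tailedness()] to the node strength vector: hubs are the
#' nodes whose strength exceeds `Q3 + 3 * IQR` of the strength distribution.
#'
#' @inheritParams n_nodes
#' @return A `hub_report` (see [right_tailedness()]).
#' @export
identify_hubs <- function(network) {
  .check_kind(network, directed = FALSE, signed = FALSE,
              what = "identify_hubs()")
  right_tailedness(strengths(network)$strength)
}

#' @export
print.hub_report <- function(x, ...) {
  cat(sprintf(
    "<hub_report: p_R = %.4g (exponential reference %.4g), %sheavy-tailed, %d hub(s)>\n",
    x$p_R, exp_right_tail_p(), if (x$heavy_tailed) "" else "not ",
    length(x$hub_indices)))
  invisible(x)
}

#' z-scored Rand index between two partitions
#'
#' Standardizes the Rand pair count `w` (the number of node pairs co-assigned
#' in both partitions) under the fixed-margins permutation model: all
#' relabelings of one partition with the same group sizes are equally likely,
#' the pair count then follows the hypergeometric pair model, and
#' `z = (w - E[w]) / sd(w)`. Accepts any number of classes; commonly used
#' here to compare binary hub/non-hub partitions between an empirical
#' network and its randomized nulls.
#'
#' @param partition_a,partition_b label vectors of equal length.
#' @return Scalar z-score.
#' @seealso [zrand_perm()] for a permutation-based estimate of the same
#'   quantity.
#' @export
zrand <- function(partition_a, partition_b) {
  a <- as.integer(factor(partition_a))
  b <- as.integer(factor(partition_b))
  n <- length(a)
  if (length(b) != n) stop("partitions have different lengths", call. = FALSE)
  if (n < 2) stop("partitions must cover at least 2 nodes", call. = FALSE)
  if (length(unique(a)) < 2 || length(unique(b)) < 2) {
    stop("undefined z-Rand: a partition has a single class", call. = FALSE)
  }
  M <- n * (n - 1) / 2
  na <- as.numeric(table(a))
  nb <- as.numeric(table(b))
  M1 <- sum(choose(na, 2))
  M2 <- sum(choose(nb, 2))
  cont <- table(a, b)
  w <- sum(choose(cont, 2))
  c1 <- n * (n^2 - 3 * n - 2) - 8 * (n + 1) * M1 + 4 * sum(na^3)
  c2 <- n * (n^2 - 3 * n - 2) - 8 * (n + 1) * M2 + 4 * sum(nb^3)
  vw <- M / 16 -
    (4 * M1 - 2 * M)^2 * (4 * M2 - 2 * M)^2 / (256 * M^2) +
    c1 * c2 / (16 * n * (n - 1) * (n - 2)) +
    ((4 * M1 - 2 * M)^2 - 4 * c1 - 4 * M) *
      ((4 * M2 - 2 * M)^2 - 4 * c2 - 4 * M) /
      (64 * n * (n - 1) * (n - 2) * (n - 3))
  if (vw <= 0) stop("undefined z-Rand: degenerate pair-count variance",
                    call. = FALSE)
  (w - M1 * M2 / M) / sqrt(vw)
}

#' @rdname zrand
#' @param n_perm number of random relabelings.
#' @param seed integer seed.
#' @return `zrand_perm()`: a Monte-Carlo estimate of the same z-score,
#'   obtained by permuting the labels of `partition_b`.
#' @export
zrand_perm <- function(partition_a, partition_b, n_perm = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- as.integer(factor(partition_a))
  b <- as.integer(factor(partition_b))
  pair_count <- function(x, y) sum(choose(table(x, y), 2))
  w_obs <- pair_count(a, b)
  w_null <- vapply(seq_len(n_perm), function(i) pair_count(a, sample(b)),
                   numeric(1))
  (w_obs - mean(w_null)) / stats::sd(w_null)
}
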