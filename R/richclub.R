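#' Weighted rich-club coefficient at one degree threshold
#'
#' The rich club at threshold `k` is the set of nodes with binary degree at
#' least `k`; its weighted connectedness `W_ge_k` is the total weight of the
#' edges joining two club members ("rich links"). Two variants of the
#' coefficient `phi = C / D` are provided:
#' * `"simplified"`: `phi = W_ge_k` (numerator only). When normalized against
#'   nulls that preserve the degree sequence and weight multiset, the
#'   denominator cancels, so this is the quantity that matters.
#' * `"top_ranked"`: `phi = W_ge_k / sum(top E_ge_k weights)`, the fraction
#'   of weight the rich nodes share relative to what they could share if
#'   linked by the network's strongest connections; always in `[0, 1]`.
#'
#' The coefficient is undefined (NA) when the club has fewer than two nodes
#' or no internal edges.
#'
#' @inheritParams n_nodes
#' @param k degree threshold.
#' @param variant `"simplified"` or `"top_ranked"`.
#' @return One-row tibble with columns `k`, `club_size`, `E_ge_k`, `phi`.
#' @export
rich_club_coefficient <- function(network, k,
                                  variant = c("simplified", "top_ranked")) {
  variant <- match.arg(variant)
  .check_kind(network, directed = FALSE, signed = FALSE,
              what = "rich_club_coefficient()")
  deg <- degrees(network)$degree
  club <- which(deg >= k)
  w <- network$weights
  if (length(club) < 2) {
    return(tibble::tibble(k = k, club_size = length(club), E_ge_k = 0L,
                          phi = NA_real_))
  }
  sub <- w[club, club, drop = FALSE]
  ut <- upper.tri(sub) & sub != 0
  e_ge_k <- sum(ut)
  if (e_ge_k == 0) {
    return(tibble::tibble(k = k, club_size = length(club), E_ge_k = 0L,
                          phi = NA_real_))
  }
  w_ge_k <- sum(sub[ut])
  phi <- if (variant == "simplified") {
    w_ge_k
  } else {
    all_w <- sort(.weight_multiset(network), decreasing = TRUE)
    w_ge_k / sum(all_w[seq_len(e_ge_k)])
  }
  tibble::tibble(k = k, club_size = length(club), E_ge_k = as.integer(e_ge_k),
                 phi = phi)
}

#' Normalized weighted rich-club curve
#'
#' Computes the empirical rich-club coefficient across a range of degree
#' thresholds, the mean coefficient over a null ensemble, the normalized
#' coefficient `phi_norm(k) = phi(k) / mean(phi_null(k))`, and a one-sided
#' p-value per threshold as the proportion of nulls whose coefficient is
#' strictly greater than the empirical one. Thresholds where the empirical
#' coefficient is undefined are dropped from the curve (and from the
#' multiple-comparison correction count); nulls undefined at a given
#' threshold are excluded from the mean and p-value there, with the exclusion
#' count reported.
#'
#' @inheritParams rich_club_coefficient
#' @param ensemble a `null_ensemble` of randomized networks (see
#'   [generate_ensemble()]).
#' @param k_range integer thresholds to evaluate; defaults to
#'   `1:(max degree - 1)`.
#' @param alpha significance level.
#' @param correction `"bonferroni"` (over the number of defined thresholds)
#'   or `"none"`.
#' @return A `rich_club_curve` tibble with columns `k`, `club_size`,
#'   `E_ge_k`, `phi`, `phi_null_mean`, `phi_norm`, `p`, `significant`,
#'   `n_null_defined`.
#' @export
normalized_rich_club <- function(network, ensemble, k_range = NULL,
                                 variant = c("simplified", "top_ranked"),
                                 alpha = 0.05,
                                 correction = c("bonferroni", "none")) {
  variant <- match.arg(variant)
  correction <- match.arg(correction)
  stopifnot(inherits(ensemble, "null_ensemble"))
  nulls <- ensemble$networks
  if (length(nulls) == 0) stop("empty null ensemble", call. = FALSE)
  if (n_nodes(nulls[[1]]) != n_nodes(network)) {
    stop("ensemble networks and empirical network differ in size",
         call. = FALSE)
  }
  if (is.null(k_range)) {
    k_range <- seq_len(max(degrees(network)$degree) - 1)
  }
  emp <- dplyr::bind_rows(
    lapply(k_range, function(k) rich_club_coefficient(network, k, variant))
  )
  keep <- !is.na(emp$phi)
  emp <- emp[keep, , drop = FALSE]
  null_phi <- vapply(nulls, function(nn) {
    vapply(emp$k, function(k) rich_club_coefficient(nn, k, variant)$phi,
           numeric(1))
  }, numeric(nrow(emp)))
  null_phi <- matrix(null_phi, nrow = nrow(emp))
  n_def <- rowSums(!is.na(null_phi))
  phi_null_mean <- rowMeans(null_phi, na.rm = TRUE)
  exceed <- rowSums(null_phi > emp$phi, na.rm = TRUE)
  p <- ifelse(n_def > 0, exceed / n_def, NA_real_)
  n_tests <- nrow(emp)
  thr <- if (correction == "bonferroni") alpha / n_tests else alpha
  out <- tibble::tibble(
    k = emp$k, club_size = emp$club_size, E_ge_k = emp$E_ge_k,
    phi = emp$phi, phi_null_mean = phi_null_mean,
    phi_norm = emp$phi / phi_null_mean,
    p = p, significant = !is.na(p) & p < thr,
    n_null_defined = as.integer(n_def)
  )
  structure(out, class = c("rich_club_curve", class(out)),
            variant = variant, alpha = alpha, correction = correction,
            n_nulls = length(nulls))
}

#' Write a rich-club curve to CSV
#'
#' Columns: `k, club_size, E_ge_k, phi, phi_null_mean, phi_norm, p,
#' significant`.
#'
#' @param curve a `rich_club_curve` from [normalized_rich_club()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rich_club_curve <- function(curve, path) {
  cols <- c("k", "club_size", "E_ge_k", "phi", "phi_null_mean", "phi_norm",
            "p", "significant")
  utils::write.csv(as.data.frame(curve)[, cols], path, row.names = FALSE)
  invisible(path)
}
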