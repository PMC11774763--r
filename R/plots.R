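#' Plot a normalized rich-club curve
#'
#' Normalized coefficient versus degree threshold, with significant
#' thresholds (after correction) highlighted and the no-enrichment line at 1.
#'
#' @param object a `rich_club_curve` from [normalized_rich_club()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.rich_club_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$phi_norm)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "#2166ac")) +
    ggplot2::labs(x = "degree threshold k",
                  y = expression(phi[norm]^w * (k)),
                  colour = "significant") +
    ggplot2::theme_minimal()
}

#' Plot a morphospace
#'
#' Null networks as points in the (characteristic path length, mean
#' clustering) plane with the empirical network marked.
#'
#' @param object a `morphospace` from [morphospace()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.morphospace <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$cpl, y = .data$clustering)) +
    ggplot2::geom_point(alpha = 0.5, colour = "#2166ac") +
    ggplot2::geom_point(data = object$reference, colour = "#4a1486",
                        shape = 18, size = 3) +
    ggplot2::labs(x = "characteristic path length", y = "mean clustering") +
    ggplot2::theme_minimal()
}

#' Plot subsample convergence trajectories
#'
#' Mean relative difference to the full-ensemble statistic versus subsample
#' size, with the 95% bootstrap band, one panel per statistic.
#'
#' @param object a `convergence_trajectory` from [subsample_convergence()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.convergence_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$sample_size,
                                       y = .data$rel_diff)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                         fill = "#2166ac", alpha = 0.25) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::facet_wrap(~.data$statistic, scales = "free_y") +
    ggplot2::labs(x = "subsample size", y = "relative difference") +
    ggplot2::theme_minimal()
}

#' Plot an annealing energy trace
#'
#' End-of-stage energy on a log scale across annealing stages.
#'
#' @param object an `energy_trace` from [simulated_annealing()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.energy_trace <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$stage,
                                             y = .data$energy)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "annealing stage", y = "energy (m.s.e.)") +
    ggplot2::theme_minimal()
}

#' @export
plot.rich_club_curve <- function(x, ...) print(autoplot(x, ...))
#' @export
plot.morphospace <- function(x, ...) print(autoplot(x, ...))
#' @export
plot.convergence_trajectory <- function(x, ...) print(autoplot(x, ...))
#' @export
plot.energy_trace <- function(x, ...) print(autoplot(x, ...))

#' @importFrom rlang .data
NULL
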