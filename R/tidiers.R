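#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a null ensemble
#'
#' One row per null: derived seeds and, for annealing ensembles, the final
#' and best energies and the number of stages run.
#'
#' @param x a `null_ensemble`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.null_ensemble <- function(x, ...) {
  out <- tibble::as_tibble(x$seeds)
  if (!is.null(x$traces)) {
    out$initial_energy <- vapply(x$traces, `[[`, numeric(1), "initial_energy")
    out$final_energy <- vapply(x$traces, `[[`, numeric(1), "final_energy")
    out$best_energy <- vapply(x$traces, `[[`, numeric(1), "best_energy")
    out$stages_run <- vapply(x$traces, `[[`, numeric(1), "stages_run")
  }
  out
}

#' @rdname tidy.null_ensemble
#' @export
glance.null_ensemble <- function(x, ...) {
  out <- tibble::tibble(algorithm = x$algorithm,
                        n_nulls = length(x$networks),
                        n_nodes = n_nodes(x$networks[[1]]),
                        master_seed = x$master_seed)
  if (!is.null(x$traces)) {
    fe <- vapply(x$traces, `[[`, numeric(1), "final_energy")
    out$mean_final_energy <- mean(fe)
    out$max_final_energy <- max(fe)
  }
  out
}

#' Tidy an annealing energy trace
#'
#' @param x an `energy_trace`.
#' @param ... unused.
#' @return A tibble with columns `stage`, `energy`, `accepted`.
#' @export
tidy.energy_trace <- function(x, ...) {
  tibble::tibble(stage = seq_len(x$stages_run),
                 energy = x$stage_energies,
                 accepted = x$accepted_per_stage)
}

#' @rdname tidy.energy_trace
#' @export
glance.energy_trace <- function(x, ...) {
  tibble::tibble(initial_energy = x$initial_energy,
                 final_energy = x$final_energy,
                 best_energy = x$best_energy,
                 stages_run = x$stages_run)
}

#' Tidy a hub report
#'
#' @param x a `hub_report`.
#' @param ... unused.
#' @return `tidy()`: one row per hub; `glance()`: the scalar summary.
#' @export
tidy.hub_report <- function(x, ...) {
  tibble::tibble(hub = x$hub_indices)
}

#' @rdname tidy.hub_report
#' @export
glance.hub_report <- function(x, ...) {
  tibble::tibble(q1 = x$q1, q3 = x$q3, iqr = x$iqr,
                 outlier_threshold = x$outlier_threshold,
                 p_R = x$p_R, heavy_tailed = x$heavy_tailed,
                 n_hubs = length(x$hub_indices))
}

#' Tidy a morphospace
#'
#' @param x a `morphospace`.
#' @param ... unused.
#' @return `tidy()`: the per-null (cpl, clustering) points; `glance()`: the
#'   ensemble means and variances plus the reference point.
#' @export
tidy.morphospace <- function(x, ...) x$points

#' @rdname tidy.morphospace
#' @export
glance.morphospace <- function(x, ...) {
  dplyr::bind_cols(x$summary,
                   tibble::tibble(reference_cpl = x$reference$cpl,
                                  reference_clu = x$reference$clustering))
}

#' Tidy a benchmark report
#'
#' @param x a `benchmark_report`.
#' @param ... unused.
#' @return `tidy()`: per-null metric rows; `glance()`: per-algorithm means.
#' @export
tidy.benchmark_report <- function(x, ...) x$per_null

#' @rdname tidy.benchmark_report
#' @export
glance.benchmark_report <- function(x, ...) {
  dplyr::summarise(dplyr::group_by(x$per_null, .data$algorithm),
                   mean_rho = mean(.data$rho, na.rm = TRUE),
                   mean_ks = mean(.data$ks, na.rm = TRUE),
                   .groups = "drop")
}
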