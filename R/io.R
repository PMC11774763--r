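#' Read a weighted network from disk
#'
#' Two plain-text formats are supported. `"dense"` is a square numeric table,
#' comma- or whitespace-delimited (autodetected); an optional header row is
#' interpreted as node labels. `"edgelist"` is a TSV with columns
#' `source`, `target`, `weight`; undirected files list each edge once and are
#' symmetrized on read. Numeric node identifiers in edge lists are taken as
#' 0-based indices; non-numeric identifiers become labels in first-appearance
#' order.
#'
#' @param path file to read.
#' @param format `"dense"` or `"edgelist"`.
#' @param directed,signed flags of the stored network.
#' @return A [weighted_network()].
#' @export
read_network <- function(path, format = c("dense", "edgelist"),
                         directed = FALSE, signed = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "dense") {
    .read_dense(path, directed, signed)
  } else {
    .read_edgelist(path, directed, signed)
  }
}

.read_dense <- function(path, directed, signed) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty dense matrix file: ", path, call. = FALSE)
  sep <- if (grepl(",", lines[[1]], fixed = TRUE)) "," else ""
  split1 <- if (sep == ",") strsplit(lines[[1]], ",")[[1]] else
    strsplit(trimws(lines[[1]]), "[[:space:]]+")[[1]]
  parsed1 <- suppressWarnings(as.numeric(split1))
  has_header <- any(is.na(parsed1) & !is.nan(parsed1))  # NaN is data, not a label
  labels <- NULL
  if (has_header) {
    labels <- trimws(split1)
    lines <- lines[-1]
  }
  rows <- lapply(lines, function(l) {
    toks <- if (sep == ",") strsplit(l, ",")[[1]] else
      strsplit(trimws(l), "[[:space:]]+")[[1]]
    suppressWarnings(as.numeric(trimws(toks)))
  })
  ncols <- unique(vapply(rows, length, integer(1)))
  if (length(ncols) != 1 || ncols != length(rows)) {
    stop("dense matrix file is not square: ", length(rows), " rows, columns ",
         paste(ncols, collapse = "/"), call. = FALSE)
  }
  w <- do.call(rbind, rows)
  if (anyNA(w)) stop("dense matrix file contains non-numeric or NA entries",
                     call. = FALSE)
  weighted_network(w, directed = directed, signed = signed, labels = labels)
}

.read_edgelist <- function(path, directed, signed) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "character"))
  if (ncol(raw) != 3) stop("edge list must have three columns", call. = FALSE)
  if (nrow(raw) > 0 && is.na(suppressWarnings(as.numeric(raw[1, 3])))) {
    raw <- raw[-1, , drop = FALSE]  # header row
  }
  if (nrow(raw) == 0) stop("edge list has no edges", call. = FALSE)
  wt <- suppressWarnings(as.numeric(raw[[3]]))
  if (anyNA(wt)) stop("non-numeric weights in edge list", call. = FALSE)
  ids <- c(raw[[1]], raw[[2]])
  numeric_ids <- !anyNA(suppressWarnings(as.numeric(ids)))
  if (numeric_ids) {
    src <- as.integer(raw[[1]]) + 1L  # 0-based on disk
    dst <- as.integer(raw[[2]]) + 1L
    labels <- NULL
    n <- max(src, dst)
  } else {
    labels <- unique(ids)
    src <- match(raw[[1]], labels)
    dst <- match(raw[[2]], labels)
    n <- length(labels)
  }
  if (any(src == dst)) stop("edge list contains a self-loop", call. = FALSE)
  key <- if (directed) paste(src, dst) else
    paste(pmin(src, dst), pmax(src, dst))
  if (anyDuplicated(key)) stop("duplicate edge in edge list", call. = FALSE)
  w <- matrix(0, n, n)
  w[cbind(src, dst)] <- wt
  if (!directed) w[cbind(dst, src)] <- wt
  weighted_network(w, directed = directed, signed = signed, labels = labels)
}

#' Write a weighted network to disk
#'
#' Dense output is comma-delimited with full floating precision, so a
#' read/write round trip reproduces the matrix exactly. Edge lists are TSV
#' with a `source\ttarget\tweight` header; undirected edges are written once.
#'
#' @param network a [weighted_network()].
#' @param path output file.
#' @param format `"dense"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("dense", "edgelist")) {
  format <- match.arg(format)
  stopifnot(is_weighted_network(network))
  fmt <- function(x) formatC(x, digits = 17, format = "g")
  if (format == "dense") {
    w <- network$weights
    lines <- apply(w, 1, function(r) paste(fmt(r), collapse = ","))
    if (!is.null(network$labels)) {
      lines <- c(paste(network$labels, collapse = ","), lines)
    }
    writeLines(lines, path)
  } else {
    et <- edge_table(network)
    if (is.null(network$labels)) {
      src <- et$i - 1L  # 0-based on disk
      dst <- et$j - 1L
    } else {
      src <- network$labels[et$i]
      dst <- network$labels[et$j]
    }
    lines <- c("source\ttarget\tweight",
               paste(src, dst, fmt(et$weight), sep = "\t"))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Write a null ensemble to a directory
#'
#' Each member network is saved as a dense CSV plus a JSON manifest recording
#' the algorithm, configuration, per-null seeds, final energies and file names.
#'
#' @param ensemble a [null_ensemble] as returned by [generate_ensemble()].
#' @param dir output directory (created if absent).
#' @return The manifest path, invisibly.
#' @export
write_ensemble <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "null_ensemble"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nets <- ensemble$networks
  files <- sprintf("null_%04d.csv", seq_along(nets))
  for (i in seq_along(nets)) {
    write_network(nets[[i]], file.path(dir, files[i]), format = "dense")
  }
  final_energies <- if (is.null(ensemble$traces)) NULL else
    vapply(ensemble$traces, function(tr) tr$final_energy, numeric(1))
  manifest <- list(
    algorithm = ensemble$algorithm,
    config = ensemble$config,
    master_seed = ensemble$master_seed,
    seeds = ensemble$seeds,
    final_energies = final_energies,
    directed = nets[[1]]$directed,
    signed = nets[[1]]$signed,
    files = files
  )
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  if (!is.null(ensemble$traces)) {
    jsonlite::write_json(
      lapply(ensemble$traces, unclass),
      file.path(dir, "traces.json"), digits = NA, null = "null"
    )
  }
  invisible(mpath)
}

#' Read a null ensemble written by [write_ensemble()]
#'
#' @param dir directory containing `manifest.json`.
#' @return A [null_ensemble] object.
#' @export
read_ensemble <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", dir, call. = FALSE)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  nets <- lapply(manifest$files, function(f) {
    read_network(file.path(dir, f), format = "dense",
                 directed = isTRUE(manifest$directed),
                 signed = isTRUE(manifest$signed))
  })
  traces <- NULL
  tpath <- file.path(dir, "traces.json")
  if (file.exists(tpath)) {
    traces <- lapply(jsonlite::read_json(tpath, simplifyVector = FALSE),
                     function(tr) {
                       structure(list(
                         stage_energies = as.numeric(unlist(tr$stage_energies)),
                         accepted_per_stage = as.integer(unlist(tr$accepted_per_stage)),
                         initial_energy = as.numeric(unlist(tr$initial_energy)),
                         final_energy = as.numeric(unlist(tr$final_energy)),
                         best_energy = as.numeric(unlist(tr$best_energy)),
                         stages_run = as.integer(unlist(tr$stages_run))
                       ), class = "energy_trace")
                     })
  }
  structure(
    list(networks = nets, algorithm = manifest$algorithm,
         config = manifest$config, master_seed = manifest$master_seed,
         seeds = manifest$seeds, traces = traces),
    class = "null_ensemble"
  )
}
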