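# Readers and writers: epochs as an RDS array container with a JSON
# sidecar, sensor layouts and design tables as CSV, results as JSON.

#' Write an epoch_set to disk
#'
#' The numeric payload goes into `<stem>.rds` (a binary array container);
#' times, sensor ids and trial metadata go into a human-readable JSON
#' sidecar `<stem>.json`. The round trip through [read_epochs()] is
#' bit-exact.
#'
#' @param x an `epoch_set`.
#' @param stem output path stem (without extension).
#' @return Invisibly, the two file paths.
#' @export
write_epochs <- function(x, stem) {
  stopifnot(inherits(x, "epoch_set"))
  dir.create(dirname(stem), recursive = TRUE, showWarnings = FALSE)
  data_path <- paste0(stem, ".rds")
  meta_path <- paste0(stem, ".json")
  # the binary container carries the exact numerics (times included:
  # their last bits do not survive a decimal round trip)
  saveRDS(list(data = x$data, times = x$times), data_path)
  meta <- list(participant = x$participant, times = x$times,
               sensor_ids = x$sensor_ids, trials = x$trials,
               dim = dim(x$data))
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(data = data_path, meta = meta_path))
}

#' Read an epoch_set written by [write_epochs()]
#'
#' @param stem path stem used at write time.
#' @return An `epoch_set`.
#' @export
read_epochs <- function(stem) {
  data_path <- paste0(stem, ".rds")
  meta_path <- paste0(stem, ".json")
  if (!file.exists(data_path) || !file.exists(meta_path))
    stop("format-error: missing ", if (!file.exists(data_path))
      data_path else meta_path)
  payload <- readRDS(data_path)
  data <- payload$data
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(as.integer(meta$dim), as.integer(dim(data))))
    stop("format-error: field `dim` disagrees with the data array")
  if (length(meta$sensor_ids) != dim(data)[1L])
    stop("format-error: field `sensor_ids` length mismatch")
  if (length(meta$times) != length(payload$times) ||
      max(abs(meta$times - payload$times)) > 1e-9)
    stop("format-error: field `times` disagrees with the container")
  if (length(payload$times) != dim(data)[2L])
    stop("format-error: field `times` length mismatch")
  if (nrow(meta$trials) != dim(data)[3L])
    stop("format-error: field `trials` row count mismatch")
  epoch_set(data, payload$times, meta$sensor_ids,
            as.data.frame(meta$trials),
            participant = meta$participant)
}

#' Write / read a sensor layout as CSV (id, x, y, z in mm)
#' @param layout a `sensor_layout`.
#' @param path CSV path.
#' @return `write_layout` the path invisibly; `read_layout` a
#'   `sensor_layout`.
#' @export
write_layout <- function(layout, path) {
  utils::write.csv(as.data.frame(layout)[, c("id", "x", "y", "z")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("id", "x", "y", "z"), names(d))
  if (length(miss))
    stop("format-error: layout CSV missing column ",
         paste(miss, collapse = ", "))
  structure(d, radius = max(sqrt(d$x^2 + d$y^2 + d$z^2)),
            class = c("sensor_layout", "data.frame"))
}

#' Write / read a pair design table as CSV
#' @param design a `pair_design`.
#' @param path CSV path.
#' @return `write_design` the path invisibly; `read_design` a validated
#'   `pair_design`.
#' @export
write_design <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  pair_design(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Serialize an analysis result to JSON
#'
#' Window results, cluster results and ANOVA tables are flattened into a
#' plain list before writing; arbitrary lists pass through.
#'
#' @param x a result object.
#' @param path JSON path.
#' @return The path, invisibly.
#' @export
write_result_json <- function(x, path) {
  strip <- function(v) {
    if (inherits(v, "cluster_result"))
      v <- list(clusters = lapply(v$clusters, function(cl)
                  cl[setdiff(names(cl), "cells")]),
                n_perm = v$n_perm, tail_p = v$tail_p)
    if (is.data.frame(v)) v <- as.list(v)
    v
  }
  jsonlite::write_json(strip(unclass(x)), path, auto_unbox = TRUE,
                       digits = NA, force = TRUE, na = "null")
  invisible(path)
}
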