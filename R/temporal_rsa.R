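# Temporal RSA: per-sensor correlation of time courses within the
# detected window, condition-averaged topographic maps, and the
# sensor-level cluster permutation test (in cluster.R).

#' Temporal similarity map of two trials
#'
#' Per sensor, the Pearson correlation over the window's time samples
#' between the two trials' time series. Constant series are NA (flagged
#' undefined).
#'
#' @param a,b numeric `sensor x time` matrices on identical axes.
#' @param times time axis in seconds.
#' @param window `(start, end)` seconds, half-open; must contain at least
#'   3 samples.
#' @param sensor_ids optional sensor labels.
#' @return Object of class `topographic_map`: `r` per sensor,
#'   `sensor_ids`, `window`.
#' @export
temporal_similarity_map <- function(a, b, times, window,
                                    sensor_ids = NULL) {
  if (!is.matrix(a) || !all(dim(a) == dim(b)))
    stop("invalid-argument: trials must be matrices of equal dimension")
  idx <- window_indices(times, window)
  if (length(idx) < 3L)
    stop("invalid-argument: window shorter than 3 samples")
  r <- row_correlations(a[, idx, drop = FALSE], b[, idx, drop = FALSE])
  structure(list(r = r,
                 sensor_ids = if (is.null(sensor_ids))
                   as.character(seq_len(nrow(a))) else sensor_ids,
                 window = window, label = NA),
            class = "topographic_map")
}

# Pearson correlation of each row of A with the matching row of B;
# zero-variance rows give NA.
row_correlations <- function(A, B) {
  A <- A - rowMeans(A)
  B <- B - rowMeans(B)
  na <- sqrt(rowSums(A * A))
  nb <- sqrt(rowSums(B * B))
  bad <- na <= .Machine$double.eps * ncol(A) |
         nb <= .Machine$double.eps * ncol(B)
  r <- rowSums(A * B) / (na * nb)
  r[bad] <- NA_real_
  r
}

#' @export
print.topographic_map <- function(x, ...) {
  cat(sprintf(
    "<topographic_map> %d sensors, window [%g, %g) s, mean R = %.4f\n",
    length(x$r), x$window[1L], x$window[2L], mean(x$r, na.rm = TRUE)))
  invisible(x)
}

#' Condition-averaged temporal similarity maps
#'
#' For every participant, the temporal similarity map of every comparison
#' in the set is computed and the raw r values are averaged per sensor;
#' the group map is the mean over participants.
#'
#' @param epochs_list list of `epoch_set` objects.
#' @param comparisons a `comparison_set`.
#' @param window `(start, end)` seconds, half-open.
#' @return List of class `map_average`: `r` (group mean per sensor),
#'   `per_participant` (participant x sensor matrix), `sensor_ids`,
#'   `window`, `label`, `n_comparisons`.
#' @export
average_condition_maps <- function(epochs_list, comparisons, window) {
  stopifnot(length(epochs_list) >= 1L,
            inherits(comparisons, "comparison_set"))
  times <- epochs_list[[1L]]$times
  idx <- window_indices(times, window)
  if (length(idx) < 3L)
    stop("invalid-argument: window shorter than 3 samples")
  ns <- dim(epochs_list[[1L]]$data)[1L]
  np <- length(epochs_list)
  pp <- matrix(NA_real_, np, ns)
  n_comp <- integer(np)
  for (p in seq_len(np)) {
    ep <- epochs_list[[p]]
    ci <- comparison_indices(ep, comparisons)
    if (!length(ci$ia))
      stop("empty-condition: no available comparisons for participant ",
           format(ep$participant))
    acc <- numeric(ns); cnt <- numeric(ns)
    for (k in seq_along(ci$ia)) {
      r <- row_correlations(ep$data[, idx, ci$ia[k]],
                            ep$data[, idx, ci$ib[k]])
      good <- !is.na(r)
      acc[good] <- acc[good] + r[good]
      cnt <- cnt + good
    }
    m <- acc / pmax(cnt, 1)
    m[cnt == 0] <- NA_real_
    pp[p, ] <- m
    n_comp[p] <- length(ci$ia)
  }
  structure(list(r = colMeans(pp), per_participant = pp,
                 sensor_ids = epochs_list[[1L]]$sensor_ids,
                 window = window, label = attr(comparisons, "label"),
                 n_comparisons = n_comp),
            class = "map_average")
}

#' @export
print.map_average <- function(x, ...) {
  cat(sprintf(
    "<map_average> label = %s, %d participants x %d sensors, mean R = %.4f\n",
    format(x$label), nrow(x$per_participant),
    ncol(x$per_participant), mean(x$r, na.rm = TRUE)))
  invisible(x)
}
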