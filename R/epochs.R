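#' Epoched multi-sensor time series for one participant
#'
#' Container for a participant's epoched MEG data together with the trial
#' metadata the paired-design analyses need. The numeric payload is stored as
#' a 3-D array with dimensions `sensor x time x trial` (column-major order
#' puts the sensor dimension fastest, which is what the spatial-pattern
#' correlations iterate over).
#'
#' @param data numeric array, `n_sensors x n_times x n_trials`.
#' @param times numeric vector of sample times in seconds, relative to
#'   sentence-final-word (SFW) onset; strictly increasing and uniformly
#'   spaced.
#' @param sensor_ids character vector of sensor labels, length `n_sensors`.
#' @param trials data.frame with one row per trial; must contain at least
#'   `sentence_id` and `pair_id`. Typical columns are `member_index`,
#'   `expectancy` (`"expected"`/`"unexpected"`), `category`
#'   (`"noun"`/`"verb"`) and `presentation_position`.
#' @param participant identifier for the participant (scalar).
#'
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, times, sensor_ids, trials, participant = NA) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array (sensor x time x trial)")
  d <- dim(data)
  if (length(sensor_ids) != d[1L])
    stop("length(sensor_ids) != number of sensor rows in `data`")
  if (length(times) != d[2L])
    stop("length(times) != number of time samples in `data`")
  if (!is.data.frame(trials) || nrow(trials) != d[3L])
    stop("`trials` must be a data.frame with one row per trial")
  if (!all(c("sentence_id", "pair_id") %in% names(trials)))
    stop("`trials` must contain columns sentence_id and pair_id")
  dt <- diff(times)
  if (length(dt) && (any(dt <= 0) || diff(range(dt)) > 1e-9 * mean(dt)))
    stop("`times` must be strictly increasing and uniformly spaced")
  structure(
    list(data = data, times = as.numeric(times),
         sensor_ids = as.character(sensor_ids),
         trials = trials, participant = participant),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> participant %s: %d trials x %d sensors x %d samples\n",
    format(x$participant), d[3L], d[1L], d[2L]))
  cat(sprintf("  time %.3f .. %.3f s  (fs = %.6g Hz)\n",
              x$times[1L], x$times[length(x$times)],
              1 / mean(diff(x$times))))
  invisible(x)
}

#' Sampling rate of an epoch_set
#' @param x an `epoch_set`.
#' @return Sampling rate in Hz.
#' @export
sampling_rate <- function(x) {
  stopifnot(inherits(x, "epoch_set"))
  1 / mean(diff(x$times))
}

#' Indices of the samples inside a time window
#'
#' Windows are half-open, `[start, end)`, the convention used throughout the
#' package.
#'
#' @param times numeric time axis (seconds).
#' @param window length-2 numeric `(start, end)` in seconds.
#' @return Integer vector of indices.
#' @export
window_indices <- function(times, window) {
  stopifnot(length(window) == 2L, window[1L] < window[2L])
  which(times >= window[1L] & times < window[2L])
}

# Centre and L2-normalise the across-sensor pattern at every (time, trial).
# Returns an array of the same shape; columns with zero across-sensor
# variance become NA (flagged undefined, never silently zero).
center_norm_patterns <- function(data) {
  d <- dim(data)
  ns <- d[1L]
  m <- matrix(data, nrow = ns)
  mu <- colMeans(m)
  m <- m - rep(mu, each = ns)
  nrm <- sqrt(colSums(m * m))
  bad <- nrm <= ns * .Machine$double.eps * pmax(abs(mu), 1)
  nrm[bad] <- 1
  m <- m / rep(nrm, each = ns)
  if (any(bad)) m[, bad] <- NA_real_
  array(m, d)
}

# Map sentence ids to trial indices in an epoch_set; NA when absent.
match_trials <- function(epochs, sentence_ids) {
  match(sentence_ids, epochs$trials$sentence_id)
}
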