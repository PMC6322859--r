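# Spatial RSA: instantaneous across-sensor pattern correlations between
# the two trials of a comparison, their condition averages, supra-threshold
# window detection, window-averaged group tests, and cross-temporal
# (temporal generalization) similarity matrices.

#' Spatial-pattern similarity time series of two trials
#'
#' At every time sample, the Pearson correlation across sensors between the
#' two trials' instantaneous sensor vectors. Samples where either vector
#' has zero across-sensor variance are NA (flagged undefined, never
#' silently zero).
#'
#' @param a,b numeric `sensor x time` matrices on identical sensor sets and
#'   time axes.
#' @param times optional time axis (seconds).
#' @param label condition label.
#' @return Object of class `similarity_series`: `r` (per-sample
#'   correlations), `times`, `label`, `n_comparisons = 1`.
#' @export
spatial_similarity_series <- function(a, b, times = NULL, label = NA) {
  if (!is.matrix(a) || !is.matrix(b) || !all(dim(a) == dim(b)))
    stop("invalid-argument: trials must be sensor x time matrices of equal dimension")
  na <- center_norm_patterns(array(a, c(dim(a), 1L)))[, , 1L]
  nb <- center_norm_patterns(array(b, c(dim(b), 1L)))[, , 1L]
  r <- colSums(na * nb)
  structure(list(r = r,
                 times = if (is.null(times)) seq_len(ncol(a)) else times,
                 label = label, n_comparisons = 1L),
            class = "similarity_series")
}

#' @export
print.similarity_series <- function(x, ...) {
  cat(sprintf(
    "<similarity_series> label = %s, %d samples (%d undefined), mean R = %.4f\n",
    format(x$label), length(x$r), sum(is.na(x$r)),
    mean(x$r, na.rm = TRUE)))
  invisible(x)
}

# Resolve a comparison_set against an epoch_set: trial index pairs, with
# comparisons missing a trial dropped (bookkeeping kept by callers).
comparison_indices <- function(epochs, comparisons) {
  ia <- match_trials(epochs, comparisons$sentence_a)
  ib <- match_trials(epochs, comparisons$sentence_b)
  ok <- !is.na(ia) & !is.na(ib)
  list(ia = ia[ok], ib = ib[ok], n_dropped = sum(!ok))
}

# Comparison x time matrix of spatial correlations for one participant,
# from pre-normalised patterns N (sensor x time x trial). Works on the
# flattened (sensor*time) x trial matrix: contiguous column access keeps
# the inner loop cheap even for tens of thousands of comparisons.
comparison_series_matrix <- function(N, ia, ib, time_idx) {
  d <- dim(N)
  ns <- d[1L]
  Nw <- if (length(time_idx) == d[2L]) N
        else N[, time_idx, , drop = FALSE]
  nt <- length(time_idx)
  N2 <- matrix(Nw, ns * nt)
  out <- matrix(NA_real_, length(ia), nt)
  for (k in seq_along(ia)) {
    v <- N2[, ia[k]] * N2[, ib[k]]
    dim(v) <- c(ns, nt)
    out[k, ] <- colSums(v)
  }
  out
}

#' Condition-averaged spatial similarity time series
#'
#' For every participant, computes the spatial similarity time series of
#' every comparison in the set and averages the raw r values (no Fisher z)
#' over comparisons; the group series is the mean over participants.
#' Undefined samples are excluded from averages with counts retained.
#'
#' @param epochs_list list of `epoch_set` objects, one per participant.
#' @param comparisons a `comparison_set`.
#' @param time_window optional `(start, end)` seconds restricting the
#'   computation (half-open).
#' @return Object of class `similarity_average`: `r` (group mean), `times`,
#'   `per_participant` (participant x time matrix), `label`,
#'   `n_comparisons` and `n_dropped` per participant.
#' @export
average_condition_series <- function(epochs_list, comparisons,
                                     time_window = NULL) {
  stopifnot(length(epochs_list) >= 1L, inherits(comparisons,
                                                "comparison_set"))
  times <- epochs_list[[1L]]$times
  idx <- if (is.null(time_window)) seq_along(times)
         else window_indices(times, time_window)
  pp <- matrix(NA_real_, length(epochs_list), length(idx))
  n_comp <- integer(length(epochs_list))
  n_drop <- integer(length(epochs_list))
  for (p in seq_along(epochs_list)) {
    ep <- epochs_list[[p]]
    ci <- comparison_indices(ep, comparisons)
    if (!length(ci$ia))
      stop("empty-condition: no available comparisons for participant ",
           format(ep$participant))
    N <- center_norm_patterns(ep$data[, idx, , drop = FALSE])
    rmat <- comparison_series_matrix(N, ci$ia, ci$ib,
                                     seq_along(idx))
    pp[p, ] <- colMeans(rmat, na.rm = TRUE)
    n_comp[p] <- length(ci$ia)
    n_drop[p] <- ci$n_dropped
  }
  structure(list(r = colMeans(pp), times = times[idx],
                 per_participant = pp, label = attr(comparisons, "label"),
                 n_comparisons = n_comp, n_dropped = n_drop),
            class = "similarity_average")
}

#' @export
print.similarity_average <- function(x, ...) {
  cat(sprintf(
    "<similarity_average> label = %s, %d participants x %d samples, mean R = %.4f\n",
    format(x$label), nrow(x$per_participant), length(x$r),
    mean(x$r, na.rm = TRUE)))
  invisible(x)
}

#' Detect the supra-threshold similarity window
#'
#' Finds the longest contiguous run of samples whose combined similarity
#' (typically the mean of the within- and between-pair group averages)
#' exceeds the threshold inside a search interval.
#'
#' @param r numeric similarity values (or a `similarity_average`).
#' @param times time axis (taken from the object when `r` is a
#'   `similarity_average`).
#' @param threshold R threshold (0.04 by default; 0.03 is the customary
#'   sensitivity setting).
#' @param search_interval optional `(start, end)` restriction in seconds.
#' @return List with `start`, `end` (first/last supra-threshold sample
#'   times), `n_samples`, `found`. When no sample exceeds the threshold,
#'   `found = FALSE` and the bounds are NA (an empty window, not an error).
#' @export
detect_window <- function(r, times = NULL, threshold = 0.04,
                          search_interval = NULL) {
  if (inherits(r, "similarity_average")) {
    times <- r$times
    r <- r$r
  }
  if (is.null(times)) times <- seq_along(r)
  keep <- if (is.null(search_interval)) seq_along(times)
          else window_indices(times, search_interval)
  above <- !is.na(r[keep]) & r[keep] > threshold
  if (!any(above))
    return(list(start = NA_real_, end = NA_real_, n_samples = 0L,
                found = FALSE))
  rl <- rle(above)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  runs <- which(rl$values)
  best <- runs[which.max(rl$lengths[runs])]
  i0 <- keep[starts[best]]; i1 <- keep[ends[best]]
  list(start = times[i0], end = times[i1],
       n_samples = i1 - i0 + 1L, found = TRUE)
}

#' Window-averaged paired test of within vs between similarity
#'
#' Averages each participant's within- and between-pair similarity over a
#' time interval and runs a two-sided paired t-test across participants.
#'
#' @param within,between `similarity_average` objects on the same
#'   participants and time axis.
#' @param interval `(start, end)` seconds (half-open); the detected
#'   supra-threshold window in the standard pipeline.
#' @return List of class `window_result`: `interval`, `mean_r_within`,
#'   `mean_r_between`, `t`, `df`, `p`, `per_participant` (two-column
#'   matrix), `degenerate`.
#' @export
window_test <- function(within, between, interval) {
  stopifnot(inherits(within, "similarity_average"),
            inherits(between, "similarity_average"))
  if (nrow(within$per_participant) != nrow(between$per_participant))
    stop("invalid-argument: same participants required in both conditions")
  idx <- window_indices(within$times, interval)
  if (!length(idx)) stop("invalid-argument: interval outside the time axis")
  w <- rowMeans(within$per_participant[, idx, drop = FALSE], na.rm = TRUE)
  b <- rowMeans(between$per_participant[, idx, drop = FALSE], na.rm = TRUE)
  tt <- paired_t(w, b)
  structure(list(interval = interval, mean_r_within = mean(w),
                 mean_r_between = mean(b), t = tt$t, df = tt$df,
                 p = tt$p, per_participant = cbind(within = w,
                                                   between = b),
                 degenerate = tt$degenerate),
            class = "window_result")
}

#' @export
print.window_result <- function(x, ...) {
  cat(sprintf(
    "<window_result> [%g, %g] s: R_within = %.4f, R_between = %.4f, t(%d) = %.3f, p = %.4g\n",
    x$interval[1L], x$interval[2L], x$mean_r_within, x$mean_r_between,
    x$df, x$t, x$p))
  invisible(x)
}

#' Order-by-pairs repeated-measures ANOVA
#'
#' 2 x 2 within-subject ANOVA with factors Order (expected-SFW-first vs
#' unexpected-SFW-first) and Pairs (within-pair vs between-pair) on
#' window-averaged similarity values.
#'
#' @param cells numeric array `n_participants x 2 x 2`; dimension 2 is
#'   Order (expected first, unexpected first), dimension 3 is Pairs
#'   (within, between).
#' @return The [rm_anova_2x2()] table (rows Order, Pairs, Order:Pairs).
#' @export
order_anova <- function(cells) {
  out <- rm_anova_2x2(cells)
  rownames(out) <- c("Order", "Pairs", "Order:Pairs")
  out
}

#' Cross-temporal spatial similarity matrix of two trials
#'
#' Correlates the across-sensor pattern of trial `a` at time i with that of
#' trial `b` at time j for all sample pairs in the analysis interval,
#' optionally Gaussian-smoothing the correlation values along both time
#' axes.
#'
#' @param a,b `sensor x time` matrices on identical axes.
#' @param times time axis in seconds.
#' @param interval `(start, end)` seconds restricting both axes.
#' @param rate sampling rate in Hz (required when smoothing).
#' @param smooth logical: apply the 40 ms / 8 ms SD Gaussian smoothing.
#' @param smooth_window,smooth_sd kernel parameters in seconds.
#' @param smooth_axes smooth along `"both"` axes or `"rows"` only.
#' @return Object of class `cross_temporal_matrix`: `r`
#'   (time x time), `times_row` (trial a), `times_col` (trial b), `label`.
#' @export
cross_temporal_matrix <- function(a, b, times, interval = NULL,
                                  rate = NULL, smooth = FALSE,
                                  smooth_window = 0.040,
                                  smooth_sd = 0.008,
                                  smooth_axes = c("both", "rows")) {
  smooth_axes <- match.arg(smooth_axes)
  if (!is.matrix(a) || !all(dim(a) == dim(b)))
    stop("invalid-argument: trials must be matrices of equal dimension")
  idx <- if (is.null(interval)) seq_along(times)
         else window_indices(times, interval)
  na <- center_norm_patterns(array(a, c(dim(a), 1L)))[, idx, 1L]
  nb <- center_norm_patterns(array(b, c(dim(b), 1L)))[, idx, 1L]
  M <- crossprod(na, nb)
  if (smooth) {
    if (is.null(rate)) rate <- 1 / mean(diff(times))
    M <- smooth_matrix(M, rate, smooth_window, smooth_sd, smooth_axes)
  }
  structure(list(r = M, times_row = times[idx], times_col = times[idx],
                 label = NA), class = "cross_temporal_matrix")
}

# Gaussian-smooth a matrix along rows (axis 1) or both axes.
smooth_matrix <- function(M, rate, window = 0.040, sd = 0.008,
                          axes = "both") {
  M2 <- gaussian_smooth(M, rate, window, sd)
  if (axes == "both")
    M2 <- t(gaussian_smooth(t(M2), rate, window, sd))
  M2
}

#' Condition-averaged cross-temporal similarity matrices
#'
#' Per participant, averages the cross-temporal matrices of all
#' comparisons in the set (raw r values), smoothing the averaged matrix;
#' also returns the group mean.
#'
#' @param epochs_list list of `epoch_set` objects (typically already
#'   resampled to 300 Hz).
#' @param comparisons a `comparison_set`.
#' @param interval `(start, end)` seconds for both time axes (customarily
#'   SFW-1 onset to SFW onset).
#' @param smooth logical: Gaussian smoothing of the averaged correlation
#'   values (40 ms window, 8 ms SD by default).
#' @param smooth_window,smooth_sd,smooth_axes see
#'   [cross_temporal_matrix()].
#' @return List of class `cross_temporal_average`: `mean` (time x time
#'   group matrix), `per_participant` (participant x time x time array),
#'   `times`, `label`, `n_comparisons`.
#' @export
cross_temporal_average <- function(epochs_list, comparisons, interval,
                                   smooth = TRUE, smooth_window = 0.040,
                                   smooth_sd = 0.008,
                                   smooth_axes = "both") {
  stopifnot(length(epochs_list) >= 1L)
  times <- epochs_list[[1L]]$times
  rate <- sampling_rate(epochs_list[[1L]])
  idx <- window_indices(times, interval)
  np <- length(epochs_list)
  arr <- array(NA_real_, c(np, length(idx), length(idx)))
  n_comp <- integer(np)
  for (p in seq_len(np)) {
    ep <- epochs_list[[p]]
    ci <- comparison_indices(ep, comparisons)
    if (!length(ci$ia))
      stop("empty-condition: no available comparisons for participant ",
           format(ep$participant))
    N <- center_norm_patterns(ep$data[, idx, , drop = FALSE])
    acc <- matrix(0, length(idx), length(idx))
    cnt <- matrix(0, length(idx), length(idx))
    for (k in seq_along(ci$ia)) {
      M <- crossprod(N[, , ci$ia[k]], N[, , ci$ib[k]])
      good <- !is.na(M)
      M[!good] <- 0
      acc <- acc + M
      cnt <- cnt + good
    }
    avg <- acc / pmax(cnt, 1)
    avg[cnt == 0] <- NA_real_
    if (smooth)
      avg <- smooth_matrix(avg, rate, smooth_window, smooth_sd,
                           smooth_axes)
    arr[p, , ] <- avg
    n_comp[p] <- length(ci$ia)
  }
  structure(list(mean = apply(arr, c(2L, 3L), mean),
                 per_participant = arr, times = times[idx],
                 label = attr(comparisons, "label"),
                 n_comparisons = n_comp),
            class = "cross_temporal_average")
}

#' @export
print.cross_temporal_average <- function(x, ...) {
  cat(sprintf(
    "<cross_temporal_average> label = %s, %d participants, %d x %d cells\n",
    format(x$label), dim(x$per_participant)[1L], dim(x$mean)[1L],
    dim(x$mean)[2L]))
  invisible(x)
}
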