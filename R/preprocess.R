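# Signal conditioning ahead of the RSA stages. All operations act per
# trial and per sensor (or per series) and never mix trials.

# Apply a function over the time dimension of an epoch_set or a plain
# matrix/array, returning the same container type.
map_time_series <- function(x, fun, new_times = NULL) {
  if (inherits(x, "epoch_set")) {
    d <- dim(x$data)
    m <- matrix(aperm(x$data, c(2L, 1L, 3L)), nrow = d[2L])
    out <- fun(m)
    times <- if (is.null(new_times)) x$times else new_times
    arr <- aperm(array(out, c(length(times), d[1L], d[3L])), c(2L, 1L, 3L))
    epoch_set(arr, times, x$sensor_ids, x$trials, x$participant)
  } else if (is.matrix(x)) {
    fun(x)
  } else {
    drop(fun(matrix(x, ncol = 1L)))
  }
}

#' Remove a linear trend from every sensor time series
#'
#' Per trial and per sensor, the least-squares line over the epoch is
#' subtracted.
#'
#' @param x an `epoch_set`, or a matrix with time along rows (each column a
#'   series), or a numeric vector.
#' @return Same type as the input, detrended.
#' @export
detrend_linear <- function(x) {
  map_time_series(x, function(m) {
    n <- nrow(m)
    if (n < 2L) stop("need at least 2 time samples")
    tc <- seq_len(n) - (n + 1) / 2
    ss <- sum(tc * tc)
    slope <- drop(crossprod(tc, m)) / ss
    mu <- colMeans(m)
    m - outer(tc, slope) - rep(mu, each = n)
  })
}

#' Zero-phase Butterworth low-pass filter
#'
#' A digital Butterworth filter applied forward and backward
#' (`signal::filtfilt`), giving zero phase distortion and squaring the
#' magnitude response (order-4 default: >= 48 dB attenuation at twice the
#' cutoff).
#'
#' @param x an `epoch_set`, matrix (time along rows) or vector.
#' @param cutoff cutoff frequency in Hz.
#' @param rate sampling rate in Hz; taken from the `epoch_set` when omitted.
#' @param order filter order (before the forward-backward doubling).
#' @return Filtered data, same type as the input.
#' @export
lowpass <- function(x, cutoff, rate = NULL, order = 4L) {
  if (inherits(x, "epoch_set")) rate <- sampling_rate(x)
  if (is.null(rate)) stop("`rate` is required for non-epoch input")
  if (cutoff <= 0 || cutoff >= rate / 2)
    stop("invalid-argument: cutoff must lie in (0, Nyquist)")
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  map_time_series(x, function(m) {
    apply(m, 2L, function(v) zero_phase_filter(bf, v))
  })
}

# Forward-backward IIR filtering: the mean is removed first (exact DC
# gain) and odd-reflection edge padding suppresses the start-up
# transients of the IIR recursion.
zero_phase_filter <- function(bf, x) {
  n <- length(x)
  mu <- mean(x)
  x <- x - mu
  k <- min(n - 1L, 30L * (length(bf$a) + length(bf$b)))
  pre <- 2 * x[1L] - x[(k + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - k)]
  y <- as.numeric(signal::filter(bf, c(pre, x, post)))
  y <- rev(as.numeric(signal::filter(bf, rev(y))))
  y[(k + 1L):(k + n)] + mu
}

#' Resample epochs to a lower rate
#'
#' Anti-alias filters (zero-phase Butterworth at 80% of the new Nyquist)
#' and then picks samples on a new uniform grid. The time grid follows the
#' half-open convention `[start, start + n/rate)`: 4.0 s at 300 Hz is 1200
#' samples. Integer decimation factors keep original samples; non-integer
#' factors use linear interpolation of the filtered signal.
#'
#' @param x an `epoch_set`.
#' @param target_rate new sampling rate in Hz (must not exceed the current
#'   rate; no upsampling).
#' @return An `epoch_set` on the new time grid.
#' @export
resample_epochs <- function(x, target_rate) {
  stopifnot(inherits(x, "epoch_set"))
  rate <- sampling_rate(x)
  if (target_rate > rate * (1 + 1e-9))
    stop("invalid-argument: no upsampling (target rate above source rate)")
  if (abs(target_rate - rate) < 1e-9 * rate) return(x)
  n_old <- length(x$times)
  t0 <- x$times[1L]
  n_new <- round(n_old * target_rate / rate)
  new_times <- t0 + (seq_len(n_new) - 1L) / target_rate
  filt <- lowpass(x, cutoff = 0.8 * target_rate / 2)
  fac <- rate / target_rate
  if (abs(fac - round(fac)) < 1e-9) {
    idx <- seq(1L, by = round(fac), length.out = n_new)
    out <- filt$data[, idx, , drop = FALSE]
  } else {
    d <- dim(filt$data)
    out <- array(apply(filt$data, c(1L, 3L), function(v)
      stats::approx(x$times, v, xout = new_times, rule = 2L)$y),
      c(n_new, d[1L], d[3L]))
    out <- aperm(out, c(2L, 1L, 3L))
  }
  epoch_set(out, new_times, x$sensor_ids, x$trials, x$participant)
}

#' Gaussian temporal smoothing
#'
#' Convolves a series with a truncated Gaussian kernel (support `window`
#' seconds, standard deviation `sd` seconds), renormalized so the weights
#' over the available support sum to 1 -- constants pass through unchanged,
#' including at the edges.
#'
#' @param x numeric vector, or matrix smoothed along rows (each column a
#'   series).
#' @param rate sampling rate of the series in Hz.
#' @param window kernel support in seconds.
#' @param sd kernel standard deviation in seconds.
#' @return Smoothed data, same shape as the input.
#' @export
gaussian_smooth <- function(x, rate, window = 0.040, sd = 0.008) {
  stopifnot(window > 0, sd > 0, window >= 2 * sd)
  half <- floor(window * rate / 2)
  k <- stats::dnorm(seq(-half, half), sd = sd * rate)
  k <- k / sum(k)
  vec <- !is.matrix(x)
  m <- if (vec) matrix(x, ncol = 1L) else x
  n <- nrow(m)
  if (n < length(k)) stop("invalid-argument: kernel longer than series")
  pad <- function(mm) rbind(matrix(0, half, ncol(mm)), mm,
                            matrix(0, half, ncol(mm)))
  sm <- apply(pad(m), 2L, function(v)
    stats::filter(v, k, sides = 2L)[(half + 1L):(half + n)])
  wt <- stats::filter(c(rep(0, half), rep(1, n), rep(0, half)), k,
                      sides = 2L)[(half + 1L):(half + n)]
  out <- sm / wt
  if (vec) drop(out) else out
}
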