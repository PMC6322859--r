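# Source-level RSA: sensor covariance estimation, LCMV beamformer
# filters, SVD orientation selection, and temporal RSA on the
# reconstructed grid-point time series.

#' Sensor covariance over an estimation window
#'
#' Averages over trials the within-window sample covariance of the sensors
#' (per-trial, per-sensor mean removed).
#'
#' @param epochs an `epoch_set` (customarily 30 Hz low-passed and linearly
#'   detrended beforehand).
#' @param window `(start, end)` seconds, half-open; SFW-1 onset to 1 s
#'   after SFW onset in the standard pipeline.
#' @return Object of class `covariance_estimate`: `C` (sensor x sensor),
#'   `window`, `n_trials`, `n_samples`, `ill_conditioned` flag (fewer
#'   within-window samples than sensors).
#' @export
estimate_covariance <- function(epochs, window) {
  stopifnot(inherits(epochs, "epoch_set"))
  idx <- window_indices(epochs$times, window)
  if (length(idx) < 2L) stop("invalid-argument: window too short")
  d <- dim(epochs$data)
  if (d[3L] < 2L) stop("invalid-argument: need >= 2 trials")
  ns <- d[1L]
  C <- matrix(0, ns, ns)
  for (tr in seq_len(d[3L])) {
    X <- epochs$data[, idx, tr]
    X <- X - rowMeans(X)
    C <- C + tcrossprod(X) / (length(idx) - 1L)
  }
  C <- C / d[3L]
  C <- (C + t(C)) / 2
  structure(list(C = C, window = window, n_trials = d[3L],
                 n_samples = length(idx),
                 ill_conditioned = length(idx) * d[3L] < ns),
            class = "covariance_estimate")
}

#' @export
print.covariance_estimate <- function(x, ...) {
  cat(sprintf(
    "<covariance_estimate> %d sensors, window [%g, %g) s, %d trials%s\n",
    nrow(x$C), x$window[1L], x$window[2L], x$n_trials,
    if (x$ill_conditioned) " (ill-conditioned)" else ""))
  invisible(x)
}

#' LCMV beamformer filters
#'
#' For every grid point g with 3-column lead field L_g, the linearly
#' constrained minimum variance filter
#' `W_g = (L_g' C^-1 L_g)^-1 L_g' C^-1` with
#' `C = C_data + lambda * mean(diag(C_data)) * I`. At `lambda = 0` the
#' unit-gain property `W_g L_g = I_3` holds. When `lambda = 0` and the
#' covariance condition number exceeds 1e8, a 5% regularization is applied
#' automatically (recorded in the result).
#'
#' @param forward a `forward_model`.
#' @param cov a `covariance_estimate` (or plain matrix).
#' @param lambda regularization fraction of the mean diagonal.
#' @return Object of class `beamformer_filters`: `W` (list of 3 x n_sensor
#'   matrices), `lambda` (as used), `ok` (logical per grid point; points
#'   with singular `L' C^-1 L` are flagged and excluded downstream).
#' @export
lcmv_filters <- function(forward, cov, lambda = 0) {
  stopifnot(inherits(forward, "forward_model"))
  C <- if (inherits(cov, "covariance_estimate")) cov$C else cov
  ns <- nrow(C)
  kappa_c <- kappa(C, exact = FALSE)
  if (lambda == 0 && (!is.finite(kappa_c) || kappa_c > 1e8))
    lambda <- 0.05
  Creg <- C + lambda * mean(diag(C)) * diag(ns)
  Cinv <- tryCatch(chol2inv(chol(Creg)),
                   error = function(e) solve(Creg))
  ng <- nrow(forward$grid_positions)
  W <- vector("list", ng)
  ok <- logical(ng)
  for (g in seq_len(ng)) {
    L <- gain_block(forward, g)
    LtCi <- crossprod(L, Cinv)
    M <- LtCi %*% L
    Wg <- tryCatch(solve(M, LtCi), error = function(e) NULL)
    if (is.null(Wg) || !all(is.finite(Wg))) {
      ok[g] <- FALSE
    } else {
      W[[g]] <- Wg
      ok[g] <- TRUE
    }
  }
  structure(list(W = W, ok = ok, lambda = lambda, forward = forward),
            class = "beamformer_filters")
}

#' @export
print.beamformer_filters <- function(x, ...) {
  cat(sprintf(
    "<beamformer_filters> %d grid points (%d usable), lambda = %g\n",
    length(x$W), sum(x$ok), x$lambda))
  invisible(x)
}

#' Project sensor epochs to scalar source time series
#'
#' Applies each grid point's 3 x n_sensor filter to every trial, then
#' reduces the 3-orientation time series to a scalar by projecting along
#' the direction explaining most variance (first left singular vector of
#' the 3 x T series concatenated over the participant's trials, sign fixed
#' so its largest-magnitude entry is positive).
#'
#' @param filters a `beamformer_filters`.
#' @param epochs an `epoch_set`.
#' @return An `epoch_set` of virtual channels: one "sensor" per usable
#'   grid point (ids `grid<k>`), same times and trials.
#' @export
project_orientation <- function(filters, epochs) {
  stopifnot(inherits(filters, "beamformer_filters"),
            inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  use <- which(filters$ok)
  nt <- d[2L]; ntr <- d[3L]
  flat <- matrix(epochs$data, d[1L])          # sensor x (time*trial)
  out <- array(0, c(length(use), nt, ntr))
  for (k in seq_along(use)) {
    g <- use[k]
    S <- filters$W[[g]] %*% flat              # 3 x (time*trial)
    if (all(abs(S) < .Machine$double.eps)) next  # zero source: flagged 0
    u <- svd(S, nu = 1L, nv = 0L)$u[, 1L]
    if (u[which.max(abs(u))] < 0) u <- -u
    out[k, , ] <- crossprod(u, S)
  }
  epoch_set(out, epochs$times, sprintf("grid%03d", use), epochs$trials,
            epochs$participant)
}

#' Source-level temporal RSA
#'
#' Runs the temporal similarity analysis on beamformer-projected virtual
#' channels: per-grid-point within- and between-pair averaged maps and
#' their difference.
#'
#' @param projected_list list of projected `epoch_set` objects (from
#'   [project_orientation()]), one per participant.
#' @param within,between `comparison_set`s.
#' @param window `(start, end)` seconds.
#' @return List of class `source_rsa_result`: `within`, `between`
#'   (`map_average` objects over grid points), `difference` (group mean
#'   within - between per grid point).
#' @export
source_temporal_rsa <- function(projected_list, within, between, window) {
  mw <- average_condition_maps(projected_list, within, window)
  mb <- average_condition_maps(projected_list, between, window)
  structure(list(within = mw, between = mb,
                 difference = mw$r - mb$r,
                 sensor_ids = mw$sensor_ids, window = window),
            class = "source_rsa_result")
}

#' @export
print.source_rsa_result <- function(x, ...) {
  cat(sprintf(
    "<source_rsa_result> %d grid points, window [%g, %g) s, peak diff %.4f at %s\n",
    length(x$difference), x$window[1L], x$window[2L],
    max(x$difference, na.rm = TRUE),
    x$sensor_ids[which.max(x$difference)]))
  invisible(x)
}

#' Peak region of a difference map within a cluster
#'
#' Grid points inside the cluster whose difference value is at least
#' `fraction` of the cluster's maximum (the 85%-of-maximum peak
#' characterization).
#'
#' @param difference numeric difference values per grid point.
#' @param cluster integer indices of the cluster's members (nonempty).
#' @param fraction peak fraction (default 0.85).
#' @return Integer indices of the peak region (subset of `cluster`).
#' @export
peak_region <- function(difference, cluster, fraction = 0.85) {
  if (!length(cluster)) stop("invalid-argument: empty cluster")
  vals <- difference[cluster]
  cluster[vals >= fraction * max(vals)]
}
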