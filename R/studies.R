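# Simulation studies: type-I error of the window test, familywise error of
# the cluster tests, parameter recovery, diagonal specificity of the
# cross-temporal effect, beamformer correctness, and the fidelity of the
# sampled sign-flip null. These are the package's reproducibility surface:
# the same functions back the test suite and scripts/acceptance.R.

#' Study-scale simulation configuration
#'
#' The desk-scale study condition used by the simulation studies: 12
#' participants, 40 pairs, 64 sensors at 300 Hz, epochs spanning the 1-s
#' prediction interval before SFW onset (one word onset at -1 s), with the
#' item-specific effect in its default -880...-485 ms window.
#'
#' @param seed integer seed.
#' @param ... overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
study_config <- function(seed = 1L, ...) {
  args <- list(n_participants = 12L, n_pairs = 40L, n_sensors = 64L,
               sample_rate = 300, epoch_window = c(-1, 0),
               word_onsets = -1, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

derive_seeds <- function(seed, n) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sample.int(2^30, n)
}

#' Type-I error of the window test on null simulations
#'
#' Simulates datasets with no item-specific signal (identity amplitude 0),
#' runs the within- vs between-pair window test on the effect window, and
#' reports the rejection rate at `alpha`. Calibration puts the rate inside
#' the binomial interval around `alpha`.
#'
#' @param n_runs number of null datasets.
#' @param seed integer seed.
#' @param alpha nominal level.
#' @param config base configuration (identity amplitude is forced to 0).
#'   The default epochs cover just the tested effect window; the
#'   between-pair comparisons are count-matched to the within-pair ones.
#' @return List with `rejection_rate`, `p_values`, `alpha`, `n_runs`.
#' @export
study_type1_window <- function(n_runs = 200L, seed = 1L, alpha = 0.05,
                               config = study_config(
                                 epoch_window = c(-0.95, -0.45))) {
  seeds <- derive_seeds(seed, 2L * n_runs)
  ew <- config$effect_window
  p_values <- vapply(seq_len(n_runs), function(i) {
    cfg <- config
    cfg$identity_amplitude <- 0
    cfg$seed <- seeds[i]
    sim <- simulate_dataset(cfg)
    within <- enumerate_within(sim$design)
    between <- subsample_between(enumerate_between(sim$design),
                                 nrow(within), seed = seeds[n_runs + i])
    aw <- average_condition_series(sim$epochs, within, time_window = ew)
    ab <- average_condition_series(sim$epochs, between, time_window = ew)
    window_test(aw, ab, ew)$p
  }, numeric(1L))
  list(rejection_rate = mean(p_values < alpha), p_values = p_values,
       alpha = alpha, n_runs = n_runs)
}

#' Familywise error of the cluster permutation tests on null simulations
#'
#' Simulates null datasets (no item signal) and runs either the
#' sensor-level cluster test on temporal-similarity maps or the
#' cross-temporal matrix cluster test; the familywise error is the
#' fraction of runs with any significant cluster (both tails).
#'
#' @param kind `"sensor"` or `"matrix"`.
#' @param n_runs number of null datasets.
#' @param n_perm permutations per test.
#' @param seed integer seed.
#' @param config base configuration. The matrix study defaults to a
#'   coarser setting (20 pairs, 32 sensors, 100 Hz) so the time-by-time
#'   matrices stay desk-sized.
#' @return List with `fwe_rate`, `any_significant`, `n_runs`, `n_perm`.
#' @export
study_fwe_cluster <- function(kind = c("sensor", "matrix"),
                              n_runs = 100L, n_perm = 200L, seed = 1L,
                              config = NULL) {
  kind <- match.arg(kind)
  if (is.null(config))
    config <- if (kind == "sensor")
                study_config(epoch_window = c(-0.95, -0.45))
              else study_config(n_pairs = 20L, n_sensors = 32L,
                                sample_rate = 100)
  seeds <- derive_seeds(seed, 2L * n_runs)
  ew <- config$effect_window
  hits <- vapply(seq_len(n_runs), function(i) {
    cfg <- config
    cfg$identity_amplitude <- 0
    cfg$seed <- seeds[i]
    sim <- simulate_dataset(cfg)
    within <- enumerate_within(sim$design)
    between <- subsample_between(enumerate_between(sim$design),
                                 nrow(within), seed = seeds[n_runs + i])
    res <- if (kind == "sensor") {
      mw <- average_condition_maps(sim$epochs, within, ew)
      mb <- average_condition_maps(sim$epochs, between, ew)
      graph <- neighbor_graph(sim$layout, radius = 40)
      sensor_cluster_test(mw$per_participant, mb$per_participant, graph,
                          n_perm = n_perm, seed = seeds[n_runs + i])
    } else {
      cw <- cross_temporal_average(sim$epochs, within,
                                   config$epoch_window)
      cb <- cross_temporal_average(sim$epochs, between,
                                   config$epoch_window)
      matrix_cluster_test(cw$per_participant, cb$per_participant,
                          times_row = cw$times, times_col = cw$times,
                          n_perm = n_perm, seed = seeds[n_runs + i])
    }
    length(significant_clusters(res)) > 0L
  }, logical(1L))
  list(fwe_rate = mean(hits), any_significant = hits, n_runs = n_runs,
       n_perm = n_perm, kind = kind)
}

#' Parameter recovery of the embedded within-pair effect
#'
#' Simulates datasets with the study-condition item signal, auto-detects
#' the supra-threshold window from the combined similarity series, and
#' tests within > between over the detected window. Reports detection
#' power and the overlap of the detected window with the embedded effect
#' window.
#'
#' @param n_runs number of datasets.
#' @param seed integer seed.
#' @param config base configuration (identity amplitude at its default).
#' @param threshold window-detection R threshold.
#' @return List with `power` (fraction of runs with directional p < 0.05),
#'   `mean_overlap` (fraction of the embedded window covered by the
#'   detected window), `overlaps`, `p_values`, `windows`.
#' @export
study_recovery <- function(n_runs = 50L, seed = 1L,
                           config = study_config(), threshold = 0.04) {
  seeds <- derive_seeds(seed, n_runs)
  ew <- config$effect_window
  p_values <- numeric(n_runs)
  overlaps <- numeric(n_runs)
  windows <- matrix(NA_real_, n_runs, 2L)
  for (i in seq_len(n_runs)) {
    cfg <- config
    cfg$seed <- seeds[i]
    sim <- simulate_dataset(cfg)
    within <- enumerate_within(sim$design)
    between <- subsample_between(enumerate_between(sim$design),
                                 nrow(within), seed = seeds[i])
    aw <- average_condition_series(sim$epochs, within)
    ab <- average_condition_series(sim$epochs, between)
    combined <- (aw$r + ab$r) / 2
    dw <- detect_window(combined, aw$times, threshold,
                        search_interval = cfg$epoch_window)
    if (dw$found) {
      windows[i, ] <- c(dw$start, dw$end)
      lo <- max(dw$start, ew[1L]); hi <- min(dw$end, ew[2L])
      overlaps[i] <- max(0, hi - lo) / diff(ew)
      wt <- window_test(aw, ab, c(dw$start, dw$end))
      p_values[i] <- if (wt$t > 0) wt$p else 1
    } else {
      overlaps[i] <- 0
      p_values[i] <- 1
    }
  }
  list(power = mean(p_values < 0.05), mean_overlap = mean(overlaps),
       overlaps = overlaps, p_values = p_values, windows = windows)
}

#' Diagonal specificity of the cross-temporal effect
#'
#' With a dynamic item pattern (lifetime `identity_tau`), the within- vs
#' between-pair difference in the cross-temporal matrices should be
#' confined to the diagonal: significant cluster cells should have a mean
#' |row - col| lag below the pattern lifetime.
#'
#' @param n_runs number of datasets.
#' @param seed integer seed.
#' @param config base configuration; defaults to a dynamic-pattern
#'   variant of the study condition (20 pairs, 32 sensors).
#' @param n_perm permutations per test.
#' @return List with `mean_lag_s` (cell-weighted mean |lag| of significant
#'   cluster cells across runs), `lifetime_s`, `n_significant_cells`,
#'   per-run `lags`.
#' @export
study_diagonal <- function(n_runs = 3L, seed = 1L, config = NULL,
                           n_perm = 200L) {
  if (is.null(config))
    config <- study_config(n_pairs = 20L, n_sensors = 32L,
                           identity_mode = "dynamic",
                           identity_amplitude = 0.8)
  seeds <- derive_seeds(seed, 2L * n_runs)
  lags <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    cfg <- config
    cfg$seed <- seeds[i]
    sim <- simulate_dataset(cfg)
    within <- enumerate_within(sim$design)
    between <- subsample_between(enumerate_between(sim$design),
                                 nrow(within), seed = seeds[n_runs + i])
    cw <- cross_temporal_average(sim$epochs, within, cfg$epoch_window)
    cb <- cross_temporal_average(sim$epochs, between, cfg$epoch_window)
    res <- matrix_cluster_test(cw$per_participant, cb$per_participant,
                               times_row = cw$times,
                               times_col = cw$times, n_perm = n_perm,
                               seed = seeds[n_runs + i])
    cells <- unlist(lapply(significant_clusters(res), function(cl) {
      if (cl$sign < 0) return(numeric(0))
      nr <- res$dim[1L]
      ri <- (cl$cells - 1L) %% nr + 1L
      ci <- (cl$cells - 1L) %/% nr + 1L
      abs(res$times_row[ri] - res$times_col[ci])
    }))
    lags[[i]] <- cells
  }
  all_lags <- unlist(lags)
  list(mean_lag_s = mean(all_lags), lifetime_s = config$identity_tau,
       n_significant_cells = length(all_lags), lags = lags)
}

#' Beamformer correctness checks
#'
#' Three checks on a toy grid: (1) the unit-gain property `W L = I` at
#' zero regularization under a well-conditioned covariance; (2) noiseless
#' single-source recovery -- the grid point with maximal reconstructed
#' variance is the true source and the reconstructed time course matches
#' the injected waveform; (3) on noisy multi-pair datasets, the
#' source-level RSA difference map peaks at an injected source point.
#'
#' @param n_runs noisy-recovery runs.
#' @param seed integer seed.
#' @param n_grid grid size (toy scale, <= 50).
#' @param n_sensors sensors on the shell.
#' @return List with `unit_gain_error` (max |W L - I| over grid points),
#'   `noiseless_correlation` (|corr| of reconstructed vs injected
#'   waveform at the true point), `noiseless_peak_correct`,
#'   `peak_hit_rate` (fraction of noisy runs whose difference map peaks
#'   at an injected point), `hits`.
#' @export
study_beamformer <- function(n_runs = 50L, seed = 1L, n_grid = 30L,
                             n_sensors = 32L) {
  seeds <- derive_seeds(seed, n_runs + 3L)
  layout <- make_sensor_layout(n_sensors, seed = seeds[n_runs + 1L])
  fwd <- make_forward_model(n_grid, layout, seed = seeds[n_runs + 2L])

  # (1) unit gain under a well-conditioned covariance
  cfg0 <- study_config(n_participants = 1L, n_pairs = 4L,
                       n_sensors = n_sensors,
                       identity_amplitude = 0, seed = seeds[n_runs + 3L])
  sim0 <- simulate_dataset(cfg0, layout = layout)
  cov0 <- estimate_covariance(sim0$epochs[[1L]], cfg0$epoch_window)
  flt0 <- lcmv_filters(fwd, cov0, lambda = 0)
  unit_gain_error <- max(vapply(which(flt0$ok), function(g)
    max(abs(flt0$W[[g]] %*% gain_block(fwd, g) - diag(3))),
    numeric(1L)))

  # (2) noiseless single-source recovery
  cfg1 <- study_config(n_participants = 1L, n_pairs = 1L,
                       n_sensors = n_sensors, evoked_amplitude = 0,
                       noise_sd = 0, identity_amplitude = 1,
                       seed = seeds[n_runs + 3L])
  true_pt <- as.integer(ceiling(n_grid / 2))
  sim1 <- simulate_from_sources(fwd, true_pt, cfg1, layout)
  cov1 <- estimate_covariance(sim1$epochs[[1L]], cfg1$epoch_window)
  flt1 <- lcmv_filters(fwd, cov1)
  proj1 <- project_orientation(flt1, sim1$epochs[[1L]])
  ew <- cfg1$effect_window
  idx <- window_indices(proj1$times, ew)
  vars <- apply(proj1$data[, idx, 1L], 1L, stats::var)
  peak_idx <- which(flt1$ok)[which.max(vars)]
  wf <- sim1$ground_truth$participants[[1L]]$identity_waveforms[idx, 1L]
  rec <- proj1$data[match(true_pt, which(flt1$ok)), idx, 1L]
  noiseless_correlation <- abs(stats::cor(rec, wf))

  # (3) noisy recovery of the difference-map peak. Correlation maps are
  # scale-invariant, so beamformer leakage blurs them by about one grid
  # step: a hit is the peak landing at an injected point or one of its
  # face neighbours.
  n_src_pairs <- 4L
  peak_dist <- vapply(seq_len(n_runs), function(i) {
    cfg <- study_config(n_participants = 8L, n_pairs = n_src_pairs,
                        n_sensors = n_sensors, identity_amplitude = 1.5,
                        seed = seeds[i])
    pts <- round(seq(1L, n_grid, length.out = n_src_pairs))
    sim <- simulate_from_sources(fwd, pts, cfg, layout)
    projected <- lapply(sim$epochs, function(ep) {
      cov <- estimate_covariance(ep, cfg$epoch_window)
      project_orientation(lcmv_filters(fwd, cov), ep)
    })
    within <- enumerate_within(sim$design)
    between <- subsample_between(enumerate_between(sim$design),
                                 nrow(within), seed = seeds[i])
    srsa <- source_temporal_rsa(projected, within, between,
                                cfg$effect_window)
    peak <- which.max(srsa$difference)
    min(sqrt(colSums((t(fwd$grid_positions[pts, , drop = FALSE]) -
                        fwd$grid_positions[peak, ])^2)))
  }, numeric(1L))
  hits <- peak_dist <= 1.1 * fwd$grid_spacing

  list(unit_gain_error = unit_gain_error,
       noiseless_correlation = noiseless_correlation,
       noiseless_peak_correct = peak_idx == true_pt,
       peak_hit_rate = mean(hits),
       peak_exact_rate = mean(peak_dist < 1),
       peak_dist_mm = peak_dist, hits = hits)
}

#' Fidelity of the sampled sign-flip null
#'
#' Compares the sampled permutation null of a mean-difference statistic
#' with the exhaustive 2^n sign-flip null for a small participant count:
#' the Kolmogorov-Smirnov distance between the two distributions.
#'
#' @param n_participants number of participants (<= 12).
#' @param seed integer seed.
#' @param n_perm_factor sampled permutations per exhaustive pattern.
#' @return List with `ks_distance`, `n_exhaustive`, `n_perm`.
#' @export
study_perm_null <- function(n_participants = 8L, seed = 1L,
                            n_perm_factor = 10L) {
  stopifnot(n_participants <= 12L)
  seeds <- derive_seeds(seed, 2L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seeds[1L])
  d <- stats::rnorm(n_participants, mean = 0.3)
  n_ex <- 2L^n_participants
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n_participants)))
  exhaustive <- as.vector(signs %*% d) / n_participants
  n_perm <- n_perm_factor * n_ex
  sampled <- permutation_null(d, statistic = mean, n_perm = n_perm,
                              seed = seeds[2L])$null
  grid <- sort(unique(c(exhaustive, sampled)))
  F1 <- stats::ecdf(exhaustive)(grid)
  F2 <- stats::ecdf(sampled)(grid)
  list(ks_distance = max(abs(F1 - F2)), n_exhaustive = n_ex,
       n_perm = n_perm)
}
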