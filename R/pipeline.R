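# Top-level pipeline: simulate -> preprocess -> spatial RSA (window
# auto-detection) -> temporal RSA -> source RSA, with a run manifest.

#' Run the full analysis pipeline on a simulated dataset
#'
#' Chains the stages in the order the analyses depend on each other:
#' simulation (or a supplied dataset), linear detrending plus 30 Hz
#' low-pass plus resampling to the analysis rate, within/between spatial
#' similarity averaging with supra-threshold window detection, the
#' window-averaged paired test, cross-temporal matrices with their cluster
#' permutation test, sensor-level temporal RSA with the 40 mm
#' neighborhood cluster test, and (optionally) LCMV source-level temporal
#' RSA with the grid cluster test. The detected spatial-similarity window
#' is reused by the temporal and source stages.
#'
#' @param config a [sim_config()].
#' @param dataset optional `meg_simulation` to analyse instead of
#'   simulating from `config`.
#' @param lowpass_hz low-pass cutoff (Hz); skipped when at or above
#'   Nyquist.
#' @param analysis_rate rate (Hz) the similarity analyses run at.
#' @param threshold R threshold for window detection.
#' @param window manual `(start, end)` override; `NULL` auto-detects.
#' @param search_interval interval (s) searched for the supra-threshold
#'   window (SFW-1 onset to SFW onset by default).
#' @param n_perm permutations for all cluster tests.
#' @param sensor_radius_mm sensor neighborhood radius.
#' @param do_source run the LCMV source stage.
#' @param n_grid source grid size for the toy forward model.
#' @param seed integer seed for the analysis-stage randomness (between-pair
#'   matching subsample, permutations).
#' @param out_dir optional directory; results, design and layout are
#'   written there and checksummed into the manifest.
#' @return List of class `megrsa_pipeline` with elements `window`,
#'   `window_test`, `spatial` (condition averages), `matrix_test`,
#'   `sensor_maps`, `sensor_test`, `source` (when run), and `manifest`.
#' @export
run_pipeline <- function(config = sim_config(), dataset = NULL,
                         lowpass_hz = 30, analysis_rate = 300,
                         threshold = 0.04, window = NULL,
                         search_interval = c(-1, 0), n_perm = 1000L,
                         sensor_radius_mm = 40, do_source = TRUE,
                         n_grid = 20L, seed = 1L, out_dir = NULL) {
  t0 <- Sys.time()
  sim <- if (is.null(dataset)) simulate_dataset(config) else dataset
  config <- sim$config

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  seeds <- sample.int(2^30, 4L)

  # -- preprocess ---------------------------------------------------------
  rate <- sampling_rate(sim$epochs[[1L]])
  epochs <- lapply(sim$epochs, function(ep) {
    ep <- detrend_linear(ep)
    if (lowpass_hz < rate / 2) ep <- lowpass(ep, lowpass_hz)
    if (analysis_rate < rate) ep <- resample_epochs(ep, analysis_rate)
    ep
  })

  # -- comparison sets ----------------------------------------------------
  within <- enumerate_within(sim$design)
  between <- enumerate_between(sim$design)
  between_matched <- subsample_between(between, nrow(within),
                                       seed = seeds[1L])

  # -- spatial RSA --------------------------------------------------------
  avg_w <- average_condition_series(epochs, within)
  avg_b <- average_condition_series(epochs, between_matched)
  combined <- (avg_w$r + avg_b$r) / 2
  win <- if (is.null(window)) {
    dw <- detect_window(combined, avg_w$times, threshold,
                        search_interval)
    if (!dw$found)
      stop("no supra-threshold spatial-similarity window found; ",
           "supply `window` manually")
    c(dw$start, dw$end)
  } else window
  wt <- window_test(avg_w, avg_b, win)

  interval <- search_interval
  ctm_w <- cross_temporal_average(epochs, within, interval)
  ctm_b <- cross_temporal_average(epochs, between_matched, interval)
  mtest <- matrix_cluster_test(ctm_w$per_participant,
                               ctm_b$per_participant,
                               times_row = ctm_w$times,
                               times_col = ctm_w$times,
                               n_perm = n_perm, seed = seeds[2L])

  # -- temporal RSA (sensor level) ---------------------------------------
  map_w <- average_condition_maps(epochs, within, win)
  map_b <- average_condition_maps(epochs, between_matched, win)
  graph <- neighbor_graph(sim$layout, radius = sensor_radius_mm)
  stest <- sensor_cluster_test(map_w$per_participant,
                               map_b$per_participant, graph,
                               n_perm = n_perm, seed = seeds[3L])

  # -- source RSA ---------------------------------------------------------
  source_res <- NULL
  if (do_source) {
    fwd <- if (!is.null(sim$forward)) sim$forward
           else make_forward_model(n_grid, sim$layout, seed = seeds[4L])
    cov_win <- c(max(min(epochs[[1L]]$times), -1),
                 min(max(epochs[[1L]]$times), 1))
    projected <- lapply(epochs, function(ep) {
      cov <- estimate_covariance(ep, cov_win)
      project_orientation(lcmv_filters(fwd, cov), ep)
    })
    srsa <- source_temporal_rsa(projected, within, between_matched, win)
    gtest <- grid_cluster_test(srsa$within$per_participant,
                               srsa$between$per_participant, fwd,
                               n_perm = n_perm, seed = seeds[4L])
    sig <- significant_clusters(gtest)
    peak <- if (length(sig))
      peak_region(srsa$difference, sig[[1L]]$cells) else integer(0)
    source_res <- list(forward = fwd, rsa = srsa, test = gtest,
                       peak = peak)
  }

  manifest <- list(
    config = unclass(config), seed = seed, stage_seeds = seeds,
    n_within = nrow(within), n_between = nrow(between),
    n_between_matched = nrow(between_matched),
    comparisons_dropped = avg_w$n_dropped,
    analysis_rate = analysis_rate, lowpass_hz = lowpass_hz,
    threshold = threshold, window = win,
    n_perm = n_perm, versions = list(
      megrsa = as.character(utils::packageVersion("megrsa")),
      R = paste(R.version$major, R.version$minor, sep = ".")),
    started = format(t0, "%Y-%m-%dT%H:%M:%S"),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  out <- structure(list(window = win, window_test = wt,
                        spatial = list(within = avg_w, between = avg_b,
                                       combined = combined),
                        matrix_test = mtest,
                        sensor_maps = list(within = map_w,
                                           between = map_b),
                        sensor_test = stest, source = source_res,
                        manifest = manifest),
                   class = "megrsa_pipeline")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_design(sim$design, file.path(out_dir, "design.csv"))
    write_layout(sim$layout, file.path(out_dir, "layout.csv"))
    write_result_json(wt, file.path(out_dir, "window_test.json"))
    write_result_json(mtest, file.path(out_dir, "matrix_cluster.json"))
    write_result_json(stest, file.path(out_dir, "sensor_cluster.json"))
    if (!is.null(source_res))
      write_result_json(source_res$test,
                        file.path(out_dir, "grid_cluster.json"))
    files <- list.files(out_dir, full.names = TRUE)
    files <- files[!grepl("manifest\\.json$", files)]
    manifest$checksums <- as.list(tools::md5sum(files))
    out$manifest <- manifest
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  out
}

#' @export
print.megrsa_pipeline <- function(x, ...) {
  cat("<megrsa_pipeline>\n")
  cat(sprintf("  window: [%g, %g] s (threshold %g)\n", x$window[1L],
              x$window[2L], x$manifest$threshold))
  cat(sprintf("  window test: R_within = %.4f, R_between = %.4f, t(%d) = %.3f, p = %.4g\n",
              x$window_test$mean_r_within, x$window_test$mean_r_between,
              x$window_test$df, x$window_test$t, x$window_test$p))
  cat(sprintf("  matrix clusters: %d significant\n",
              length(significant_clusters(x$matrix_test))))
  cat(sprintf("  sensor clusters: %d significant\n",
              length(significant_clusters(x$sensor_test))))
  if (!is.null(x$source))
    cat(sprintf("  grid clusters: %d significant (peak region %d points)\n",
                length(significant_clusters(x$source$test)),
                length(x$source$peak)))
  invisible(x)
}
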