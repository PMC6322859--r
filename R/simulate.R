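#' Simulation configuration
#'
#' Holds the design constants of the simulated experiment. Defaults mirror
#' the study conditions of a paired-sentence MEG reading experiment: 26
#' participants, 120 sentence pairs, 269 sensors, 4-s epochs around
#' sentence-final-word (SFW) onset with word onsets every 1000 ms, and an
#' item-specific "prediction" signature confined to 120-515 ms after SFW-1
#' onset (-880 to -485 ms relative to SFW onset), shared by the two members
#' of a pair.
#'
#' Signal scale: spatial patterns are drawn with unit across-sensor
#' standard deviation, so with `noise_sd = 1` the instantaneous spatial
#' correlation between two trials sharing a component of amplitude `A`
#' (at envelope value h) is approximately `A^2 h^2 / (A^2 h^2 + 1)`.
#'
#' @param n_participants,n_pairs,n_sensors counts (all >= 1).
#' @param sample_rate sampling rate in Hz.
#' @param epoch_window length-2 seconds relative to SFW onset, half-open.
#' @param word_onsets word onset times (s) relative to SFW onset.
#' @param effect_window length-2 seconds: where the item-specific component
#'   lives; must lie inside `epoch_window`.
#' @param evoked_amplitude amplitude of the word-locked evoked component.
#' @param identity_amplitude amplitude of the item-specific component.
#' @param identity_mode `"static"` (one spatial pattern per pair) or
#'   `"dynamic"` (pattern re-drawn every `identity_tau` seconds with smooth
#'   crossfade).
#' @param identity_tau pattern lifetime (s) in dynamic mode.
#' @param noise_sd per-sensor noise standard deviation.
#' @param noise_spatial_scale length scale (mm) of the exponential
#'   distance-decay of the noise spatial covariance.
#' @param noise_ar1 lag-1 autocorrelation of an optional AR(1) temporal
#'   structure for the noise (0 = white, the default).
#' @param seed integer RNG seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_participants = 26L, n_pairs = 120L,
                       n_sensors = 269L, sample_rate = 300,
                       epoch_window = c(-2, 2),
                       word_onsets = c(-2, -1, 0),
                       effect_window = c(-0.880, -0.485),
                       evoked_amplitude = 0.5, identity_amplitude = 0.5,
                       identity_mode = c("static", "dynamic"),
                       identity_tau = 0.1, noise_sd = 1,
                       noise_spatial_scale = 30, noise_ar1 = 0,
                       seed = 1L) {
  identity_mode <- match.arg(identity_mode)
  stopifnot(n_participants >= 1, n_pairs >= 1, n_sensors >= 1,
            sample_rate > 0, length(epoch_window) == 2L,
            length(effect_window) == 2L, identity_tau > 0,
            noise_sd >= 0, noise_ar1 >= 0, noise_ar1 < 1)
  if (!(epoch_window[1L] < effect_window[1L] &&
        effect_window[1L] < effect_window[2L] &&
        effect_window[2L] <= epoch_window[2L]))
    stop("invalid-argument: effect_window must lie inside epoch_window")
  structure(list(
    n_participants = as.integer(n_participants),
    n_pairs = as.integer(n_pairs), n_sensors = as.integer(n_sensors),
    sample_rate = sample_rate, epoch_window = epoch_window,
    word_onsets = word_onsets, effect_window = effect_window,
    evoked_amplitude = evoked_amplitude,
    identity_amplitude = identity_amplitude,
    identity_mode = identity_mode, identity_tau = identity_tau,
    noise_sd = noise_sd, noise_spatial_scale = noise_spatial_scale,
    noise_ar1 = noise_ar1, seed = as.integer(seed)), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d participants, %d pairs, %d sensors @ %g Hz\n",
    x$n_participants, x$n_pairs, x$n_sensors, x$sample_rate))
  cat(sprintf("  epoch [%g, %g) s, effect [%g, %g) s, mode %s\n",
              x$epoch_window[1L], x$epoch_window[2L], x$effect_window[1L],
              x$effect_window[2L], x$identity_mode))
  invisible(x)
}

#' Sensor positions on a hemispheric shell
#'
#' Places `n_sensors` points on a spherical cap (a stand-in helmet) using a
#' Fibonacci spiral, plus a small seeded tangential jitter so that layouts
#' are distinct across seeds yet reproducible.
#'
#' @param n_sensors number of sensors (>= 4).
#' @param seed integer RNG seed.
#' @param radius shell radius in mm.
#' @param cap_angle polar half-angle of the cap in radians.
#' @return data.frame of class `sensor_layout` with columns
#'   `id`, `x`, `y`, `z` (mm).
#' @export
make_sensor_layout <- function(n_sensors, seed = 1L, radius = 100,
                               cap_angle = 1.3) {
  if (n_sensors < 4L) stop("invalid-argument: n_sensors must be >= 4")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  i <- seq_len(n_sensors) - 0.5
  # uniform in cos(theta) over the cap
  costh <- 1 - (1 - cos(cap_angle)) * i / n_sensors
  theta <- acos(costh)
  golden <- pi * (3 - sqrt(5))
  phi <- golden * (seq_len(n_sensors) - 1L)
  pts <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), costh) * radius
  # tangential jitter (~2 mm), re-projected onto the shell
  pts <- pts + matrix(stats::rnorm(3L * n_sensors, sd = 2), ncol = 3L)
  pts <- pts / sqrt(rowSums(pts^2)) * radius
  structure(data.frame(id = sprintf("MEG%03d", seq_len(n_sensors)),
                       x = pts[, 1L], y = pts[, 2L], z = pts[, 3L],
                       stringsAsFactors = FALSE),
            radius = radius, class = c("sensor_layout", "data.frame"))
}

sensor_distances <- function(layout) {
  as.matrix(stats::dist(as.matrix(layout[, c("x", "y", "z")])))
}

# Smooth random sensor patterns: iid normals mixed through an exponential
# spatial kernel over the layout, standardised to zero mean / unit SD
# across sensors. Returns n_sensors x n_patterns.
random_smooth_patterns <- function(layout, n_patterns, smooth_mm = 40) {
  ns <- nrow(layout)
  K <- exp(-sensor_distances(layout) / smooth_mm)
  raw <- K %*% matrix(stats::rnorm(ns * n_patterns), ns)
  raw <- sweep(raw, 2L, colMeans(raw))
  sdv <- sqrt(colSums(raw^2) / (ns - 1L))
  sweep(raw, 2L, pmax(sdv, .Machine$double.eps), "/")
}

# Raised-cosine-edged plateau envelope on a time axis: 0 outside
# [on, off), ramps of `edge` seconds just inside the window.
plateau_envelope <- function(times, on, off, edge = 0.03) {
  h <- numeric(length(times))
  inside <- times >= on & times < off
  t <- times[inside]
  up <- pmin(pmax((t - on) / edge, 0), 1)
  dn <- pmin(pmax((off - t) / edge, 0), 1)
  h[inside] <- 0.5 * (1 - cos(pi * up)) * 0.5 * (1 - cos(pi * dn))
  h
}

# Time course of a pattern process: patterns at knots every tau seconds
# across [on, off), linearly interpolated (smooth crossfade). With a single
# knot the pattern is static. Returns sensors x length(times); zero outside
# the window once multiplied by the envelope (the caller applies it).
pattern_process <- function(patterns, times, on, off, tau) {
  nk <- ncol(patterns)
  if (nk == 1L) return(patterns[, rep(1L, length(times)), drop = FALSE])
  u <- (times - on) / tau
  u <- pmin(pmax(u, 0), nk - 1L)
  k <- pmin(floor(u), nk - 2L)
  f <- u - k
  lo <- patterns[, k + 1L, drop = FALSE]
  hi <- patterns[, k + 2L, drop = FALSE]
  lo * rep(1 - f, each = nrow(patterns)) +
    hi * rep(f, each = nrow(patterns))
}

n_pattern_knots <- function(on, off, tau, mode) {
  if (mode == "static") 1L else max(2L, ceiling((off - on) / tau) + 1L)
}

# Spatially correlated (optionally AR(1)-in-time) Gaussian noise:
# sensors x (n_times * n_trials), covariance noise_sd^2 * exp(-d/scale).
correlated_noise <- function(chol_K, n_times, n_trials, noise_sd, ar1 = 0) {
  ns <- nrow(chol_K)
  z <- stats::rnorm(ns * n_times * n_trials)
  dim(z) <- c(ns, n_times * n_trials)
  x <- crossprod(noise_sd * chol_K, z)
  if (ar1 > 0) {
    dim(x) <- c(ns, n_times, n_trials)
    innov <- sqrt(1 - ar1^2)
    for (t in 2:n_times)
      x[, t, ] <- ar1 * x[, t - 1L, ] + innov * x[, t, ]
  }
  dim(x) <- c(ns, n_times, n_trials)
  x
}

epoch_times <- function(config) {
  n <- round(diff(config$epoch_window) * config$sample_rate)
  config$epoch_window[1L] + (seq_len(n) - 1L) / config$sample_rate
}

# Word-evoked response envelope: active 120-515 ms after each word onset
# (the post-word interval over which spatial similarity is elevated).
evoked_envelope <- function(times, word_onsets) {
  h <- numeric(length(times))
  for (on in word_onsets)
    h <- pmax(h, plateau_envelope(times, on + 0.120, on + 0.515))
  h
}

#' Simulate a multi-participant epoched MEG dataset
#'
#' Each trial is the sum of three components: (1) a word-locked evoked
#' response -- a spatial-pattern process shared by every trial of a
#' participant, time-locked to each word onset and active 120-515 ms after
#' it; (2) an item-specific component -- a spatial pattern (static or
#' dynamic) and a temporal waveform drawn per pair and *identical for the
#' two members of a pair*, confined to `effect_window`; (3) zero-mean
#' Gaussian noise whose sensor covariance decays exponentially with
#' inter-sensor distance.
#'
#' @param config a [sim_config()].
#' @param design optional `pair_design`; generated from the config seed when
#'   omitted.
#' @param layout optional `sensor_layout`; generated when omitted.
#' @return An object of class `meg_simulation`: list with `epochs` (one
#'   `epoch_set` per participant), `design`, `layout`, `config` and
#'   `ground_truth` (identity patterns/waveforms per pair, evoked
#'   components, effect window).
#' @export
simulate_dataset <- function(config, design = NULL, layout = NULL) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  if (is.null(layout))
    layout <- make_sensor_layout(config$n_sensors,
                                 seed = sample.int(2^30, 1L))
  if (is.null(design)) {
    design <- random_pair_design(config$n_pairs,
                                 seed = sample.int(2^30, 1L))
    design$presentation_position <- sample.int(nrow(design))
  }
  if (nrow(layout) != config$n_sensors)
    stop("layout size disagrees with config$n_sensors")
  if (n_pairs(design) != config$n_pairs)
    stop("design size disagrees with config$n_pairs")

  times <- epoch_times(config)
  ew <- config$effect_window
  id_env <- plateau_envelope(times, ew[1L], ew[2L])
  ev_env <- evoked_envelope(times, config$word_onsets)
  active <- which(id_env > 0)
  nk <- n_pattern_knots(ew[1L], ew[2L], config$identity_tau,
                        config$identity_mode)
  chol_K <- chol(exp(-sensor_distances(layout) /
                       config$noise_spatial_scale) +
                 diag(1e-10, nrow(layout)))

  ns <- config$n_sensors; nt <- length(times)
  n_trials <- 2L * config$n_pairs
  pair_of_trial <- match(design$pair_id, unique(design$pair_id))

  truth <- list(effect_window = ew, identity_envelope = id_env,
                evoked_envelope = ev_env, times = times,
                identity_mode = config$identity_mode,
                identity_tau = config$identity_tau,
                participants = vector("list", config$n_participants))
  epochs <- vector("list", config$n_participants)

  for (p in seq_len(config$n_participants)) {
    # evoked: pattern process over each word's response, 130 ms lifetime
    ev_knots <- n_pattern_knots(0.120, 0.515, 0.13, "dynamic")
    ev_pat <- random_smooth_patterns(layout, ev_knots)
    evoked <- matrix(0, ns, nt)
    for (on in config$word_onsets) {
      seg <- which(times >= on + 0.120 & times < on + 0.515)
      if (!length(seg)) next
      proc <- pattern_process(ev_pat, times[seg], on + 0.120, on + 0.515,
                              0.13)
      evoked[, seg] <- evoked[, seg] + proc *
        rep(ev_env[seg], each = ns)
    }
    evoked <- config$evoked_amplitude * evoked

    # item identity: per pair, a pattern process and a temporal waveform
    id_pats <- if (config$identity_amplitude > 0)
      array(random_smooth_patterns(layout, nk * config$n_pairs),
            c(ns, nk, config$n_pairs)) else NULL
    wf <- matrix(0, nt, config$n_pairs)
    if (config$identity_amplitude > 0 && length(active)) {
      raw <- matrix(stats::rnorm(length(active) * config$n_pairs),
                    length(active))
      raw <- gaussian_smooth(raw, rate = config$sample_rate,
                             window = 0.1, sd = 0.025)
      raw <- sweep(raw, 2L, sqrt(colMeans(raw^2)), "/")
      wf[active, ] <- raw * id_env[active]
    }

    identity_sig <- vector("list", config$n_pairs)
    for (q in seq_len(config$n_pairs)) {
      if (is.null(id_pats)) next
      proc <- matrix(0, ns, nt)
      proc[, active] <- pattern_process(
        matrix(id_pats[, , q], ns, nk), times[active], ew[1L], ew[2L],
        config$identity_tau)
      identity_sig[[q]] <- config$identity_amplitude * proc *
        rep(wf[, q], each = ns)
    }

    data <- if (config$noise_sd > 0)
      correlated_noise(chol_K, nt, n_trials, config$noise_sd,
                       config$noise_ar1)
    else array(0, c(ns, nt, n_trials))
    if (config$evoked_amplitude != 0)
      data <- data + as.vector(evoked)     # recycled over trials
    for (tr in seq_len(n_trials)) {
      if (!is.null(identity_sig[[pair_of_trial[tr]]]))
        data[, , tr] <- data[, , tr] + identity_sig[[pair_of_trial[tr]]]
    }
    epochs[[p]] <- epoch_set(data, times, layout$id, design,
                             participant = p)
    truth$participants[[p]] <- list(
      evoked = evoked, identity_patterns = id_pats,
      identity_waveforms = wf)
  }
  structure(list(epochs = epochs, design = design, layout = layout,
                 config = config, ground_truth = truth),
            class = "meg_simulation")
}

#' @export
print.meg_simulation <- function(x, ...) {
  cat(sprintf(
    "<meg_simulation> %d participants x %d trials (%d pairs), %d sensors, %d samples\n",
    length(x$epochs), dim(x$epochs[[1L]]$data)[3L], n_pairs(x$design),
    dim(x$epochs[[1L]]$data)[1L], dim(x$epochs[[1L]]$data)[2L]))
  invisible(x)
}

#' Toy forward model on a regular source grid
#'
#' Builds a regular lattice of grid points (default spacing 10 mm) inside a
#' hemispheric source volume and a quasi-dipolar gain matrix: the field of a
#' dipole `q` at `r` seen by a radially oriented sensor at `s` is
#' `(q x (s - r)) . s / (|s| |s - r|^3)`. Each grid point contributes three
#' gain columns (unit dipoles along x, y, z).
#'
#' @param n_grid number of grid points (>= 1).
#' @param layout a `sensor_layout`.
#' @param seed integer RNG seed (sub-mm lattice jitter, for reproducible
#'   non-degenerate geometry).
#' @param grid_spacing lattice spacing in mm.
#' @param source_radius radius (mm) of the source hemisphere.
#' @return An object of class `forward_model`: `grid_positions`
#'   (n_grid x 3, mm), `gain` (n_sensors x 3*n_grid), `grid_spacing`.
#' @export
make_forward_model <- function(n_grid, layout, seed = 1L,
                               grid_spacing = 10,
                               source_radius = attr(layout, "radius") * 0.7) {
  stopifnot(n_grid >= 1)
  if (is.null(source_radius)) source_radius <- 70
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  # half-spacing offset keeps points off the z-axis, where a z-oriented
  # dipole is silent for radial sensors (degenerate 3rd gain column)
  g <- seq(-source_radius, source_radius, by = grid_spacing) +
    grid_spacing / 2
  lat <- as.matrix(expand.grid(x = g, y = g, z = g[g >= grid_spacing]))
  keep <- sqrt(rowSums(lat^2)) <= source_radius
  lat <- lat[keep, , drop = FALSE]
  if (nrow(lat) < n_grid)
    stop("source volume too small for ", n_grid, " grid points")
  center <- c(0, 0, source_radius / 2)
  ord <- order(sqrt(colSums((t(lat) - center)^2)))
  pos <- lat[ord[seq_len(n_grid)], , drop = FALSE]
  pos <- pos + matrix(stats::rnorm(length(pos), sd = 0.1), ncol = 3L)

  sens <- as.matrix(layout[, c("x", "y", "z")])
  shat <- sens / sqrt(rowSums(sens^2))
  # sensor orientations: radial plus a small random tangential tilt --
  # a perfectly radial array on a sphere is blind to radial dipoles
  # (rank-2 lead fields), so the tilt is what makes all three dipole
  # orientations visible
  tilt <- matrix(stats::rnorm(length(shat)), ncol = 3L)
  tilt <- tilt - shat * rowSums(tilt * shat)
  tilt <- tilt / sqrt(rowSums(tilt^2))
  nvec <- shat + 0.3 * tilt
  nvec <- nvec / sqrt(rowSums(nvec^2))
  gain <- matrix(0, nrow(sens), 3L * n_grid)
  for (gpt in seq_len(n_grid)) {
    dvec <- sweep(sens, 2L, pos[gpt, ])
    d3 <- pmax(sqrt(rowSums(dvec^2)), 1e-6)^3
    # field of unit dipole q: q . ((s - r) x n_s) / |s - r|^3
    cx <- (dvec[, 2L] * nvec[, 3L] - dvec[, 3L] * nvec[, 2L]) / d3
    cy <- (dvec[, 3L] * nvec[, 1L] - dvec[, 1L] * nvec[, 3L]) / d3
    cz <- (dvec[, 1L] * nvec[, 2L] - dvec[, 2L] * nvec[, 1L]) / d3
    block <- cbind(cx, cy, cz)
    sv <- svd(block, nu = 0, nv = 0)$d
    if (sv[3L] < 1e-8 * sv[1L])
      stop("degenerate lead field at grid point ", gpt,
           " (condition ", format(sv[1L] / sv[3L]), "); ",
           "choose a different seed or grid")
    gain[, (3L * gpt - 2L):(3L * gpt)] <- block
  }
  gain <- gain / mean(sqrt(colSums(gain^2)))
  structure(list(grid_positions = pos, gain = gain,
                 grid_spacing = grid_spacing, sensor_ids = layout$id),
            class = "forward_model")
}

#' @export
print.forward_model <- function(x, ...) {
  cat(sprintf(
    "<forward_model> %d grid points (%g mm spacing), %d sensors\n",
    nrow(x$grid_positions), x$grid_spacing, nrow(x$gain)))
  invisible(x)
}

gain_block <- function(forward, g) {
  forward$gain[, (3L * g - 2L):(3L * g), drop = FALSE]
}

#' Simulate epochs with item signatures injected at source grid points
#'
#' Like [simulate_dataset()], but the item-specific component of each pair
#' is a temporal waveform injected at an assigned grid point with a fixed
#' random dipole orientation, projected to the sensors through the forward
#' model's gain. The evoked component and noise are added exactly as in
#' [simulate_dataset()].
#'
#' @param forward a `forward_model`.
#' @param source_points integer vector, one grid index per pair.
#' @param config a [sim_config()] (its `identity_mode` is ignored: source
#'   patterns are fixed dipoles).
#' @param layout the `sensor_layout` the forward model was built on.
#' @param design optional `pair_design`.
#' @param orientations optional 3 x n_pairs matrix of dipole orientations
#'   (unit vectors); random when omitted.
#' @return A `meg_simulation`; `ground_truth` additionally records
#'   `source_points`, `orientations` and the injected waveforms.
#' @export
simulate_from_sources <- function(forward, source_points, config, layout,
                                  design = NULL, orientations = NULL) {
  stopifnot(inherits(forward, "forward_model"),
            inherits(config, "sim_config"))
  ng <- nrow(forward$grid_positions)
  if (length(source_points) != config$n_pairs)
    stop("need one source point per pair")
  if (any(source_points < 1L | source_points > ng))
    stop("invalid-argument: grid index out of range")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  if (is.null(design)) {
    design <- random_pair_design(config$n_pairs,
                                 seed = sample.int(2^30, 1L))
    design$presentation_position <- sample.int(nrow(design))
  }
  if (is.null(orientations)) {
    orientations <- matrix(stats::rnorm(3L * config$n_pairs), 3L)
  }
  nrm <- sqrt(colSums(orientations^2))
  if (any(nrm < 1e-12)) stop("invalid-argument: zero orientation vector")
  orientations <- sweep(orientations, 2L, nrm, "/")

  # sensor pattern of each pair: gain block times orientation, scaled to
  # unit across-sensor SD so identity_amplitude means what it does in
  # simulate_dataset()
  ns <- nrow(forward$gain)
  pats <- matrix(0, ns, config$n_pairs)
  for (q in seq_len(config$n_pairs)) {
    v <- gain_block(forward, source_points[q]) %*% orientations[, q]
    pats[, q] <- v / stats::sd(v)   # unit across-sensor SD, not centred:
                                    # the data stay in the gain span
  }

  times <- epoch_times(config)
  ew <- config$effect_window
  id_env <- plateau_envelope(times, ew[1L], ew[2L])
  ev_env <- evoked_envelope(times, config$word_onsets)
  active <- which(id_env > 0)
  chol_K <- chol(exp(-sensor_distances(layout) /
                       config$noise_spatial_scale) +
                 diag(1e-10, nrow(layout)))
  nt <- length(times)
  n_trials <- 2L * config$n_pairs
  pair_of_trial <- match(design$pair_id, unique(design$pair_id))

  truth <- list(effect_window = ew, source_points = source_points,
                orientations = orientations, sensor_patterns = pats,
                times = times, participants = vector("list",
                                                     config$n_participants))
  epochs <- vector("list", config$n_participants)
  for (p in seq_len(config$n_participants)) {
    ev_pat <- random_smooth_patterns(layout,
                                     n_pattern_knots(0.12, 0.515, 0.13,
                                                     "dynamic"))
    evoked <- matrix(0, ns, nt)
    for (on in config$word_onsets) {
      seg <- which(times >= on + 0.120 & times < on + 0.515)
      if (!length(seg)) next
      evoked[, seg] <- evoked[, seg] +
        pattern_process(ev_pat, times[seg], on + 0.12, on + 0.515, 0.13) *
        rep(ev_env[seg], each = ns)
    }
    evoked <- config$evoked_amplitude * evoked

    wf <- matrix(0, nt, config$n_pairs)
    if (length(active)) {
      raw <- matrix(stats::rnorm(length(active) * config$n_pairs),
                    length(active))
      raw <- gaussian_smooth(raw, rate = config$sample_rate,
                             window = 0.1, sd = 0.025)
      raw <- sweep(raw, 2L, sqrt(colMeans(raw^2)), "/")
      wf[active, ] <- raw * id_env[active]
    }

    data <- if (config$noise_sd > 0)
      correlated_noise(chol_K, nt, n_trials, config$noise_sd,
                       config$noise_ar1)
    else array(0, c(ns, nt, n_trials))
    if (config$evoked_amplitude != 0)
      data <- data + as.vector(evoked)
    for (tr in seq_len(n_trials)) {
      q <- pair_of_trial[tr]
      data[, , tr] <- data[, , tr] +
        config$identity_amplitude * pats[, q] %o% wf[, q]
    }
    epochs[[p]] <- epoch_set(data, times, layout$id, design,
                             participant = p)
    truth$participants[[p]] <- list(evoked = evoked,
                                    identity_waveforms = wf)
  }
  structure(list(epochs = epochs, design = design, layout = layout,
                 config = config, forward = forward,
                 ground_truth = truth),
            class = "meg_simulation")
}
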