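test_that("covariance estimation is unbiased, symmetric and PSD", {
  set.seed(14)
  ns <- 8L; nt <- 3000L
  trials <- data.frame(sentence_id = c("S1", "S2"), pair_id = c(1L, 1L))
  arr <- array(rnorm(ns * nt * 2L), c(ns, nt, 2L))
  ep <- epoch_set(arr, (seq_len(nt) - 1L) / 1000, sprintf("s%d", 1:ns),
                  trials)
  cv <- estimate_covariance(ep, c(0, 3))
  expect_lt(norm(cv$C - diag(ns), "F") / norm(diag(ns), "F"), 0.10)
  expect_equal(cv$C, t(cv$C))
  expect_true(all(eigen(cv$C, symmetric = TRUE,
                        only.values = TRUE)$values >
                    -1e-10 * sum(diag(cv$C))))
  # constant signals: zero covariance
  ep0 <- epoch_set(array(3, c(4L, 10L, 2L)), (0:9) / 10,
                   letters[1:4], trials)
  expect_equal(max(abs(estimate_covariance(ep0, c(0, 1))$C)), 0)
  # a single sinusoid on one sensor: rank-1 structure
  arr1 <- array(0, c(4L, 500L, 2L))
  arr1[2L, , ] <- sin(2 * pi * 5 * (0:499) / 250)
  ep1 <- epoch_set(arr1, (0:499) / 250, letters[1:4], trials)
  ev <- eigen(estimate_covariance(ep1, c(0, 2))$C, symmetric = TRUE,
              only.values = TRUE)$values
  expect_lt(ev[2L] / ev[1L], 1e-6)
})

test_that("LCMV filters satisfy the unit-gain constraint", {
  lay <- make_sensor_layout(24L, seed = 5L)
  fwd <- make_forward_model(10L, lay, seed = 5L)
  # identity covariance with orthonormal lead field: W = L'
  Lq <- qr.Q(qr(megrsa:::gain_block(fwd, 1L)))
  fwd_o <- fwd
  fwd_o$grid_positions <- fwd$grid_positions[1L, , drop = FALSE]
  fwd_o$gain <- Lq
  flt_o <- lcmv_filters(fwd_o, diag(24L), lambda = 0)
  expect_equal(flt_o$W[[1L]], t(Lq), tolerance = 1e-10)
  # any invertible covariance, lambda = 0: W L = I3
  set.seed(9)
  A <- matrix(rnorm(24L * 24L), 24L)
  C <- crossprod(A) / 24 + diag(24L)
  flt <- lcmv_filters(fwd, C, lambda = 0)
  for (g in which(flt$ok))
    expect_equal(flt$W[[g]] %*% megrsa:::gain_block(fwd, g), diag(3L),
                 tolerance = 1e-8)
})

test_that("noiseless single-source activity is localized and recovered", {
  lay <- make_sensor_layout(32L, seed = 6L)
  fwd <- make_forward_model(20L, lay, seed = 6L)
  cfg <- tiny_config(n_pairs = 1L, n_sensors = 32L, noise_sd = 0,
                     evoked_amplitude = 0, identity_amplitude = 1)
  true_pt <- 7L
  sim <- simulate_from_sources(fwd, true_pt, cfg, lay)
  ep <- sim$epochs[[1L]]
  flt <- lcmv_filters(fwd, estimate_covariance(ep, cfg$epoch_window))
  proj <- project_orientation(flt, ep)
  idx <- window_indices(proj$times, cfg$effect_window)
  vars <- apply(proj$data[, idx, 1L], 1L, var)
  expect_equal(which(flt$ok)[which.max(vars)], true_pt)
  wf <- sim$ground_truth$participants[[1L]]$identity_waveforms[idx, 1L]
  rec <- proj$data[match(true_pt, which(flt$ok)), idx, 1L]
  expect_gt(abs(cor(rec, wf)), 0.999)
})

test_that("regularization trades output variance against noise gain", {
  lay <- make_sensor_layout(24L, seed = 8L)
  fwd <- make_forward_model(8L, lay, seed = 8L)
  cfg <- tiny_config(n_pairs = 2L, n_sensors = 24L, noise_sd = 1,
                     identity_amplitude = 1)
  sim <- simulate_from_sources(fwd, c(2L, 6L), cfg, lay)
  ep <- sim$epochs[[1L]]
  cov <- estimate_covariance(ep, cfg$epoch_window)
  lam_ladder <- c(1e-6, 0.05, 0.2, 1)
  out_var <- noise_gain <- numeric(length(lam_ladder))
  for (i in seq_along(lam_ladder)) {
    flt <- lcmv_filters(fwd, cov, lambda = lam_ladder[i])
    out_var[i] <- sum(vapply(which(flt$ok), function(g)
      sum(diag(flt$W[[g]] %*% cov$C %*% t(flt$W[[g]]))), numeric(1L)))
    noise_gain[i] <- sum(vapply(which(flt$ok), function(g)
      sum(flt$W[[g]]^2), numeric(1L)))
  }
  # lambda = 0 is the variance minimiser subject to unit gain: every
  # regularized filter has output variance at least that of lambda = 0
  flt0 <- lcmv_filters(fwd, cov, lambda = 0)
  v0 <- sum(vapply(which(flt0$ok), function(g)
    sum(diag(flt0$W[[g]] %*% cov$C %*% t(flt0$W[[g]]))), numeric(1L)))
  expect_true(all(out_var >= v0 - 1e-9 * abs(v0)))
  # the white-noise gain of the filters is non-increasing in lambda
  expect_true(all(diff(noise_gain) <= 1e-9 * noise_gain[-1L]))
})

test_that("orientation projection picks the dominant direction", {
  # filters that pass three virtual sensors straight through
  fake_fwd <- list(grid_positions = matrix(0, 1L, 3L),
                   gain = diag(3L), grid_spacing = 10)
  class(fake_fwd) <- "forward_model"
  flt <- list(W = list(diag(3L)), ok = TRUE, lambda = 0,
              forward = fake_fwd)
  class(flt) <- "beamformer_filters"
  trials <- data.frame(sentence_id = "S1", pair_id = 1L)
  # activity confined to one orientation
  nt <- 400L
  arr <- array(0, c(3L, nt, 1L))
  arr[2L, , 1L] <- sin(2 * pi * 3 * (seq_len(nt) - 1L) / 200)
  ep <- epoch_set(arr, (seq_len(nt) - 1L) / 200, letters[1:3], trials)
  proj <- project_orientation(flt, ep)
  expect_equal(abs(cor(proj$data[1L, , 1L], arr[2L, , 1L])), 1,
               tolerance = 1e-12)
  # anisotropic 3-orientation noise: projected variance matches the top
  # eigenvalue of the 3x3 covariance (uncentered, matching the SVD)
  set.seed(15)
  S <- crossprod(matrix(rnorm(9), 3L) * c(3, 1, 0.5),
                 matrix(rnorm(3L * 5000L), 3L))
  arr2 <- array(S, c(3L, 5000L, 1L))
  ep2 <- epoch_set(arr2, (seq_len(5000L) - 1L) / 1000, letters[1:3],
                   trials)
  proj2 <- project_orientation(flt, ep2)
  lam1 <- eigen(tcrossprod(S) / ncol(S), symmetric = TRUE,
                only.values = TRUE)$values[1L]
  expect_equal(mean(proj2$data[1L, , 1L]^2), lam1, tolerance = 0.02)
})

test_that("source RSA agrees with sensor RSA under identity filters", {
  cfg <- tiny_config(n_participants = 3L, n_sensors = 8L, noise_sd = 1,
                     identity_amplitude = 0.8)
  sim <- simulate_dataset(cfg)
  ns <- 8L
  # one virtual channel per sensor: W rows pick that sensor
  identity_filters <- function() {
    W <- lapply(seq_len(ns), function(s) {
      m <- matrix(0, 3L, ns); m[1L, s] <- 1
      m
    })
    structure(list(W = W, ok = rep(TRUE, ns), lambda = 0),
              class = "beamformer_filters")
  }
  projected <- lapply(sim$epochs, function(ep)
    project_orientation(identity_filters(), ep))
  within <- enumerate_within(sim$design)
  between <- enumerate_between(sim$design)
  ew <- cfg$effect_window
  src <- source_temporal_rsa(projected, within, between, ew)
  sens_w <- average_condition_maps(sim$epochs, within, ew)
  sens_b <- average_condition_maps(sim$epochs, between, ew)
  expect_equal(src$within$per_participant, sens_w$per_participant,
               tolerance = 1e-12)
  expect_equal(src$difference, sens_w$r - sens_b$r, tolerance = 1e-12)
  expect_true(all(abs(src$difference) <= 2))
  # identical conditions give a zero difference map
  src0 <- source_temporal_rsa(projected, within, within, ew)
  expect_equal(max(abs(src0$difference)), 0)
})

test_that("grid cluster test and peak region behave on small grids", {
  lay <- make_sensor_layout(24L, seed = 9L)
  fwd <- make_forward_model(12L, lay, seed = 9L)
  set.seed(33)
  n <- 6L
  w <- matrix(rnorm(n * 12L, 0.3, 0.05), n)
  b <- matrix(rnorm(n * 12L, 0.1, 0.05), n)
  res <- grid_cluster_test(w, b, fwd, n_perm = 100L, seed = 2L)
  expect_s3_class(res, "cluster_result")
  # single-grid-point volume: the cluster is that point
  fwd1 <- fwd
  fwd1$grid_positions <- fwd$grid_positions[1L, , drop = FALSE]
  res1 <- grid_cluster_test(w[, 1L, drop = FALSE],
                            b[, 1L, drop = FALSE], fwd1,
                            n_perm = 50L, seed = 2L)
  expect_true(all(vapply(res1$clusters, function(cl)
    identical(cl$cells, 1L), logical(1L))))
  # peak region arithmetic
  expect_equal(peak_region(rep(0.5, 7L), 1:7), 1:7)
  d <- c(0.1, 0.9, 0.2); expect_equal(peak_region(d, 1:3), 2L)
  grad <- seq(0, 1, length.out = 11L)
  expect_equal(peak_region(grad, 1:11), 10:11)
  expect_error(peak_region(grad, integer(0)), "empty")
})
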