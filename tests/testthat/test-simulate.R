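test_that("sensor layouts live on the shell and are seed-reproducible", {
  l <- make_sensor_layout(269L, seed = 1L)
  expect_equal(nrow(l), 269L)
  d <- as.matrix(dist(as.matrix(l[, c("x", "y", "z")])))
  diag(d) <- Inf
  expect_gt(min(d), 0)
  r <- sqrt(l$x^2 + l$y^2 + l$z^2)
  expect_equal(r, rep(100, 269L), tolerance = 1e-9)
  expect_identical(make_sensor_layout(4L, seed = 0L),
                   make_sensor_layout(4L, seed = 0L))
  # 64 sensors on a 100 mm cap: neighbours well within 40 mm
  l64 <- make_sensor_layout(64L, seed = 7L)
  d64 <- as.matrix(dist(as.matrix(l64[, c("x", "y", "z")])))
  diag(d64) <- Inf
  expect_lt(min(d64), 40)
  expect_error(make_sensor_layout(3L), "invalid-argument")
})

test_that("simulation is deterministic under config + seed", {
  cfg <- tiny_config(noise_sd = 0.8)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$epochs[[1L]]$data, s2$epochs[[1L]]$data)
  expect_identical(s1$design, s2$design)
  s3 <- simulate_dataset(tiny_config(noise_sd = 0.8, seed = 8L))
  expect_false(identical(s1$epochs[[1L]]$data, s3$epochs[[1L]]$data))
})

test_that("noise-only simulations reproduce the distance-decay covariance", {
  cfg <- sim_config(n_participants = 1L, n_pairs = 9L, n_sensors = 32L,
                    sample_rate = 300, epoch_window = c(-2, 2),
                    evoked_amplitude = 0, identity_amplitude = 0,
                    noise_sd = 1.3, noise_spatial_scale = 30, seed = 4L)
  sim <- simulate_dataset(cfg)
  X <- matrix(sim$epochs[[1L]]$data, 32L)   # >= 5000 samples (21600)
  expect_gte(ncol(X), 5000L)
  Cemp <- tcrossprod(X - rowMeans(X)) / (ncol(X) - 1L)
  D <- as.matrix(dist(as.matrix(sim$layout[, c("x", "y", "z")])))
  Ctrue <- 1.3^2 * exp(-D / 30)
  expect_lt(norm(Cemp - Ctrue, "F") / norm(Ctrue, "F"), 0.10)
})

test_that("identity component is pair-shared and confined to the window", {
  cfg <- tiny_config(identity_amplitude = 0.8, noise_sd = 0)
  sim <- simulate_dataset(cfg)
  ep <- sim$epochs[[1L]]
  idx <- window_indices(ep$times, cfg$effect_window)
  out <- setdiff(seq_along(ep$times), idx)
  # pair symmetry: the two members of a pair are identical (noiseless)
  expect_identical(ep$data[, , 1L], ep$data[, , 2L])
  # effect confinement: outside the window only the evoked part remains,
  # so trials from different pairs coincide exactly
  expect_equal(max(abs(ep$data[, out, 1L] - ep$data[, out, 3L])), 0)
  expect_gt(max(abs(ep$data[, idx, 1L] - ep$data[, idx, 3L])), 0)
})

test_that("evoked-only trials are identical with unit spatial correlation", {
  cfg <- tiny_config(identity_amplitude = 0, noise_sd = 0,
                     evoked_amplitude = 1)
  ep <- simulate_dataset(cfg)$epochs[[1L]]
  expect_identical(ep$data[, , 1L], ep$data[, , 4L])
  r <- spatial_similarity_series(ep$data[, , 1L], ep$data[, , 4L])$r
  expect_equal(r[!is.na(r)], rep(1, sum(!is.na(r))), tolerance = 1e-12)
  expect_true(any(!is.na(r)))
})

test_that("static identity raises within- above between-pair correlation", {
  cfg <- tiny_config(identity_amplitude = 0.8, noise_sd = 0)
  ep <- simulate_dataset(cfg)$epochs[[1L]]
  idx <- window_indices(ep$times, cfg$effect_window)
  rw <- spatial_similarity_series(ep$data[, , 1L], ep$data[, , 2L])$r[idx]
  rb <- spatial_similarity_series(ep$data[, , 1L], ep$data[, , 3L])$r[idx]
  both <- !is.na(rw) & !is.na(rb)
  expect_true(any(both))
  expect_true(all(rw[both] >= rb[both] - 1e-12))
})

test_that("dynamic identity decorrelates across lags", {
  cfg <- tiny_config(n_pairs = 2L, sample_rate = 300,
                     identity_mode = "dynamic", identity_tau = 0.05,
                     identity_amplitude = 1, evoked_amplitude = 0,
                     noise_sd = 0)
  ep <- simulate_dataset(cfg)$epochs[[1L]]
  M <- cross_temporal_matrix(ep$data[, , 1L], ep$data[, , 2L], ep$times,
                             interval = cfg$effect_window)$r
  n <- nrow(M); lag <- round(0.2 * 300)
  diag0 <- mean(diag(M), na.rm = TRUE)
  diag_lag <- mean(M[cbind((lag + 1L):n, 1L:(n - lag))], na.rm = TRUE)
  expect_gt(diag0, 0.99)
  expect_lt(diag_lag, diag0 - 0.5)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(effect_window = c(-3, -2.5)),
               "effect_window")
  expect_error(sim_config(n_pairs = 0), "n_pairs")
})

test_that("toy forward models are full-rank, smooth and seeded", {
  lay <- make_sensor_layout(10L, seed = 3L)
  fm <- make_forward_model(1L, lay, seed = 3L)
  expect_equal(dim(fm$gain), c(10L, 3L))
  expect_equal(qr(fm$gain)$rank, 3L)
  lay64 <- make_sensor_layout(64L, seed = 3L)
  fm20 <- make_forward_model(20L, lay64, seed = 3L)
  expect_true(all(is.finite(fm20$gain)))
  expect_true(all(colSums(fm20$gain^2) > 0))
  expect_identical(fm20$gain,
                   make_forward_model(20L, lay64, seed = 3L)$gain)
})

test_that("source-injected data lie in the span of the gain columns", {
  lay <- make_sensor_layout(24L, seed = 5L)
  fm <- make_forward_model(12L, lay, seed = 5L)
  cfg <- tiny_config(n_pairs = 1L, n_sensors = 24L, noise_sd = 0,
                     evoked_amplitude = 0, identity_amplitude = 1)
  sim <- simulate_from_sources(fm, 4L, cfg, lay)
  ep <- sim$epochs[[1L]]
  idx <- window_indices(ep$times, cfg$effect_window)
  L <- fm$gain[, 10:12]
  X <- ep$data[, idx, 1L]
  resid <- X - L %*% solve(crossprod(L), crossprod(L, X))
  expect_lt(max(abs(resid)), 1e-8 * max(abs(X)))
  # two pairs at different points: within-pair trials identical
  cfg2 <- tiny_config(n_pairs = 2L, n_sensors = 24L, noise_sd = 0,
                      evoked_amplitude = 0, identity_amplitude = 1)
  sim2 <- simulate_from_sources(fm, c(2L, 9L), cfg2, lay)
  ep2 <- sim2$epochs[[1L]]
  r <- row_cor <- cor(as.vector(ep2$data[, idx, 1L]),
                      as.vector(ep2$data[, idx, 2L]))
  expect_equal(r, 1, tolerance = 1e-12)
  expect_error(simulate_from_sources(fm, c(2L, 99L), cfg2, lay),
               "invalid-argument")
})
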