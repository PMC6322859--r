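test_that("spatial similarity series equals the Pearson brute force", {
  a <- matrix(c(1, 2, 3, 1, 0, 2), 3L)
  b <- matrix(c(3, 5, 7, 1, 0, 2), 3L)   # col 1 = 2*a+1, col 2 = a col 2
  r <- spatial_similarity_series(a, b)$r
  expect_equal(r[1L], 1, tolerance = 1e-12)
  expect_equal(r, brute_spatial_series(a, b), tolerance = 1e-12)
  # self and negated self
  set.seed(4)
  x <- matrix(rnorm(40), 5L)
  expect_equal(spatial_similarity_series(x, x)$r, rep(1, 8L),
               tolerance = 1e-12)
  expect_equal(spatial_similarity_series(x, -x)$r, rep(-1, 8L),
               tolerance = 1e-12)
  # zero-variance sample flagged undefined
  x0 <- x; x0[, 3L] <- 2
  expect_true(is.na(spatial_similarity_series(x0, x)$r[3L]))
  expect_error(spatial_similarity_series(x, x[, 1:3]),
               "invalid-argument")
})

test_that("similarity outputs match brute force on many small instances", {
  set.seed(10)
  for (i in 1:25) {
    ns <- sample(2:4, 1L)
    nt <- sample(3:6, 1L)
    a <- matrix(rnorm(ns * nt), ns)
    b <- matrix(rnorm(ns * nt), ns)
    expect_equal(spatial_similarity_series(a, b)$r,
                 brute_spatial_series(a, b), tolerance = 1e-12)
    expect_equal(
      temporal_similarity_map(a, b, seq_len(nt), c(1, nt + 1))$r,
      brute_temporal_map(a, b), tolerance = 1e-12)
    expect_equal(
      cross_temporal_matrix(a, b, seq_len(nt))$r,
      brute_cross_temporal(a, b), tolerance = 1e-12)
  }
})

test_that("condition averaging matches an independent comparison loop", {
  cfg <- tiny_config(n_participants = 5L, noise_sd = 1,
                     identity_amplitude = 0.6)
  sim <- simulate_dataset(cfg)
  w <- enumerate_within(sim$design)
  avg <- average_condition_series(sim$epochs, w)
  # brute force: loop comparisons and participants with stats::cor
  pp <- sapply(seq_along(sim$epochs), function(p) {
    ep <- sim$epochs[[p]]
    rs <- sapply(seq_len(nrow(w)), function(k) {
      ia <- match(w$sentence_a[k], ep$trials$sentence_id)
      ib <- match(w$sentence_b[k], ep$trials$sentence_id)
      brute_spatial_series(ep$data[, , ia], ep$data[, , ib])
    })
    rowMeans(rs)
  })
  expect_equal(avg$per_participant, t(pp), tolerance = 1e-12)
  expect_equal(avg$r, rowMeans(pp), tolerance = 1e-12)
  expect_equal(avg$n_comparisons, rep(3L, 5L))
  # two constant series average to their mean
  expect_true(all(abs(avg$r) <= 1))
})

test_that("averaging drops comparisons with missing trials, with counts", {
  cfg <- tiny_config(noise_sd = 0.5)
  sim <- simulate_dataset(cfg)
  ep <- sim$epochs[[1L]]
  keep <- 1:4   # drop the trials of pair 3
  ep2 <- epoch_set(ep$data[, , keep], ep$times, ep$sensor_ids,
                   ep$trials[keep, ], 1L)
  avg <- average_condition_series(list(ep2),
                                  enumerate_within(sim$design))
  expect_equal(avg$n_comparisons, 2L)
  expect_equal(avg$n_dropped, 1L)
  empty <- epoch_set(ep$data[, , 1L, drop = FALSE], ep$times,
                     ep$sensor_ids, ep$trials[1L, ], 1L)
  expect_error(average_condition_series(list(empty),
                                        enumerate_within(sim$design)),
               "empty-condition")
})

test_that("window detection returns the longest supra-threshold run", {
  times <- seq(-2, 2 - 1 / 300, by = 1 / 300)
  expect_false(detect_window(rep(0, length(times)), times)$found)
  # boxcar over exactly -0.9..-0.5
  r <- ifelse(times >= -0.9 & times <= -0.5, 0.08, 0)
  dw <- detect_window(r, times, threshold = 0.04)
  expect_true(dw$found)
  expect_lt(abs(dw$start - (-0.9)), 1.5 / 300)
  expect_lt(abs(dw$end - (-0.5)), 1.5 / 300)
  # two runs: the longer one wins
  r2 <- ifelse(times > -1 & times < -0.7, 0.1,
               ifelse(times > -0.4 & times < -0.3, 0.2, 0))
  dw2 <- detect_window(r2, times, threshold = 0.04)
  expect_lt(abs(dw2$start - (-1)), 2 / 300)
  expect_lt(abs(dw2$end - (-0.7)), 2 / 300)
  # search interval restriction
  dw3 <- detect_window(r2, times, 0.04, search_interval = c(-0.5, 0))
  expect_lt(abs(dw3$start - (-0.4)), 2 / 300)
})

test_that("window test reduces to the paired t on window means", {
  mk <- function(mat, times) {
    structure(list(r = colMeans(mat), times = times,
                   per_participant = mat, label = "x",
                   n_comparisons = rep(1L, nrow(mat))),
              class = "similarity_average")
  }
  times <- seq(0, 0.99, by = 0.01)
  set.seed(8)
  w <- matrix(rnorm(400, 0.1, 0.05), 4L)
  b <- matrix(rnorm(400, 0.05, 0.05), 4L)
  res <- window_test(mk(w, times), mk(b, times), c(0.2, 0.6))
  idx <- which(times >= 0.2 & times < 0.6)
  tt <- t.test(rowMeans(w[, idx]), rowMeans(b[, idx]), paired = TRUE)
  expect_equal(res$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)
  expect_equal(res$df, 3)
  # identical conditions: t = 0, p = 1
  res0 <- window_test(mk(w, times), mk(w, times), c(0.2, 0.6))
  expect_equal(c(res0$t, res0$p), c(0, 1))
  # constant positive difference: degenerate, flagged maximal
  res1 <- window_test(mk(b + 0.2, times), mk(b, times), c(0.2, 0.6))
  expect_true(res1$degenerate)
  expect_equal(res1$t, Inf)
})

test_that("cross-temporal matrices are consistent with the series", {
  set.seed(5)
  a <- matrix(rnorm(16 * 50), 16L)
  times <- seq(0, 49) / 100
  M <- cross_temporal_matrix(a, a, times)
  expect_equal(unname(diag(M$r)), rep(1, 50L), tolerance = 1e-12)
  b <- matrix(rnorm(16 * 50), 16L)
  M2 <- cross_temporal_matrix(a, b, times)
  s <- spatial_similarity_series(a, b)$r
  expect_equal(unname(diag(M2$r)), s, tolerance = 1e-10)
  expect_true(all(abs(M2$r) <= 1 + 1e-12))
})

test_that("matrix cluster test finds embedded effects and respects the null", {
  set.seed(21)
  n <- 8L; nt <- 20L
  base <- array(rnorm(n * nt * nt, 0, 0.05), c(n, nt, nt))
  # null: within == between -> no supra-threshold cells at all
  res0 <- matrix_cluster_test(base, base, n_perm = 50L, seed = 1L)
  expect_length(res0$clusters, 0L)
  # embedded diagonal band effect
  effect <- matrix(0, nt, nt)
  for (i in 5:15) for (j in 5:15)
    if (abs(i - j) <= 1) effect[i, j] <- 0.15
  within <- base + rep(effect, each = n) +
    array(rnorm(n * nt * nt, 0, 0.05), c(n, nt, nt))
  res <- matrix_cluster_test(within, base,
                             times_row = seq_len(nt) / 100,
                             times_col = seq_len(nt) / 100,
                             n_perm = 200L, seed = 2L)
  sig <- significant_clusters(res)
  expect_gte(length(sig), 1L)
  cells <- sig[[which.max(vapply(sig, function(cl) length(cl$cells),
                                 0))]]$cells
  ri <- (cells - 1L) %% nt + 1L
  ci <- (cells - 1L) %/% nt + 1L
  expect_true(any(ri == ci & ri >= 5L & ri <= 15L))
  # determinism
  res2 <- matrix_cluster_test(within, base,
                              times_row = seq_len(nt) / 100,
                              times_col = seq_len(nt) / 100,
                              n_perm = 200L, seed = 2L)
  expect_identical(res2$null, res$null)
  expect_error(matrix_cluster_test(within, base, n_perm = 0L),
               "n_perm")
})

test_that("4-connectivity clustering groups edge-adjacent cells only", {
  mask <- matrix(FALSE, 4L, 4L)
  mask[1L, 1L] <- mask[2L, 1L] <- mask[2L, 2L] <- TRUE  # L-shape
  mask[4L, 4L] <- TRUE                                  # isolated
  mask[1L, 3L] <- TRUE                                  # diagonal from (2,2)
  comps <- megrsa:::label_matrix_components(which(mask), 4L, 4L)
  sizes <- sort(lengths(comps))
  expect_equal(sizes, c(1L, 1L, 3L))
})
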