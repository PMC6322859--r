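# Shared fixtures and independent brute-force oracles.

# Small hand-built design: n_pairs pairs, alternating noun/verb, member 1
# expected, optional shared SFW-1 tokens.
tiny_design <- function(n_pairs, sfw1 = NULL, positions = NULL) {
  n <- 2L * n_pairs
  d <- data.frame(
    sentence_id = sprintf("S%02d", seq_len(n)),
    pair_id = rep(seq_len(n_pairs), each = 2L),
    member_index = rep(1:2, n_pairs),
    expectancy = rep(c("expected", "unexpected"), n_pairs),
    category = rep(rep(c("noun", "verb"), length.out = n_pairs),
                   each = 2L),
    stringsAsFactors = FALSE)
  if (!is.null(sfw1)) d$sfw1_token <- sfw1
  if (!is.null(positions)) d$presentation_position <- positions
  pair_design(d)
}

# Brute-force Pearson oracles, written against stats::cor sample by sample
# (independent of the package's vectorised path).
brute_spatial_series <- function(a, b) {
  vapply(seq_len(ncol(a)), function(t) {
    va <- a[, t]; vb <- b[, t]
    if (stats::sd(va) == 0 || stats::sd(vb) == 0) return(NA_real_)
    stats::cor(va, vb)
  }, numeric(1L))
}

brute_temporal_map <- function(a, b) {
  vapply(seq_len(nrow(a)), function(s) {
    if (stats::sd(a[s, ]) == 0 || stats::sd(b[s, ]) == 0)
      return(NA_real_)
    stats::cor(a[s, ], b[s, ])
  }, numeric(1L))
}

brute_cross_temporal <- function(a, b) {
  nt <- ncol(a)
  M <- matrix(NA_real_, nt, nt)
  for (i in seq_len(nt)) for (j in seq_len(nt)) {
    if (stats::sd(a[, i]) > 0 && stats::sd(b[, j]) > 0)
      M[i, j] <- stats::cor(a[, i], b[, j])
  }
  M
}

# epoch_set with given per-trial sensor x time matrices
epochs_from_list <- function(mats, times, design, participant = 1L) {
  arr <- array(unlist(mats), c(dim(mats[[1L]]), length(mats)))
  epoch_set(arr, times, sprintf("s%02d", seq_len(nrow(mats[[1L]]))),
            as.data.frame(design), participant)
}

# tiny noiseless simulation config used across files
tiny_config <- function(...) {
  args <- list(n_participants = 1L, n_pairs = 3L, n_sensors = 12L,
               sample_rate = 120, epoch_window = c(-1, 0),
               word_onsets = -1, seed = 7L)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}
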