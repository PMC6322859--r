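# Shared statistical primitives: paired/independent t, 2x2 repeated
# measures ANOVA, percentile convention, and the seeded sign-flip
# permutation machinery used by all cluster tests.

#' Paired t-test
#'
#' Classical two-sided paired t on per-participant values; `df = n - 1`.
#' When the differences have zero variance the statistic is degenerate and
#' is flagged: `t` is `+/-Inf` (or 0 for identical inputs) and `p` is 0
#' (or 1).
#'
#' @param a,b numeric vectors of equal length (>= 2), one value per
#'   participant.
#' @return List with `t`, `df`, `p`, `mean_diff`, `degenerate`.
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2L) stop("invalid-argument: need >= 2 participants")
  d <- a - b
  if (stats::sd(d) < .Machine$double.eps * max(1, max(abs(d)))) {
    md <- mean(d)
    return(list(t = if (md == 0) 0 else sign(md) * Inf, df = n - 1L,
                p = if (md == 0) 1 else 0, mean_diff = md,
                degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate),
       degenerate = FALSE)
}

#' Two-factor repeated-measures ANOVA (2 x 2)
#'
#' Within-subject ANOVA for a 2 x 2 design via the difference-score
#' formulation: each one-degree-of-freedom effect (factor A, factor B,
#' interaction) is a paired contrast across participants, `F = t^2` with
#' df (1, n - 1), and partial eta^2 = F / (F + df2).
#'
#' @param cells numeric array `n x 2 x 2` (participant, factor A level,
#'   factor B level) of cell means per participant.
#' @return data.frame with rows A, B, A:B and columns `F`, `df1`, `df2`,
#'   `p`, `pes` (partial eta squared).
#' @export
rm_anova_2x2 <- function(cells) {
  if (length(dim(cells)) != 3L || any(dim(cells)[2:3] != 2L))
    stop("invalid-argument: `cells` must be an n x 2 x 2 array")
  if (anyNA(cells)) stop("invalid-argument: missing cells")
  n <- dim(cells)[1L]
  if (n < 2L) stop("invalid-argument: need >= 2 participants")
  contrast <- function(w) {
    sc <- (cells[, 1L, 1L] * w[1L] + cells[, 1L, 2L] * w[2L] +
             cells[, 2L, 1L] * w[3L] + cells[, 2L, 2L] * w[4L]) / 2
    v <- stats::var(sc)
    if (v < .Machine$double.eps) {
      f <- if (mean(sc) == 0) 0 else Inf
    } else f <- n * mean(sc)^2 / v
    p <- stats::pf(f, 1L, n - 1L, lower.tail = FALSE)
    c(F = f, df1 = 1, df2 = n - 1, p = p, pes = f / (f + (n - 1)))
  }
  out <- rbind(A = contrast(c(1, 1, -1, -1)),
               B = contrast(c(1, -1, 1, -1)),
               `A:B` = contrast(c(1, -1, -1, 1)))
  as.data.frame(out)
}

#' Percentile with the linear-interpolation convention
#'
#' Thin wrapper around `stats::quantile(type = 7)` (the linear
#' interpolation definition), fixed so cluster thresholds are reproducible.
#'
#' @param x numeric vector.
#' @param p percentile in `[0, 100]`.
#' @return The percentile value.
#' @export
percentile <- function(x, p) {
  unname(stats::quantile(x, p / 100, type = 7L, names = FALSE))
}

#' Permutation p-value convention
#'
#' `p = (b + 1) / (n_perm + 1)` where `b` counts null draws at least as
#' extreme as the observed statistic; never zero, and with 1000
#' permutations the smallest attainable p is about 0.001.
#'
#' @param observed observed statistic (scalar).
#' @param null numeric vector of null statistics.
#' @return The p-value.
#' @export
perm_pvalue <- function(observed, null) {
  (sum(null >= observed) + 1) / (length(null) + 1)
}

# n_perm x n_participants matrix of independent +/-1 flips, seeded.
flip_matrix <- function(n_participants, n_perm, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  matrix(sample(c(-1, 1), n_perm * n_participants, replace = TRUE),
         n_perm, n_participants)
}

#' Sign-flip permutation null for a max statistic
#'
#' Implements the participant-level condition-swap scheme: swapping the
#' within/between labels inside a participant is equivalent to flipping the
#' sign of that participant's within-minus-between difference. For each of
#' `n_perm` permutations every participant's difference is flipped
#' independently with probability 1/2 and the statistic is recomputed; the
#' p-value uses the `(b + 1)/(n_perm + 1)` convention.
#'
#' @param diffs per-participant differences: a numeric vector, or a matrix
#'   with one row per participant.
#' @param statistic function mapping a difference object like `diffs` to a
#'   scalar statistic (e.g. a max cluster mass); must be deterministic.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer RNG seed.
#' @return List with `observed`, `null` (length `n_perm`), `p`.
#' @export
permutation_null <- function(diffs, statistic, n_perm = 1000L, seed = 1L) {
  if (n_perm < 1L) stop("invalid-argument: n_perm must be >= 1")
  m <- if (is.matrix(diffs)) diffs else matrix(diffs, ncol = 1L)
  n <- nrow(m)
  observed <- statistic(diffs)
  flips <- flip_matrix(n, n_perm, seed)
  null <- vapply(seq_len(n_perm), function(i) {
    flipped <- m * flips[i, ]
    statistic(if (is.matrix(diffs)) flipped else drop(flipped))
  }, numeric(1L))
  list(observed = observed, null = null,
       p = perm_pvalue(observed, null))
}
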