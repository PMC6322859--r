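#' Pair design table
#'
#' Bookkeeping for a paired sentence design: 2N sentences grouped into N
#' pairs, where the two members of a pair predict the same sentence-final
#' word (SFW) but one ends with the expected word and the other with an
#' unexpected word.
#'
#' @param x data.frame with one row per sentence. Required columns:
#'   `sentence_id`, `pair_id`, `member_index` (1 or 2), `expectancy`
#'   (`"expected"` / `"unexpected"`). Optional columns used by some
#'   analyses: `category` (`"noun"` / `"verb"`), `sfw1_token`,
#'   `presentation_position`, plus arbitrary numeric/binary property codes.
#'
#' @return An object of class `pair_design` (a validated data.frame).
#' @export
pair_design <- function(x) {
  stopifnot(is.data.frame(x))
  req <- c("sentence_id", "pair_id", "member_index", "expectancy")
  miss <- setdiff(req, names(x))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(x$sentence_id)) stop("duplicated sentence_id")
  tab <- table(x$pair_id)
  if (any(tab != 2L)) stop("every pair_id must have exactly two members")
  for (p in split(x, x$pair_id)) {
    if (!setequal(p$member_index, 1:2))
      stop("pair ", p$pair_id[1L], ": member_index must be {1, 2}")
    if (!setequal(p$expectancy, c("expected", "unexpected")))
      stop("pair ", p$pair_id[1L],
           ": expectancy must differ between the two members")
  }
  class(x) <- c("pair_design", "data.frame")
  x
}

#' Number of pairs in a design
#' @param design a `pair_design`.
#' @return N, the number of pairs.
#' @export
n_pairs <- function(design) length(unique(design$pair_id))

#' Build a randomized balanced pair design
#'
#' Constructs a synthetic design table: `n_pairs` pairs (2 sentences each),
#' half predicting nouns and half verbs, expectancy assigned to member 1 at
#' random, and SFW-1 tokens drawn from a vocabulary so that a controllable
#' fraction of sentences share their SFW-1 across pairs.
#'
#' @param n_pairs number of sentence pairs (N).
#' @param seed integer RNG seed.
#' @param n_sfw1_tokens size of the SFW-1 vocabulary the sentences draw
#'   from; smaller values produce more cross-pair SFW-1 sharing.
#' @return A `pair_design`.
#' @export
random_pair_design <- function(n_pairs, seed = 1L,
                               n_sfw1_tokens = 2L * n_pairs) {
  stopifnot(n_pairs >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_s <- 2L * n_pairs
  cat_half <- rep(c("noun", "verb"), length.out = n_pairs)
  exp_first <- sample(c(TRUE, FALSE), n_pairs, replace = TRUE)
  d <- data.frame(
    sentence_id = sprintf("S%03d", seq_len(n_s)),
    pair_id = rep(seq_len(n_pairs), each = 2L),
    member_index = rep(1:2, n_pairs),
    expectancy = as.vector(vapply(exp_first, function(e)
      if (e) c("expected", "unexpected") else c("unexpected", "expected"),
      character(2L))),
    category = rep(cat_half, each = 2L),
    sfw1_token = sprintf("w%03d", sample.int(n_sfw1_tokens, n_s,
                                             replace = TRUE)),
    stringsAsFactors = FALSE)
  pair_design(d)
}

new_comparison_set <- function(a, b, label) {
  structure(data.frame(sentence_a = a, sentence_b = b,
                       stringsAsFactors = FALSE),
            label = label, class = c("comparison_set", "data.frame"))
}

#' @export
print.comparison_set <- function(x, ...) {
  cat(sprintf("<comparison_set> label = %s, %d comparisons\n",
              attr(x, "label"), nrow(x)))
  invisible(x)
}

#' Enumerate within-pair comparisons
#'
#' One unordered comparison per pair: the two sentences that predict the
#' same SFW. For N pairs the count is exactly N.
#'
#' @param design a `pair_design`.
#' @return A `comparison_set` with label `"within"`.
#' @export
enumerate_within <- function(design) {
  stopifnot(inherits(design, "pair_design"))
  sp <- split(design$sentence_id, design$pair_id)
  a <- vapply(sp, `[`, "", 1L)
  b <- vapply(sp, `[`, "", 2L)
  new_comparison_set(unname(a), unname(b), "within")
}

#' Enumerate between-pair comparisons
#'
#' All unordered pairs of sentences whose members belong to different pairs.
#' For N pairs (2N sentences) the count is C(2N, 2) - N = 2N(N-1).
#'
#' @param design a `pair_design`.
#' @return A `comparison_set` with label `"between"`.
#' @export
enumerate_between <- function(design) {
  stopifnot(inherits(design, "pair_design"))
  cmb <- utils::combn(nrow(design), 2L)
  keep <- design$pair_id[cmb[1L, ]] != design$pair_id[cmb[2L, ]]
  new_comparison_set(design$sentence_id[cmb[1L, keep]],
                     design$sentence_id[cmb[2L, keep]], "between")
}

#' Random subsample of a comparison set
#'
#' Used for the matched-count control in which the between-pair comparisons
#' are subsampled to the number of within-pair comparisons.
#'
#' @param set a `comparison_set`.
#' @param k subset size; must not exceed `nrow(set)`.
#' @param seed integer RNG seed.
#' @return A `comparison_set` of `k` comparisons (same label, suffixed
#'   `"_subset"` unless `k` equals the full size).
#' @export
subsample_between <- function(set, k, seed = 1L) {
  stopifnot(inherits(set, "comparison_set"))
  n <- nrow(set)
  if (k > n) stop("k exceeds the number of comparisons (", n, ")")
  if (k == n) return(set)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  idx <- sort(sample.int(n, k))
  new_comparison_set(set$sentence_a[idx], set$sentence_b[idx],
                     paste0(attr(set, "label"), "_subset"))
}

#' Enumerate within-category (between-pair) comparisons
#'
#' Between-pair comparisons whose predicted SFWs share syntactic category
#' (noun with noun, verb with verb). Within-pair comparisons are excluded by
#' default: they share word identity, not merely category, and the analysis
#' contrasts category-only similarity against identity similarity.
#'
#' @param design a `pair_design` with a `category` column.
#' @param include_within also include the within-pair comparisons (the
#'   variant in which "all pairs predicting the same category" is read
#'   literally).
#' @return A `comparison_set` with label `"within_category"`.
#' @export
enumerate_within_category <- function(design, include_within = FALSE) {
  stopifnot(inherits(design, "pair_design"))
  if (is.null(design$category) || anyNA(design$category))
    stop("every sentence needs a category label")
  cmb <- utils::combn(nrow(design), 2L)
  same_cat <- design$category[cmb[1L, ]] == design$category[cmb[2L, ]]
  diff_pair <- design$pair_id[cmb[1L, ]] != design$pair_id[cmb[2L, ]]
  keep <- same_cat & (diff_pair | include_within)
  new_comparison_set(design$sentence_id[cmb[1L, keep]],
                     design$sentence_id[cmb[2L, keep]], "within_category")
}

#' Split the design by presentation order of pair members
#'
#' Partitions the pairs according to whether the expected-SFW or the
#' unexpected-SFW member was presented first, and returns the within- and
#' between-pair comparison sets restricted to each subset of pairs.
#'
#' @param design a `pair_design` with a `presentation_position` column
#'   (ordinal, no ties).
#' @return A list with elements `expected_first` and `unexpected_first`,
#'   each a list holding `pairs` (pair ids), `within` and `between`
#'   comparison sets.
#' @export
split_by_order <- function(design) {
  stopifnot(inherits(design, "pair_design"))
  pos <- design$presentation_position
  if (is.null(pos) || anyNA(pos)) stop("presentation_position not populated")
  if (anyDuplicated(pos)) stop("ties in presentation_position")
  sp <- split(seq_len(nrow(design)), design$pair_id)
  first_expected <- vapply(sp, function(i) {
    i1 <- i[which.min(pos[i])]
    design$expectancy[i1] == "expected"
  }, logical(1L))
  subset_cs <- function(pids) {
    sub <- design[design$pair_id %in% pids, , drop = FALSE]
    class(sub) <- c("pair_design", "data.frame")
    list(pairs = pids,
         within = enumerate_within(sub),
         between = if (length(pids) > 1L) enumerate_between(sub)
                   else new_comparison_set(character(0), character(0),
                                           "between"))
  }
  pid <- vapply(sp, function(i) design$pair_id[i[1L]],
                design$pair_id[1L])
  list(expected_first = subset_cs(pid[first_expected]),
       unexpected_first = subset_cs(pid[!first_expected]))
}

# Check a presentation order against the design constraints; returns a list
# with ok flag and diagnostics. Independent of the generator (brute scan).
check_presentation_order <- function(design, order_ids, min_separation,
                                     max_run) {
  pos <- match(design$sentence_id, order_ids)
  sep <- vapply(split(pos, design$pair_id),
                function(p) abs(diff(p)) - 1L, numeric(1L))
  expectancy <- design$expectancy[match(order_ids, design$sentence_id)]
  runs <- rle(expectancy)$lengths
  list(ok = all(sep >= min_separation) && all(runs <= max_run),
       min_separation = min(sep), max_run = max(runs))
}

#' Build a pseudo-randomized presentation order
#'
#' Emits an order of all 2N sentences in which at least `min_separation`
#' other sentences intervene between the two members of each pair and no
#' more than `max_run` sentences with the same expectancy occur in
#' succession. A random permutation is drawn and repaired by bounded
#' randomized moves; if no valid order is found within `max_attempts`
#' moves the function fails with a diagnostic.
#'
#' @param design a `pair_design`.
#' @param min_separation minimum number of sentences between pair members.
#' @param max_run maximum run length of equal-expectancy sentences.
#' @param seed integer RNG seed.
#' @param max_attempts bound on repair moves before giving up.
#' @return Character vector of sentence ids in presentation order, with the
#'   achieved minimum separation and maximum run as attributes.
#' @export
build_presentation_order <- function(design, min_separation = 30L,
                                     max_run = 3L, seed = 1L,
                                     max_attempts = 10000L) {
  stopifnot(inherits(design, "pair_design"))
  n <- nrow(design)
  if (min_separation >= n)
    stop("constraint unsatisfiable: min_separation >= number of sentences")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ids <- design$sentence_id
  expectancy <- design$expectancy
  pairof <- design$pair_id
  order_idx <- sample.int(n)

  violations <- function(ord) {
    pos <- integer(n); pos[ord] <- seq_len(n)
    bad <- integer(0)
    for (p in split(seq_len(n), pairof)) {
      if (abs(pos[p[1L]] - pos[p[2L]]) - 1L < min_separation)
        bad <- c(bad, p)
    }
    ex <- expectancy[ord]
    r <- rle(ex)
    if (any(r$lengths > max_run)) {
      ends <- cumsum(r$lengths)
      for (k in which(r$lengths > max_run))
        bad <- c(bad, ord[seq(ends[k] - r$lengths[k] + 1L, ends[k])])
    }
    unique(bad)
  }

  attempt <- 0L
  repeat {
    bad <- violations(order_idx)
    if (!length(bad)) break
    attempt <- attempt + 1L
    if (attempt > max_attempts)
      stop(sprintf(
        "constraint-failure: no valid order after %d moves (%d sentences in violation; min_separation=%d, max_run=%d)",
        max_attempts, length(bad), min_separation, max_run))
    # move one violating sentence to a random position (swap)
    v <- if (length(bad) == 1L) bad else sample(bad, 1L)
    i <- which(order_idx == v)
    j <- sample.int(n, 1L)
    order_idx[c(i, j)] <- order_idx[c(j, i)]
  }
  out <- ids[order_idx]
  chk <- check_presentation_order(design, out, min_separation, max_run)
  structure(out, min_separation = chk$min_separation,
            max_run = chk$max_run)
}

#' Select the same-SFW-1 control subsets
#'
#' The between subset contains sentence pairs from *different* pairs that
#' share exactly the same SFW-1 token (same pre-final word, different
#' predicted word). The within subset contains the within-pair comparisons
#' whose sentences participate in the between subset.
#'
#' @param design a `pair_design` with an `sfw1_token` column.
#' @return List with `within` and `between` comparison sets (possibly
#'   empty).
#' @export
select_same_sfw1_control <- function(design) {
  stopifnot(inherits(design, "pair_design"))
  if (is.null(design$sfw1_token)) stop("sfw1_token not populated")
  cmb <- utils::combn(nrow(design), 2L)
  same_tok <- design$sfw1_token[cmb[1L, ]] == design$sfw1_token[cmb[2L, ]]
  diff_pair <- design$pair_id[cmb[1L, ]] != design$pair_id[cmb[2L, ]]
  keep <- same_tok & diff_pair
  between <- new_comparison_set(design$sentence_id[cmb[1L, keep]],
                                design$sentence_id[cmb[2L, keep]],
                                "same_sfw1_between")
  used <- unique(c(between$sentence_a, between$sentence_b))
  pids <- unique(design$pair_id[design$sentence_id %in% used])
  win_all <- enumerate_within(design)
  in_sub <- design$pair_id[match(win_all$sentence_a,
                                 design$sentence_id)] %in% pids
  within <- new_comparison_set(win_all$sentence_a[in_sub],
                               win_all$sentence_b[in_sub],
                               "same_sfw_within")
  list(within = within, between = between)
}

#' Compare context properties between within- and between-pair comparisons
#'
#' For every property column, computes a per-comparison difference code
#' (absolute difference for numeric properties, 0/1 mismatch for
#' non-numeric) for all within-pair and all between-pair comparisons, and
#' runs an independent two-sample pooled-variance t-test of within vs
#' between codes.
#'
#' @param design a `pair_design`.
#' @param properties character vector of property column names.
#' @return data.frame with one row per property: `t`, `df`, `p`,
#'   `mean_within`, `mean_between`, and a `degenerate` flag when both groups
#'   have zero variance (statistic undefined).
#' @export
compare_pair_properties <- function(design, properties) {
  stopifnot(inherits(design, "pair_design"))
  miss <- setdiff(properties, names(design))
  if (length(miss)) stop("unknown properties: ", paste(miss, collapse = ", "))
  win <- enumerate_within(design)
  btw <- enumerate_between(design)
  code <- function(cs, col) {
    va <- design[[col]][match(cs$sentence_a, design$sentence_id)]
    vb <- design[[col]][match(cs$sentence_b, design$sentence_id)]
    if (is.numeric(va)) abs(va - vb) else as.numeric(va != vb)
  }
  res <- lapply(properties, function(col) {
    cw <- code(win, col); cb <- code(btw, col)
    if (stats::var(cw) == 0 && stats::var(cb) == 0) {
      md <- mean(cw) - mean(cb)
      data.frame(property = col,
                 t = if (md == 0) 0 else sign(md) * Inf,
                 df = length(cw) + length(cb) - 2L,
                 p = if (md == 0) NA_real_ else 0,
                 mean_within = mean(cw), mean_between = mean(cb),
                 degenerate = TRUE)
    } else {
      tt <- stats::t.test(cw, cb, var.equal = TRUE)
      data.frame(property = col, t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 mean_within = mean(cw), mean_between = mean(cb),
                 degenerate = FALSE)
    }
  })
  do.call(rbind, res)
}

# RNG bookkeeping: seeded helpers must not disturb the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
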