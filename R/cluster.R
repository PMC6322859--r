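# Cluster-based permutation machinery: neighborhood graphs, connected
# components, and the cluster-mass tests over time-by-time matrices,
# sensors, and source grid points.

#' Sensor (or grid-point) neighborhood graph
#'
#' Connects every pair of positions within `radius` mm (Euclidean). The
#' graph is symmetric with no self-edges.
#'
#' @param positions a `sensor_layout`, or a numeric matrix of 3-D positions
#'   (mm) with one row per sensor/grid point.
#' @param radius neighborhood radius in mm (40 mm for sensor-level
#'   analyses by default).
#' @return Object of class `neighbor_graph`: `adj` (list of integer
#'   neighbor vectors), `n`, `radius`, `ids`.
#' @export
neighbor_graph <- function(positions, radius = 40) {
  ids <- NULL
  if (inherits(positions, "sensor_layout")) {
    ids <- positions$id
    positions <- as.matrix(positions[, c("x", "y", "z")])
  }
  stopifnot(is.matrix(positions), radius >= 0)
  d <- as.matrix(stats::dist(positions))
  adj <- lapply(seq_len(nrow(d)), function(i) {
    nb <- which(d[i, ] <= radius)
    nb[nb != i]
  })
  structure(list(adj = adj, n = nrow(d), radius = radius,
                 ids = if (is.null(ids)) as.character(seq_len(nrow(d)))
                       else ids),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("<neighbor_graph> %d nodes, radius %g mm, mean degree %.2f\n",
              x$n, x$radius, mean(lengths(x$adj))))
  invisible(x)
}

# Connected components of a subset of graph nodes (BFS through adj lists
# restricted to `members`). Returns a list of integer vectors.
graph_components <- function(members, adj) {
  if (!length(members)) return(list())
  in_set <- logical(length(adj))
  in_set[members] <- TRUE
  seen <- logical(length(adj))
  comps <- list()
  for (s in members) {
    if (seen[s]) next
    comp <- integer(0)
    stack <- s
    seen[s] <- TRUE
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      comp <- c(comp, v)
      nb <- adj[[v]]
      nb <- nb[in_set[nb] & !seen[nb]]
      if (length(nb)) {
        seen[nb] <- TRUE
        stack <- c(stack, nb)
      }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# Connected components (4-connectivity) of cells in an nr x nc matrix.
# `mask_idx`: integer indices of supra-threshold cells. Returns a list of
# integer index vectors.
label_matrix_components <- function(mask_idx, nr, nc) {
  m <- length(mask_idx)
  if (!m) return(list())
  total <- nr * nc
  inmask <- logical(total)
  inmask[mask_idx] <- TRUE
  pos <- integer(total)
  pos[mask_idx] <- seq_len(m)
  row <- (mask_idx - 1L) %% nr + 1L
  down <- mask_idx[row < nr]
  down <- down[inmask[down + 1L]]
  right <- mask_idx[mask_idx + nr <= total]
  right <- right[inmask[right + nr]]
  edges <- c(rbind(pos[down], pos[down + 1L]),
             rbind(pos[right], pos[right + nr]))
  if (!length(edges)) return(as.list(mask_idx))
  g <- igraph::make_graph(edges, n = m, directed = FALSE)
  memb <- igraph::components(g)$membership
  unname(split(mask_idx, memb))
}

# Per-cell paired t statistics from a participant x cell difference
# matrix; zero-variance cells give t = 0 (never supra-threshold).
cellwise_t <- function(D) {
  n <- nrow(D)
  mu <- colMeans(D)
  v <- (colSums(D * D) - n * mu^2) / (n - 1L)
  t <- mu / sqrt(pmax(v, 0) / n)
  t[!is.finite(t)] <- 0
  t
}

# Max |cluster mass| over positive and negative supra-threshold components
# of a t map laid out as an nr x nc matrix.
max_mass_matrix <- function(tvec, nr, nc, crit) {
  mx <- 0
  for (sgn in c(1, -1)) {
    idx <- which(sgn * tvec > crit)
    for (cl in label_matrix_components(idx, nr, nc))
      mx <- max(mx, abs(sum(tvec[cl])))
  }
  mx
}

new_cluster_result <- function(clusters, null, n_perm, tail_p, info) {
  structure(c(list(clusters = clusters, null = null, n_perm = n_perm,
                   tail_p = tail_p), info), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s), %d permutations\n",
              length(x$clusters), x$n_perm))
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  #%d: %d members, mass %.3f, p = %.4g%s\n", i,
                length(cl$cells), cl$mass, cl$p,
                if (cl$significant) " *" else ""))
  }
  invisible(x)
}

#' Significant clusters of a cluster_result
#' @param x a `cluster_result`.
#' @return The subset of clusters with `significant = TRUE`.
#' @export
significant_clusters <- function(x) {
  stopifnot(inherits(x, "cluster_result"))
  Filter(function(cl) isTRUE(cl$significant), x$clusters)
}

#' Cluster permutation test over cross-temporal similarity matrices
#'
#' Paired t-tests at every (i, j) cell of the within- vs between-pair
#' cross-temporal matrices across participants; cells with uncorrected
#' p <= `alpha_cell` form clusters under 4-connectivity (edge-adjacent
#' cells); the cluster mass is the sum of t values. The null distribution
#' re-assigns the condition labels within each participant (equivalently,
#' flips the sign of the participant's difference matrix), recomputes the
#' max |cluster mass| per permutation, and a cluster is significant when
#' its `(b+1)/(n_perm+1)` p-value is at most `tail_p` (two-sided testing
#' with 2.5% tails by default).
#'
#' @param within,between 3-D arrays `n_participants x n_row x n_col` of
#'   per-participant averaged cross-temporal matrices on common time axes.
#' @param times_row,times_col optional time axes (seconds) carried into the
#'   result.
#' @param n_perm number of permutations.
#' @param seed integer RNG seed.
#' @param alpha_cell uncorrected cell-level threshold.
#' @param tail_p per-tail significance level.
#' @return A `cluster_result`; each cluster records `cells` (matrix
#'   indices), `mass`, `sign`, `p`, `significant`, and mean |row - col|
#'   `lag_s` when time axes are supplied.
#' @export
matrix_cluster_test <- function(within, between, times_row = NULL,
                                times_col = NULL, n_perm = 1000L,
                                seed = 1L, alpha_cell = 0.05,
                                tail_p = 0.025) {
  if (n_perm < 1L) stop("invalid-argument: n_perm must be >= 1")
  stopifnot(length(dim(within)) == 3L, all(dim(within) == dim(between)))
  n <- dim(within)[1L]
  if (n < 2L) stop("invalid-argument: need >= 2 participants")
  nr <- dim(within)[2L]; nc <- dim(within)[3L]
  D <- matrix(within - between, n)      # participant x cells
  D[is.na(D)] <- 0
  tvec <- cellwise_t(D)
  crit <- stats::qt(1 - alpha_cell / 2, n - 1L)

  clusters <- list()
  for (sgn in c(1, -1)) {
    idx <- which(sgn * tvec > crit)
    for (cl in label_matrix_components(idx, nr, nc)) {
      lag <- NA_real_
      if (!is.null(times_row) && !is.null(times_col)) {
        ri <- (cl - 1L) %% nr + 1L
        ci <- (cl - 1L) %/% nr + 1L
        lag <- mean(abs(times_row[ri] - times_col[ci]))
      }
      clusters[[length(clusters) + 1L]] <-
        list(cells = cl, mass = sum(tvec[cl]), sign = sgn, lag_s = lag)
    }
  }

  flips <- flip_matrix(n, n_perm, seed)
  ss <- colSums(D * D)
  null <- numeric(n_perm)
  chunk <- 64L
  for (start in seq(1L, n_perm, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n_perm)
    M <- (flips[rows, , drop = FALSE] %*% D) / n
    for (k in seq_along(rows)) {
      mu <- M[k, ]
      v <- (ss - n * mu^2) / (n - 1L)
      tp <- mu / sqrt(pmax(v, 0) / n)
      tp[!is.finite(tp)] <- 0
      null[rows[k]] <- max_mass_matrix(tp, nr, nc, crit)
    }
  }
  for (i in seq_along(clusters)) {
    p <- perm_pvalue(abs(clusters[[i]]$mass), null)
    clusters[[i]]$p <- p
    clusters[[i]]$significant <- p <= tail_p
  }
  new_cluster_result(clusters, null, n_perm, tail_p,
                     list(statistic = "summed t", cell_threshold = crit,
                          dim = c(nr, nc), times_row = times_row,
                          times_col = times_col))
}

#' Cluster permutation test over sensors (or grid points)
#'
#' Thresholds the group-mean within-minus-between difference map at its
#' 95th percentile across sensors (and, for the negative tail, at the 5th
#' percentile); supra-threshold sensors within the neighborhood graph form
#' clusters; the cluster mass is the summed mean difference. The identical
#' statistic -- percentile threshold recomputed from the permuted map --
#' is evaluated inside every sign-flip permutation, and the max |mass|
#' forms the null.
#'
#' @param within,between matrices `n_participants x n_sensors` of
#'   per-participant averaged temporal-similarity maps.
#' @param graph a [neighbor_graph()] over the same sensors.
#' @param n_perm number of permutations.
#' @param seed integer RNG seed.
#' @param threshold_percentile percentile (of the map across sensors) used
#'   to form clusters.
#' @param tail_p per-tail significance level.
#' @return A `cluster_result`; clusters record `cells` (sensor indices),
#'   `ids`, `mass`, `sign`, `p`, `significant`.
#' @export
sensor_cluster_test <- function(within, between, graph, n_perm = 1000L,
                                seed = 1L, threshold_percentile = 95,
                                tail_p = 0.025) {
  if (n_perm < 1L) stop("invalid-argument: n_perm must be >= 1")
  stopifnot(inherits(graph, "neighbor_graph"),
            is.matrix(within), all(dim(within) == dim(between)))
  if (ncol(within) != graph$n)
    stop("maps and graph disagree on the number of sensors")
  n <- nrow(within)
  if (n < 2L) stop("invalid-argument: need >= 2 participants")
  D <- within - between
  D[is.na(D)] <- 0

  clusters_of <- function(d) {
    out <- list()
    hi <- percentile(d, threshold_percentile)
    lo <- percentile(d, 100 - threshold_percentile)
    for (sgn in c(1, -1)) {
      idx <- if (sgn > 0) which(d > hi) else which(d < lo)
      for (cl in graph_components(idx, graph$adj))
        out[[length(out) + 1L]] <- list(cells = cl, mass = sum(d[cl]),
                                        sign = sgn)
    }
    out
  }

  d_obs <- colMeans(D)
  clusters <- clusters_of(d_obs)
  flips <- flip_matrix(n, n_perm, seed)
  null <- vapply(seq_len(n_perm), function(i) {
    cls <- clusters_of(colMeans(D * flips[i, ]))
    if (!length(cls)) 0 else max(abs(vapply(cls, `[[`, 0, "mass")))
  }, numeric(1L))
  for (i in seq_along(clusters)) {
    p <- perm_pvalue(abs(clusters[[i]]$mass), null)
    clusters[[i]]$p <- p
    clusters[[i]]$significant <- p <= tail_p
    clusters[[i]]$ids <- graph$ids[clusters[[i]]$cells]
  }
  new_cluster_result(clusters, null, n_perm, tail_p,
                     list(statistic = "summed mean difference",
                          threshold_percentile = threshold_percentile,
                          mean_difference = d_obs))
}

#' Cluster permutation test over source grid points
#'
#' [sensor_cluster_test()] with clusters formed by contiguous grid points:
#' the neighborhood graph connects points within 1.1 grid-spacing steps
#' (the 6 face neighbors of a regular lattice).
#'
#' @param within,between matrices `n_participants x n_grid` of source-level
#'   temporal-similarity maps.
#' @param forward the `forward_model` holding the grid geometry.
#' @param ... passed on to [sensor_cluster_test()].
#' @return A `cluster_result`.
#' @export
grid_cluster_test <- function(within, between, forward, ...) {
  stopifnot(inherits(forward, "forward_model"))
  g <- neighbor_graph(forward$grid_positions,
                      radius = 1.1 * forward$grid_spacing)
  sensor_cluster_test(within, between, g, ...)
}
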