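# Row-standardize so that tcrossprod(xs, ys) / (frames - 1) is Pearson r.
row_standardize <- function(m) {
  mu <- rowMeans(m)
  cen <- m - mu
  s <- sqrt(rowSums(cen^2) / (ncol(m) - 1))
  s[s == 0] <- NA_real_
  cen / s
}

#' Pairwise Pearson correlation of z-scored traces
#'
#' @param z Numeric matrix, neurons x frames (typically from
#'   [zscore_traces()]).
#' @return A `ca_corr`: symmetric correlation matrix `r` (diagonal 1,
#'   zero-variance pairs `NA`) and `n_frames`.
#' @export
pairwise_correlation <- function(z) {
  assert_matrix(z, "z")
  if (nrow(z) < 2 || ncol(z) < 3) {
    abort("Need >= 2 neurons and >= 3 frames.", class = "catraces_invalid_parameter")
  }
  zs <- row_standardize(z)
  r <- tcrossprod(zs) / (ncol(z) - 1)
  r[r > 1] <- 1; r[r < -1] <- -1
  r <- (r + t(r)) / 2
  diag(r) <- ifelse(is.na(diag(r)), NA, 1)
  structure(list(r = r, n_frames = ncol(z)), class = "ca_corr")
}

# One stationary-bootstrap index schedule: geometric block lengths with
# mean `mean_block`, uniform random start per block, circular wrap.
stationary_bootstrap_indices <- function(n_frames, mean_block) {
  p <- 1 / mean_block
  jump <- c(TRUE, runif(n_frames - 1) < p)
  block <- cumsum(jump)
  starts <- sample.int(n_frames, max(block), replace = TRUE)
  block_start_t <- which(jump)[block]
  ((starts[block] + (seq_len(n_frames) - block_start_t) - 1L) %% n_frames) + 1L
}

#' Stationary block-bootstrap null for pairwise correlations
#'
#' For every neuron pair, the second member's trace is resampled by the
#' stationary bootstrap (random start points, geometric block lengths with
#' mean `mean_block_frames`, circular wrap-around), which preserves its
#' autocorrelation while destroying any cross-correlation; Pearson r is
#' recomputed per iteration and the pair's significance threshold is the
#' `quantile` (default 99th) percentile of this null distribution. One
#' shared resampling schedule per iteration is applied to all neurons,
#' which keeps the cost linear in iterations rather than in pairs.
#'
#' @param z Neurons x frames matrix of z-scored traces.
#' @param n_iterations Bootstrap iterations (5000 in full analyses).
#' @param mean_block_frames Mean block length, frames (23 frames = 1.84 s
#'   at a 12.5-Hz effective rate).
#' @param quantile Null quantile defining significance.
#' @param seed Integer seed.
#' @return A `ca_bootnull`: symmetric per-pair `threshold` matrix and the
#'   parameters used.
#' @export
stationary_bootstrap_null <- function(z, n_iterations = 5000,
                                      mean_block_frames = 23,
                                      quantile = 0.99, seed = 1L) {
  assert_matrix(z, "z")
  n <- nrow(z); n_frames <- ncol(z)
  if (n_frames <= mean_block_frames) {
    abort("Need more frames than the mean block length.",
          class = "catraces_invalid_parameter")
  }
  if (n_iterations < 100) warn("Fewer than 100 iterations: unstable quantile.")
  set.seed(seed)
  zs <- row_standardize(z)
  up <- which(upper.tri(matrix(0, n, n)))
  nulls <- matrix(NA_real_, length(up), n_iterations)
  for (it in seq_len(n_iterations)) {
    idx <- stationary_bootstrap_indices(n_frames, mean_block_frames)
    zb <- row_standardize(z[, idx, drop = FALSE])
    r_it <- tcrossprod(zs, zb) / (n_frames - 1)
    nulls[, it] <- r_it[up]
  }
  thr_vals <- apply(nulls, 1, stats::quantile, probs = quantile,
                    names = FALSE, type = 7, na.rm = TRUE)
  threshold <- matrix(NA_real_, n, n)
  threshold[up] <- thr_vals
  threshold[lower.tri(threshold)] <- t(threshold)[lower.tri(threshold)]
  structure(list(threshold = threshold, n_iterations = n_iterations,
                 mean_block_frames = mean_block_frames,
                 quantile = quantile, seed = seed),
            class = "ca_bootnull")
}

#' Euclidean distances between ROI centroids
#'
#' @param centroids Tibble with `x_um`, `y_um` columns (and optionally
#'   `id`), or a two-column matrix.
#' @return Symmetric distance matrix, um.
#' @export
centroid_distances <- function(centroids) {
  xy <- if (is.data.frame(centroids)) {
    as.matrix(centroids[, c("x_um", "y_um")])
  } else {
    as.matrix(centroids)
  }
  if (nrow(xy) < 2) abort("Need at least 2 centroids.",
                          class = "catraces_invalid_parameter")
  as.matrix(dist(xy))
}

#' Build the functional connectivity graph
#'
#' Edges are neuron pairs whose Pearson r exceeds that pair's bootstrap
#' threshold. Reports per-neuron significant and strong (r > 0.3 among
#' significant) connection counts, population connections-per-neuron
#' (edges / neurons), and connection density as a percent of the
#' `n (n - 1) / 2` possible pairs. Pairs with undefined correlations are
#' excluded from edges but remain in the density denominator.
#'
#' @param corr A `ca_corr`.
#' @param null A `ca_bootnull` over the same neurons.
#' @param centroids Optional centroid tibble for node positions and edge
#'   distances.
#' @param strong_threshold Strong-edge correlation cut-off.
#' @return A `ca_graph`: `edges` and `nodes` tibbles plus scalar metrics.
#' @export
build_graph <- function(corr, null, centroids = NULL, strong_threshold = 0.3) {
  stopifnot(inherits(corr, "ca_corr"), inherits(null, "ca_bootnull"))
  r <- corr$r
  n <- nrow(r)
  if (!all(dim(null$threshold) == dim(r))) {
    abort("Correlation and null cover different neuron sets.",
          class = "catraces_dimension_error")
  }
  dmat <- if (!is.null(centroids)) centroid_distances(centroids) else NULL
  ij <- which(upper.tri(r), arr.ind = TRUE)
  rv <- r[upper.tri(r)]
  tv <- null$threshold[upper.tri(r)]
  sig <- !is.na(rv) & !is.na(tv) & rv > tv
  edges <- tibble(i = ij[sig, 1], j = ij[sig, 2], r = rv[sig],
                  threshold = tv[sig],
                  strong = rv[sig] > strong_threshold,
                  distance_um = if (!is.null(dmat)) dmat[ij[sig, , drop = FALSE]]
                                else NA_real_)
  n_sig <- tabulate(c(edges$i, edges$j), nbins = n)
  n_strong <- tabulate(c(edges$i[edges$strong], edges$j[edges$strong]), nbins = n)
  nodes <- tibble(neuron = seq_len(n),
                  x_um = if (!is.null(centroids)) centroids$x_um else NA_real_,
                  y_um = if (!is.null(centroids)) centroids$y_um else NA_real_,
                  n_significant = n_sig, n_strong = n_strong)
  structure(list(edges = edges, nodes = nodes, n_neurons = n,
                 connections_per_neuron = nrow(edges) / n,
                 strong_connections_per_neuron = sum(edges$strong) / n,
                 density_percent = 100 * nrow(edges) / (n * (n - 1) / 2),
                 strong_threshold = strong_threshold),
            class = "ca_graph")
}
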