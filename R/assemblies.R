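# The "first clear minimum" of the kernel-smoothed distribution of per-ROI
# maximal z-scored loadings: located as the deepest trough between the two
# highest density peaks, which ignores shallow wiggles inside either mode.
first_local_minimum <- function(x) {
  d <- density(x)
  y <- d$y
  maxs <- which(diff(sign(diff(y))) == -2) + 1L
  mins <- which(diff(sign(diff(y))) == 2) + 1L
  if (length(maxs) < 2 || length(mins) == 0) {
    # unimodal distribution: no trough separating member from non-member mode
    warn("No clear minimum in the loading distribution; using the mean.")
    return(mean(x))
  }
  top2 <- sort(maxs[order(y[maxs], decreasing = TRUE)][1:2])
  cand <- mins[mins > top2[1] & mins < top2[2]]
  if (length(cand) == 0) {
    warn("No clear minimum in the loading distribution; using the mean.")
    return(mean(x))
  }
  d$x[cand[which.min(y[cand])]]
}

#' Number of significant principal components
#'
#' Counts eigenvalues of the neurons' correlation matrix exceeding a null
#' bound. The default `"circular_shift"` null circularly shifts each
#' neuron's trace by an independent random offset — preserving every
#' trace's autocorrelation (calcium traces are strongly autocorrelated
#' through the indicator kernel) while destroying co-activation — and
#' takes the largest surrogate eigenvalue over `n_shuffles` shuffles as
#' the bound. The `"marchenko_pastur"` alternative uses the analytic
#' i.i.d. upper edge `(1 + sqrt(n_neurons / n_frames))^2`, which is exact
#' for white traces but too permissive for autocorrelated ones. Under
#' either null, pure i.i.d. noise yields ~0 components and each planted
#' co-activating group adds one.
#'
#' @param z Neurons x frames matrix of z-scored traces.
#' @param method Null model for the eigenvalue bound.
#' @param n_shuffles Surrogate count for the circular-shift null.
#' @param seed Integer seed for the surrogate shuffles.
#' @return Integer count of supra-bound components.
#' @export
select_significant_pcs <- function(z,
                                   method = c("circular_shift",
                                              "marchenko_pastur"),
                                   n_shuffles = 10, seed = 1L) {
  method <- match.arg(method)
  assert_matrix(z, "z")
  if (nrow(z) < 3) abort("Need >= 3 neurons.", class = "catraces_invalid_parameter")
  zs <- row_standardize(z)
  if (any(is.na(zs))) {
    warn("Zero-variance rows in `z`; they contribute no components.")
    zs[is.na(zs)] <- 0
  }
  n_frames <- ncol(z)
  C <- tcrossprod(zs) / (n_frames - 1)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  bound <- if (method == "marchenko_pastur") {
    (1 + sqrt(nrow(z) / n_frames))^2
  } else {
    set.seed(seed)
    max(vapply(seq_len(n_shuffles), function(s) {
      shifts <- sample.int(n_frames, nrow(zs), replace = TRUE) - 1L
      zsh <- zs
      for (i in seq_len(nrow(zs))) {
        if (shifts[i] > 0) {
          zsh[i, ] <- zs[i, c((shifts[i] + 1L):n_frames, 1:shifts[i])]
        }
      }
      max(eigen(tcrossprod(zsh) / (n_frames - 1), symmetric = TRUE,
                only.values = TRUE)$values)
    }, numeric(1)))
  }
  sum(ev > bound)
}

#' Detect candidate assemblies by PCA with Promax rotation
#'
#' Computes PCA loadings of the z-scored population, relaxes orthogonality
#' with an oblique Promax rotation (so neurons may belong to several
#' assemblies), z-scores each component's loadings, and assigns membership
#' to neurons whose z-scored loading exceeds `z_max`. By default `z_max` is
#' the first local minimum of the smoothed distribution of each ROI's
#' maximal z-scored loading — an automated stand-in for a manual pick on
#' that distribution — and can be overridden.
#'
#' @param z Neurons x frames matrix of z-scored traces.
#' @param n_pcs Number of components to rotate (see
#'   [select_significant_pcs()]).
#' @param promax_power Promax power (conventional default 4).
#' @param z_max Optional fixed membership threshold.
#' @return A `ca_assemblies` model (pre-merge, pre-surrogate): memberships,
#'   z-scored `loadings`, `z_max`, `n_pcs`, empty `merge_log`.
#' @export
promax_assemblies <- function(z, n_pcs, promax_power = 4, z_max = NULL) {
  assert_matrix(z, "z")
  assert_scalar(n_pcs, "n_pcs", lower = 1)
  n <- nrow(z)
  zs <- row_standardize(z)
  C <- tcrossprod(zs) / (ncol(z) - 1)
  eig <- eigen(C, symmetric = TRUE)
  k <- min(n_pcs, sum(eig$values > 0))
  L <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(eig$values[seq_len(k)]), k, k)
  RL <- if (k >= 2) {
    rot <- tryCatch(promax(L, m = promax_power),
                    error = function(e) abort(
                      paste0("Promax rotation failed: ", conditionMessage(e)),
                      class = "catraces_rotation_error"))
    unclass(rot$loadings)
  } else L
  # orient each component so its dominant loading is positive
  for (cc in seq_len(ncol(RL))) {
    if (RL[which.max(abs(RL[, cc])), cc] < 0) RL[, cc] <- -RL[, cc]
  }
  zl <- scale(RL)
  max_load <- apply(zl, 1, max)
  if (is.null(z_max)) z_max <- first_local_minimum(max_load)
  memberships <- lapply(seq_len(ncol(zl)), function(cc) which(zl[, cc] > z_max))
  if (all(lengths(memberships) == 0)) {
    warn("All memberships empty at this z_max; model flagged.")
  }
  structure(list(memberships = memberships, loadings = zl,
                 raw_loadings = RL, z_max = z_max, n_pcs = as.integer(n_pcs),
                 promax_power = promax_power, n_neurons = n,
                 merge_log = tibble(a = integer(), b = integer(), dot = numeric()),
                 synchrony_p = rep(NA_real_, ncol(zl)),
                 max_loadings = max_load),
            class = "ca_assemblies")
}

# Normalized indicator dot product |A intersect B| / sqrt(|A| |B|).
membership_dot <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) return(0)
  length(intersect(a, b)) / sqrt(length(a) * length(b))
}

#' Merge highly overlapping assemblies
#'
#' Oblique rotation can split one cell group across components; membership
#' indicator vectors (normalized to unit length) whose dot product exceeds
#' `overlap_threshold` (default 0.6) are merged. Merging is greedy —
#' repeatedly union the pair with the largest dot product, ties broken by
#' lower component index — until no pair exceeds the threshold.
#'
#' @param model A `ca_assemblies`.
#' @param overlap_threshold Dot-product threshold for merging.
#' @return The model with merged memberships and a `merge_log`.
#' @export
merge_assemblies <- function(model, overlap_threshold = 0.6) {
  stopifnot(inherits(model, "ca_assemblies"))
  mem <- model$memberships
  log <- list()
  repeat {
    k <- length(mem)
    if (k < 2) break
    best <- c(0, 0); best_dot <- -Inf
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        d <- membership_dot(mem[[a]], mem[[b]])
        if (d > best_dot) { best_dot <- d; best <- c(a, b) }
      }
    }
    if (best_dot <= overlap_threshold) break
    log[[length(log) + 1]] <- tibble(a = best[1], b = best[2], dot = best_dot)
    mem[[best[1]]] <- sort(union(mem[[best[1]]], mem[[best[2]]]))
    mem[[best[2]]] <- NULL
  }
  model$memberships <- mem
  model$merge_log <- bind_rows(model$merge_log, bind_rows(log))
  model$synchrony_p <- rep(NA_real_, length(mem))
  model
}

#' Surrogate test of assembly synchrony
#'
#' Compares each assembly's peak frame-wise event co-activation count
#' against surrogate datasets in which every member's event train is
#' independently circularly shifted (preserving rates and autostructure,
#' destroying synchrony).
#' `p = (1 + #{surrogate peak >= observed}) / (n_surrogates + 1)`.
#' Assemblies with `p >= p_threshold` or fewer than 2 members are dropped.
#' Event trains are onset frames: for a `ca_raster` the onset of each
#' detected transient, for a plain logical matrix its TRUE frames.
#'
#' @param model A `ca_assemblies`.
#' @param raster A `ca_raster` (or logical neurons x frames matrix of point
#'   events) aligned with the traces the model was fit on.
#' @param n_surrogates Number of surrogate datasets.
#' @param p_threshold Retention threshold.
#' @param seed Integer seed.
#' @return The model with `synchrony_p` for retained assemblies and a
#'   `dropped` record.
#' @export
test_assembly_synchrony <- function(model, raster, n_surrogates = 1000,
                                    p_threshold = 0.05, seed = 1L) {
  stopifnot(inherits(model, "ca_assemblies"))
  active <- if (inherits(raster, "ca_raster")) onset_raster(raster) else raster
  if (n_surrogates < 100) warn("Fewer than 100 surrogates: unstable p-values.")
  set.seed(seed)
  n_frames <- ncol(active)
  res <- map(model$memberships, function(mem) {
    if (length(mem) < 2) return(list(p = NA_real_, keep = FALSE))
    sub <- active[mem, , drop = FALSE]
    obs <- max(colSums(sub))
    hits <- 0L
    for (s in seq_len(n_surrogates)) {
      shifted <- matrix(FALSE, nrow(sub), n_frames)
      for (r in seq_len(nrow(sub))) {
        sh <- sample.int(n_frames, 1L) - 1L
        shifted[r, ] <- sub[r, ((seq_len(n_frames) - 1L + sh) %% n_frames) + 1L]
      }
      if (max(colSums(shifted)) >= obs) hits <- hits + 1L
    }
    p <- (hits + 1) / (n_surrogates + 1)
    list(p = p, keep = p < p_threshold)
  })
  keep <- map_lgl(res, "keep")
  model$dropped <- tibble(
    assembly = which(!keep),
    size = lengths(model$memberships[!keep]),
    synchrony_p = map_dbl(res[!keep], "p"))
  model$memberships <- model$memberships[keep]
  model$synchrony_p <- map_dbl(res[keep], "p")
  model
}

#' Matching-index activation series
#'
#' `MI(a, t)` is the proportion of assembly `a`'s members active at frame
#' `t` (1 = perfect co-activation). The alternative `"jaccard"` method
#' divides instead by the union of members and all active neurons.
#'
#' @param raster A `ca_raster` or logical neurons x frames matrix.
#' @param memberships List of member index vectors (or a `ca_assemblies`).
#' @param method `"proportion"` (default) or `"jaccard"`.
#' @return Matrix, assemblies x frames, values in `[0, 1]`.
#' @export
matching_index_series <- function(raster, memberships,
                                  method = c("proportion", "jaccard")) {
  method <- match.arg(method)
  active <- if (inherits(raster, "ca_raster")) raster$active else raster
  if (inherits(memberships, "ca_assemblies")) memberships <- memberships$memberships
  if (length(memberships) == 0 || any(lengths(memberships) == 0)) {
    abort("Memberships must be non-empty.", class = "catraces_invalid_parameter")
  }
  m_t <- colSums(active)
  out <- t(vapply(memberships, function(mem) {
    k <- colSums(active[mem, , drop = FALSE])
    if (method == "proportion") k / length(mem)
    else ifelse(k == 0, 0, k / (length(mem) + m_t - k))
  }, numeric(ncol(active))))
  out
}

#' Hypergeometric activation significance
#'
#' At each frame, the probability of observing at least `k` assembly
#' members among the `m` active neurons drawn without replacement from the
#' population of `N` ROIs is the hypergeometric upper tail; frames with
#' `p < p_threshold` are significant activations.
#'
#' @param raster A `ca_raster` or logical matrix.
#' @param memberships List of member index vectors (or `ca_assemblies`).
#' @param p_threshold Significance threshold.
#' @return List with `p` and logical `significant` matrices
#'   (assemblies x frames).
#' @export
activation_significance <- function(raster, memberships, p_threshold = 0.05) {
  active <- if (inherits(raster, "ca_raster")) raster$active else raster
  if (inherits(memberships, "ca_assemblies")) memberships <- memberships$memberships
  N <- nrow(active)
  if (any(lengths(memberships) > N)) {
    abort("Assembly larger than the population.", class = "catraces_invalid_parameter")
  }
  m_t <- colSums(active)
  p <- t(vapply(memberships, function(mem) {
    K <- length(mem)
    k <- colSums(active[mem, , drop = FALSE])
    phyper(k - 1, K, N - K, m_t, lower.tail = FALSE)
  }, numeric(ncol(active))))
  list(p = p, significant = p < p_threshold)
}

#' Assembly activation series with significance masking
#'
#' Combines the matching index with hypergeometric activation significance;
#' `percent_of_max` is the matching index multiplied by the Boolean
#' significance series, scaled to percent — the series used for
#' assembly-assembly and assembly-speed correlations.
#'
#' @inheritParams activation_significance
#' @inheritParams matching_index_series
#' @param frame_rate_hz Frame rate of the raster (metadata).
#' @return A `ca_activation`: `matching_index`, `p`, `significant`,
#'   `percent_of_max`, and `masked` (MI x significance).
#' @export
assembly_activation <- function(raster, memberships, p_threshold = 0.05,
                                method = "proportion", frame_rate_hz = NULL) {
  if (inherits(memberships, "ca_assemblies")) memberships <- memberships$memberships
  mi <- matching_index_series(raster, memberships, method)
  sig <- activation_significance(raster, memberships, p_threshold)
  fs <- frame_rate_hz %||%
    (if (inherits(raster, "ca_raster")) raster$frame_rate_hz else NA_real_)
  structure(list(matching_index = mi, p = sig$p, significant = sig$significant,
                 masked = mi * sig$significant,
                 percent_of_max = 100 * mi * sig$significant,
                 p_threshold = p_threshold, frame_rate_hz = fs),
            class = "ca_activation")
}

#' Assembly-assembly correlations
#'
#' Pearson r between significance-masked matching-index series for every
#' assembly pair, with the same stationary-bootstrap significance test used
#' for neuron pairs. The mean r is reported over significant pairs only.
#'
#' @param activation A `ca_activation`.
#' @param n_iterations,mean_block_frames,quantile Bootstrap parameters, see
#'   [stationary_bootstrap_null()].
#' @param seed Integer seed.
#' @return List: `pairs` tibble `(i, j, r, threshold, significant)` and
#'   `mean_r_significant`.
#' @export
assembly_assembly_correlation <- function(activation, n_iterations = 1000,
                                          mean_block_frames = 23,
                                          quantile = 0.99, seed = 1L) {
  stopifnot(inherits(activation, "ca_activation"))
  m <- activation$masked
  if (nrow(m) < 2) abort("Need >= 2 assemblies.", class = "catraces_invalid_parameter")
  sds <- apply(m, 1, sd)
  if (any(sds == 0)) warn("Constant masked series: those pairs are undefined.")
  corr <- pairwise_correlation(m)
  null <- stationary_bootstrap_null(m, n_iterations, mean_block_frames,
                                    quantile, seed)
  ij <- which(upper.tri(corr$r), arr.ind = TRUE)
  rv <- corr$r[upper.tri(corr$r)]
  tv <- null$threshold[upper.tri(corr$r)]
  ok <- !is.na(rv) & !is.na(tv)
  pairs <- tibble(i = ij[, 1], j = ij[, 2], r = rv, threshold = tv,
                  significant = ok & rv > tv)[ok, ]
  list(pairs = pairs,
       mean_r_significant = if (any(pairs$significant))
         mean(pairs$r[pairs$significant]) else NA_real_)
}

#' Assembly-speed correlations
#'
#' Pearson r of each assembly's masked matching-index series against the
#' frame-aligned speed trace; significance from a stationary bootstrap of
#' the speed trace.
#'
#' @param activation A `ca_activation`.
#' @param speed Speed trace at the raster's frame rate.
#' @param n_iterations,mean_block_frames,quantile Bootstrap parameters.
#' @param seed Integer seed.
#' @return Tibble `(assembly, r, threshold, significant)` with the fraction
#'   of movement-correlated assemblies as attribute `fraction_significant`.
#' @export
assembly_speed_correlation <- function(activation, speed, n_iterations = 1000,
                                       mean_block_frames = 23,
                                       quantile = 0.99, seed = 1L) {
  stopifnot(inherits(activation, "ca_activation"))
  m <- activation$masked
  if (nrow(m) == 0) return(tibble(assembly = integer(), r = numeric(),
                                  threshold = numeric(), significant = logical()))
  if (length(speed) != ncol(m)) {
    abort("Speed and activation series differ in frame count.",
          class = "catraces_dimension_error")
  }
  if (sd(speed) == 0) {
    warn("Constant speed trace: correlations undefined.")
    return(tibble(assembly = seq_len(nrow(m)), r = NA_real_,
                  threshold = NA_real_, significant = NA))
  }
  r_obs <- apply(m, 1, function(row)
    if (sd(row) == 0) NA_real_ else cor(row, speed))
  set.seed(seed)
  nulls <- matrix(NA_real_, nrow(m), n_iterations)
  for (it in seq_len(n_iterations)) {
    idx <- stationary_bootstrap_indices(length(speed), mean_block_frames)
    sp_b <- speed[idx]
    nulls[, it] <- apply(m, 1, function(row)
      if (sd(row) == 0) NA_real_ else cor(row, sp_b))
  }
  thr <- apply(nulls, 1, stats::quantile, probs = quantile, names = FALSE,
               na.rm = TRUE)
  out <- tibble(assembly = seq_len(nrow(m)), r = r_obs, threshold = thr,
                significant = !is.na(r_obs) & r_obs > thr)
  attr(out, "fraction_significant") <-
    if (all(is.na(out$significant))) NA_real_ else mean(out$significant, na.rm = TRUE)
  out
}

#' End-to-end assembly detection
#'
#' Chains component selection, Promax rotation and membership thresholding,
#' overlap merging, and the circular-shift synchrony test.
#'
#' @param z Neurons x frames matrix of z-scored traces.
#' @param raster A `ca_raster` aligned with `z`.
#' @param promax_power,z_max See [promax_assemblies()].
#' @param overlap_threshold See [merge_assemblies()].
#' @param n_surrogates,p_synchrony See [test_assembly_synchrony()].
#' @param seed Integer seed.
#' @return A retained `ca_assemblies` model.
#' @export
find_assemblies <- function(z, raster, promax_power = 4, z_max = NULL,
                            overlap_threshold = 0.6, n_surrogates = 1000,
                            p_synchrony = 0.05, seed = 1L) {
  n_pcs <- select_significant_pcs(z, seed = stage_seed(seed, 23L))
  if (n_pcs == 0) {
    warn("No significant components: returning an empty model.")
    return(structure(list(memberships = list(), loadings = NULL,
                          z_max = NA_real_, n_pcs = 0L,
                          merge_log = tibble(a = integer(), b = integer(),
                                             dot = numeric()),
                          synchrony_p = numeric(), n_neurons = nrow(z),
                          dropped = tibble()),
                     class = "ca_assemblies"))
  }
  model <- promax_assemblies(z, n_pcs, promax_power, z_max)
  model <- merge_assemblies(model, overlap_threshold)
  test_assembly_synchrony(model, raster, n_surrogates, p_synchrony, seed)
}
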