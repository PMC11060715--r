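#' Group-average frames
#'
#' Averages consecutive groups of `k` frames (the standard pair-averaging of
#' 25-Hz acquisitions to an effective 12.5 Hz uses `k = 2`). Trailing frames
#' that do not complete a group are dropped.
#'
#' @param x Numeric matrix, neurons x frames, or a numeric vector.
#' @param k Group size (>= 1).
#' @return Matrix (or vector) with `floor(frames / k)` frames.
#' @export
group_average_frames <- function(x, k = 2) {
  assert_scalar(k, "k", lower = 1)
  k <- as.integer(k)
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  assert_matrix(x, "x")
  if (k == 1) return(if (vec) drop(x) else x)
  n_out <- floor(ncol(x) / k)
  if (n_out == 0) {
    abort("Group size `k` exceeds the number of frames (empty output).",
          class = "catraces_empty_output")
  }
  out <- matrix(0, nrow(x), n_out)
  for (j in seq_len(k)) {
    out <- out + x[, seq(j, by = k, length.out = n_out), drop = FALSE]
  }
  out <- out / k
  rownames(out) <- rownames(x)
  if (vec) drop(out) else out
}

#' Neuropil correction
#'
#' Removes peri-somatic neuropil contamination from ROI fluorescence with
#' the linear formula `F_corrected = F_raw - alpha * F_neuropil`. The
#' conventional coefficient for GCaMP somata is `alpha = 0.4`.
#'
#' @param raw,neuropil Matching numeric matrices (neurons x frames).
#' @param alpha Contamination coefficient in `[0, 1]`.
#' @return Corrected fluorescence matrix.
#' @export
correct_neuropil <- function(raw, neuropil, alpha = 0.4) {
  assert_matrix(raw, "raw"); assert_matrix(neuropil, "neuropil")
  assert_scalar(alpha, "alpha", lower = 0, upper = 1)
  if (!all(dim(raw) == dim(neuropil))) {
    abort("`raw` and `neuropil` must have identical dimensions.",
          class = "catraces_dimension_error")
  }
  raw - alpha * neuropil
}

#' Running-percentile baseline estimate
#'
#' Estimates slow baseline drift as the running 8th percentile of the trace
#' over a centred 30-s window, smoothed by a 30-s running mean. Windows are
#' truncated at the recording edges rather than padded.
#'
#' @param x Numeric matrix (neurons x frames) or vector.
#' @param frame_rate_hz Frame rate of `x`, Hz.
#' @param window_s Window length, seconds.
#' @param percentile Percentile (0-100).
#' @return Baseline of the same shape as `x`.
#' @export
estimate_baseline <- function(x, frame_rate_hz, window_s = 30, percentile = 8) {
  if (window_s <= 0) abort("`window_s` must be positive.",
                           class = "catraces_invalid_parameter")
  assert_scalar(frame_rate_hz, "frame_rate_hz", lower = 1e-9)
  assert_scalar(percentile, "percentile", lower = 0, upper = 100)
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  assert_matrix(x, "x")
  if (ncol(x) < 2) abort("Need at least 2 frames.",
                         class = "catraces_invalid_parameter")
  halfwidth <- max(1L, as.integer(floor(window_s * frame_rate_hz / 2)))
  out <- t(apply(x, 1, function(row) {
    rolling_mean_cpp(rolling_quantile_cpp(row, halfwidth, percentile / 100),
                     halfwidth)
  }))
  rownames(out) <- rownames(x)
  if (vec) drop(out) else out
}

#' Compute dF/F traces
#'
#' `dff = (corrected - baseline) / baseline`, the dimensionless fractional
#' fluorescence change after drift removal.
#'
#' @param corrected Neuropil-corrected fluorescence (neurons x frames).
#' @param baseline Baseline of the same shape, strictly positive.
#' @param frame_rate_hz Frame rate of the traces, Hz.
#' @param alpha Neuropil coefficient used upstream (metadata).
#' @return A `ca_dff` object: `dff` and `baseline` matrices plus metadata.
#' @export
compute_dff <- function(corrected, baseline, frame_rate_hz, alpha = 0.4) {
  vec <- is.null(dim(corrected))
  if (vec) { corrected <- matrix(corrected, 1); baseline <- matrix(baseline, 1) }
  assert_matrix(corrected, "corrected"); assert_matrix(baseline, "baseline")
  if (!all(dim(corrected) == dim(baseline))) {
    abort("`corrected` and `baseline` must match in shape.",
          class = "catraces_dimension_error")
  }
  bad <- which(apply(baseline <= 0, 1, any))
  if (length(bad)) {
    abort(paste0("Non-positive baseline for neuron(s): ",
                 paste(bad, collapse = ", ")),
          class = "catraces_division_guard")
  }
  structure(list(dff = (corrected - baseline) / baseline, baseline = baseline,
                 alpha = alpha, frame_rate_hz = frame_rate_hz),
            class = "ca_dff")
}

#' Z-score traces per neuron
#'
#' Centres and scales each neuron's trace to mean 0, sd 1. Zero-variance
#' neurons cannot be scaled; they are dropped with a warning.
#'
#' @param x A `ca_dff` object or a numeric matrix (neurons x frames).
#' @return Matrix of z-scored traces (possibly fewer rows than input).
#' @export
zscore_traces <- function(x) {
  m <- if (inherits(x, "ca_dff")) x$dff else x
  assert_matrix(m, "x")
  sds <- apply(m, 1, sd)
  flat <- sds == 0 | is.na(sds)
  if (any(flat)) {
    warn(paste0("Excluding zero-variance neuron(s): ",
                paste(which(flat), collapse = ", ")))
    m <- m[!flat, , drop = FALSE]
    sds <- sds[!flat]
  }
  (m - rowMeans(m)) / sds
}

#' Full preprocessing of a raw recording
#'
#' Chains the standard steps in acquisition order: group-average frames
#' (default pairs, 25 Hz -> 12.5 Hz effective), neuropil-correct, estimate
#' the running-percentile baseline, and form dF/F.
#'
#' @param rec A `ca_recording` (or a list with `roi_fluorescence`,
#'   `neuropil_fluorescence`, `frame_rate_hz`).
#' @param k Frame-group size.
#' @param alpha Neuropil coefficient.
#' @param window_s,percentile Baseline parameters, see [estimate_baseline()].
#' @return A `ca_dff` object at the effective (post-averaging) frame rate.
#' @export
preprocess_traces <- function(rec, k = 2, alpha = 0.4,
                              window_s = 30, percentile = 8) {
  raw <- group_average_frames(rec$roi_fluorescence, k)
  np <- group_average_frames(rec$neuropil_fluorescence, k)
  fs_eff <- rec$frame_rate_hz / k
  corrected <- correct_neuropil(raw, np, alpha)
  baseline <- estimate_baseline(corrected, fs_eff, window_s, percentile)
  compute_dff(corrected, baseline, fs_eff, alpha)
}
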