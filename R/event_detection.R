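#' Robust per-neuron noise estimate
#'
#' Estimates the baseline noise sd of each dF/F trace from sub-median
#' fluctuations only: deviations below the per-neuron median are mirrored,
#' so sparse positive calcium transients do not inflate the estimate. For a
#' transient-free Gaussian trace this equals the true sd.
#'
#' @param dff A `ca_dff` object or numeric matrix (neurons x frames).
#' @param ci_level One-sided confidence level used downstream for the
#'   significance bound (default 0.98).
#' @return A `ca_noise` object with per-neuron `sd`.
#' @export
estimate_noise <- function(dff, ci_level = 0.98) {
  m <- if (inherits(dff, "ca_dff")) dff$dff else dff
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  assert_matrix(m, "dff")
  assert_scalar(ci_level, "ci_level", lower = 1e-9, upper = 1 - 1e-9)
  sds <- apply(m, 1, function(row) {
    d <- row - median(row)
    neg <- d[d < 0]
    if (length(neg) == 0) return(0)
    sqrt(mean(neg^2))
  })
  if (any(sds == 0)) {
    abort(paste0("Zero noise estimate (constant trace?) for neuron(s): ",
                 paste(which(sds == 0), collapse = ", ")),
          class = "catraces_zero_noise")
  }
  structure(list(sd = sds, ci_level = ci_level,
                 estimation_method = "reflected_sub_median"),
            class = "ca_noise")
}

# Two complementary decay-constant estimates over the post-onset segment of
# a candidate event (instantaneous-rise kernel: the onset frame is the
# expected peak). The initial-slope estimate is a log-linear fit over the
# contiguous supra-noise samples, insensitive to later burst contamination;
# the mass estimate is the integral-to-amplitude ratio (an exponential of
# amplitude A integrates to ~A tau fs samples), insensitive to per-sample
# noise. Returns c(slope, mass); NA where an estimate is unavailable.
fit_decay_tau <- function(x, start_idx, sd_i, fs, tau_s) {
  n <- length(x)
  horizon <- min(n, start_idx + ceiling(3 * tau_s * fs))
  seg <- x[start_idx:horizon]
  if (length(seg) < 4) return(c(NA_real_, NA_real_))

  tau_slope <- NA_real_
  usable <- which(seg > sd_i)
  if (length(usable) > 0 && usable[1] == 1) {
    gap <- which(diff(usable) > 1)
    last <- if (length(gap)) usable[gap[1]] else usable[length(usable)]
    if (last >= 4) {
      tt <- seq_len(last)
      fit <- stats::lm.fit(cbind(1, tt), log(seg[seq_len(last)]))
      slope <- fit$coefficients[2]
      if (is.finite(slope) && slope < 0) tau_slope <- -1 / (slope * fs)
    }
  }

  tau_mass <- NA_real_
  amp <- (seg[1] + seg[2] * exp(1 / (tau_s * fs))) / 2
  if (is.finite(amp) && amp > 0) {
    mass <- sum(seg) / (1 - exp(-length(seg) / (tau_s * fs)))
    tau_mass <- (mass / amp - 0.5) / fs
  }
  c(tau_slope, tau_mass)
}

#' Detect significant calcium transients
#'
#' The threshold is dynamic: each trace is first centred on its running
#' median (window `local_window_s`), which removes residual slow baseline
#' error while leaving sparse transients intact. A frame then belongs to a
#' significant transient iff (a) the centred dF/F exceeds the one-sided
#' `ci_level` bound of the neuron's baseline noise (`qnorm(ci_level) * sd`),
#' and (b) the ensuing decay of the supra-threshold excursion is consistent
#' with a single-exponential GCaMP kernel: a decay constant estimated from
#' the event onset must lie within `[tau_s / 2, 2 * tau_s]`. Contiguous
#' supra-threshold runs form one event whose onset is the first frame.
#'
#' @param dff A `ca_dff` object or numeric matrix.
#' @param noise A `ca_noise` model from [estimate_noise()].
#' @param tau_s Expected indicator decay constant, seconds (1.8 for GCaMP6S).
#' @param frame_rate_hz Frame rate; taken from `dff` when it is a `ca_dff`.
#' @param tau_band Multiplicative acceptance band around `tau_s`.
#' @param merge_gap_frames Supra-threshold runs separated by at most this
#'   many frames are treated as one event (noise can momentarily dip a
#'   decaying transient below threshold); default a quarter of the decay
#'   constant.
#' @param local_window_s Running-median window for the dynamic threshold,
#'   seconds; must be much longer than a transient. `0` disables centring.
#' @return A `ca_raster`: logical `active` matrix, per-neuron `onsets`,
#'   `rate_per_min`, and a tidy `events` tibble.
#' @export
detect_transients <- function(dff, noise, tau_s = 1.8, frame_rate_hz = NULL,
                              tau_band = c(0.5, 2), merge_gap_frames = NULL,
                              local_window_s = 30) {
  m <- if (inherits(dff, "ca_dff")) dff$dff else dff
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  assert_matrix(m, "dff")
  stopifnot(inherits(noise, "ca_noise"), length(noise$sd) == nrow(m))
  if (tau_s <= 0) abort("`tau_s` must be positive.",
                        class = "catraces_invalid_parameter")
  fs <- frame_rate_hz %||% (if (inherits(dff, "ca_dff")) dff$frame_rate_hz else
    abort("`frame_rate_hz` required when `dff` is a bare matrix."))
  zcrit <- qnorm(noise$ci_level)
  if (is.null(merge_gap_frames)) merge_gap_frames <- ceiling(0.25 * tau_s * fs)
  n <- nrow(m); n_frames <- ncol(m)
  active <- matrix(FALSE, n, n_frames)
  events <- vector("list", n)
  k_med <- if (local_window_s > 0) {
    k <- min(round(local_window_s * fs), n_frames - 1)
    if (k %% 2 == 0) k + 1 else k
  } else 0
  for (i in seq_len(n)) {
    x_i <- m[i, ]
    if (k_med >= 3) x_i <- x_i - stats::runmed(x_i, k_med)
    thr <- zcrit * noise$sd[i]
    above <- x_i > thr
    if (!any(above)) { events[[i]] <- NULL; next }
    runs <- true_runs(above)
    if (nrow(runs) > 1 && merge_gap_frames > 0) {
      gaps <- runs[-1, 1] - runs[-nrow(runs), 2] - 1L
      grp <- cumsum(c(1L, as.integer(gaps > merge_gap_frames)))
      runs <- cbind(start = as.integer(tapply(runs[, 1], grp, min)),
                    end = as.integer(tapply(runs[, 2], grp, max)))
    }
    keep <- logical(nrow(runs))
    taus <- numeric(nrow(runs))
    for (r in seq_len(nrow(runs))) {
      tau_hat <- fit_decay_tau(x_i, runs[r, 1], noise$sd[i], fs, tau_s)
      in_band <- is.finite(tau_hat) &
        tau_hat >= tau_band[1] * tau_s & tau_hat <= tau_band[2] * tau_s
      # an event is tau-consistent if either estimator agrees
      keep[r] <- any(in_band)
      taus[r] <- if (any(in_band)) tau_hat[in_band][1] else
        if (any(is.finite(tau_hat))) tau_hat[is.finite(tau_hat)][1] else NA_real_
    }
    if (any(keep)) {
      kept <- runs[keep, , drop = FALSE]
      for (r in seq_len(nrow(kept))) active[i, kept[r, 1]:kept[r, 2]] <- TRUE
      events[[i]] <- tibble(neuron = i,
                            onset = as.integer(unname(kept[, 1])),
                            duration = as.integer(unname(kept[, 2] - kept[, 1] + 1L)),
                            tau_hat_s = unname(taus[keep]))
    }
  }
  events_tbl <- if (length(ev <- Filter(Negate(is.null), events))) {
    bind_rows(ev)
  } else {
    tibble(neuron = integer(), onset = integer(), duration = integer(),
           tau_hat_s = numeric())
  }
  onsets <- lapply(seq_len(n), function(i) events_tbl$onset[events_tbl$neuron == i])
  duration_min <- n_frames / fs / 60
  rate_per_min <- vapply(onsets, length, 1L) / duration_min
  structure(list(active = active, onsets = onsets, rate_per_min = rate_per_min,
                 events = events_tbl, frame_rate_hz = fs, n_frames = n_frames),
            class = "ca_raster")
}

#' Onset raster of a detection result
#'
#' Logical neurons x frames matrix marking only the onset frame of each
#' detected transient (the point-event train used for synchrony
#' surrogates).
#'
#' @param raster A `ca_raster`.
#' @return Logical matrix.
#' @export
onset_raster <- function(raster) {
  stopifnot(inherits(raster, "ca_raster"))
  on <- matrix(FALSE, nrow(raster$active), raster$n_frames)
  if (nrow(raster$events) > 0) {
    on[cbind(raster$events$neuron, raster$events$onset)] <- TRUE
  }
  on
}

#' Segment a speed trace into movement and rest
#'
#' Frames with speed above `threshold_mms` (default 30 mm/s) are movement;
#' state runs shorter than `min_bout_frames` (default 6 frames, i.e. 240 ms
#' at a 25-Hz tracking rate) are treated as spurious artifacts and absorbed
#' into the surrounding state.
#'
#' @param speed Numeric speed trace, mm/s, or a `ca_speed` object.
#' @param threshold_mms Movement threshold, mm/s.
#' @param min_bout_frames Minimum state-run length, frames.
#' @param frame_rate_hz Tracking rate (metadata).
#' @return A `ca_movement`: logical `moving` mask, `fraction_moving`, and
#'   the parameters used.
#' @export
segment_movement <- function(speed, threshold_mms = 30, min_bout_frames = 6,
                             frame_rate_hz = 25) {
  if (inherits(speed, "ca_speed")) {
    frame_rate_hz <- speed$frame_rate_hz
    speed <- speed$speed
  }
  if (any(speed < 0)) abort("Speeds must be non-negative.",
                            class = "catraces_invalid_config")
  moving <- debounce_mask(speed > threshold_mms, min_bout_frames)
  structure(list(moving = moving, threshold_mms = threshold_mms,
                 min_bout_frames = min_bout_frames,
                 frame_rate_hz = frame_rate_hz,
                 fraction_moving = mean(moving)),
            class = "ca_movement")
}

#' Resample a movement segmentation to the effective imaging rate
#'
#' Downsamples the tracking-rate mask by blocks of `k` frames (majority
#' vote, ties counted as movement) so it aligns with group-averaged traces.
#'
#' @param seg A `ca_movement`.
#' @param k Block size (the frame-group size used on the traces).
#' @return A `ca_movement` at the reduced rate.
#' @export
resample_movement <- function(seg, k = 2) {
  stopifnot(inherits(seg, "ca_movement"))
  frac <- block_average(as.numeric(seg$moving), k)
  structure(list(moving = frac >= 0.5, threshold_mms = seg$threshold_mms,
                 min_bout_frames = seg$min_bout_frames,
                 frame_rate_hz = seg$frame_rate_hz / k,
                 fraction_moving = mean(frac >= 0.5)),
            class = "ca_movement")
}

#' Movement-conditioned transient rates
#'
#' Counts each neuron's event onsets separately in movement and rest frames
#' and divides by the time spent in each state, in minutes.
#'
#' @param raster A `ca_raster` from [detect_transients()].
#' @param seg A `ca_movement` aligned frame-by-frame with the raster.
#' @return A tibble (one row per neuron: `rate_moving`, `rate_resting`,
#'   `rate_overall`, events/min) with population means and
#'   `fraction_moving` as attributes (see [glance.ca_rates()]).
#' @export
firing_rates <- function(raster, seg) {
  stopifnot(inherits(raster, "ca_raster"), inherits(seg, "ca_movement"))
  if (length(seg$moving) != raster$n_frames) {
    abort("Raster and movement segmentation differ in frame count.",
          class = "catraces_dimension_error")
  }
  fs <- raster$frame_rate_hz
  min_moving <- sum(seg$moving) / fs / 60
  min_resting <- sum(!seg$moving) / fs / 60
  min_total <- raster$n_frames / fs / 60
  per_neuron <- map(raster$onsets, function(on) {
    n_mov <- sum(seg$moving[on])
    n_rest <- length(on) - n_mov
    tibble(
      n_moving = n_mov, n_resting = n_rest,
      rate_moving = if (min_moving > 0) n_mov / min_moving else NA_real_,
      rate_resting = if (min_resting > 0) n_rest / min_resting else NA_real_,
      rate_overall = length(on) / min_total)
  })
  out <- bind_rows(per_neuron)
  out <- mutate(out, neuron = dplyr::row_number(), .before = 1)
  if (min_moving == 0 || min_resting == 0) {
    warn("One movement state has zero duration; its rates are NA.")
  }
  structure(out, class = c("ca_rates", class(out)),
            fraction_moving = mean(seg$moving),
            minutes_moving = min_moving, minutes_resting = min_resting)
}

#' Per-neuron correlation between event rate and speed
#'
#' Bins event onsets and mean speed into `bin_s`-second bins and reports the
#' Pearson correlation per neuron.
#'
#' @param raster A `ca_raster`.
#' @param speed Speed trace aligned with the raster frames.
#' @param bin_s Bin width, seconds (must cover >= 2 frames).
#' @return Tibble `(neuron, r)`; `r` is `NA` (with a warning) when either
#'   binned series is constant.
#' @export
rate_speed_correlation <- function(raster, speed, bin_s = 10) {
  stopifnot(inherits(raster, "ca_raster"))
  fs <- raster$frame_rate_hz
  bin_frames <- round(bin_s * fs)
  if (bin_frames < 2) abort("`bin_s` must span at least 2 frames.",
                            class = "catraces_invalid_parameter")
  if (length(speed) != raster$n_frames) {
    abort("Speed and raster differ in frame count.",
          class = "catraces_dimension_error")
  }
  n_bins <- floor(raster$n_frames / bin_frames)
  bin_of <- rep(seq_len(n_bins), each = bin_frames)
  idx <- seq_len(n_bins * bin_frames)
  speed_b <- tapply(speed[idx], bin_of, mean)
  rs <- map_dbl(raster$onsets, function(on) {
    counts <- tabulate(((on[on <= length(idx)] - 1L) %/% bin_frames) + 1L,
                       nbins = n_bins)
    if (sd(counts) == 0 || sd(speed_b) == 0) return(NA_real_)
    cor(counts, as.numeric(speed_b))
  })
  if (any(is.na(rs))) warn("Constant binned series: correlation undefined for some neurons.")
  tibble(neuron = seq_along(rs), r = rs)
}
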