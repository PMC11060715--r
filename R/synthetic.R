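#' Ground-truth configuration for a synthetic population recording
#'
#' Bundles every parameter of the synthetic two-photon recording generator.
#' The defaults describe a 15-min-style awake cortical session scaled to
#' 600 s: a population of 100 neurons imaged at 25 Hz containing five
#' planted assemblies of 10 neurons each, sparse Poisson background firing,
#' GCaMP6S-like single-exponential transients (tau = 1.8 s), additive white
#' noise, slow sinusoidal baseline drift, and linear neuropil contamination
#' with coefficient 0.4.
#'
#' @param n_neurons Number of ROIs.
#' @param frame_rate_hz Acquisition frame rate in Hz (before any pair
#'   averaging downstream).
#' @param duration_s Recording length in seconds.
#' @param assembly_memberships List of integer vectors of neuron indices
#'   (1-based); overlap between assemblies is allowed.
#' @param assembly_event_rate_hz Rate of co-activation events per assembly, Hz.
#' @param background_rate_hz Per-neuron background spike rate, Hz.
#' @param movement_rate_gain Multiplier applied to all rates during planted
#'   movement bouts (1 = no movement modulation).
#' @param tau_s GCaMP decay time constant, seconds.
#' @param transient_amplitude Peak dF/F of a single transient.
#' @param noise_sd Additive Gaussian noise sd, dF/F units.
#' @param drift_amplitude Amplitude of the slow baseline drift, dF/F units.
#' @param drift_period_s Period of the sinusoidal drift, seconds.
#' @param neuropil_coefficient_true Linear contamination coefficient mixing
#'   neuropil fluorescence into the ROI signal.
#' @param seed Integer seed; identical seeds give bit-identical recordings.
#'
#' @return A `ca_ground_truth` list.
#' @export
ground_truth <- function(n_neurons = 100,
                         frame_rate_hz = 25,
                         duration_s = 600,
                         assembly_memberships = default_assemblies(n_neurons),
                         assembly_event_rate_hz = 0.05,
                         background_rate_hz = 0.05,
                         movement_rate_gain = 1,
                         tau_s = 1.8,
                         transient_amplitude = 1.0,
                         noise_sd = 0.05,
                         drift_amplitude = 0.05,
                         drift_period_s = 120,
                         neuropil_coefficient_true = 0.4,
                         seed = 1L) {
  assert_scalar(n_neurons, "n_neurons", lower = 1)
  if (duration_s <= 0 || frame_rate_hz <= 0) {
    abort("`duration_s` and `frame_rate_hz` must be positive.",
          class = "catraces_invalid_config")
  }
  if (tau_s <= 0) abort("`tau_s` must be positive.", class = "catraces_invalid_config")
  for (r in c(assembly_event_rate_hz, background_rate_hz, noise_sd,
              drift_amplitude)) {
    if (r < 0) abort("Rates and amplitudes must be non-negative.",
                     class = "catraces_invalid_config")
  }
  assembly_memberships <- lapply(assembly_memberships, as.integer)
  if (length(assembly_memberships) &&
      max(unlist(assembly_memberships), 0L) > n_neurons) {
    abort("Assembly member indices must be <= n_neurons.",
          class = "catraces_invalid_config")
  }
  structure(
    list(n_neurons = as.integer(n_neurons), frame_rate_hz = frame_rate_hz,
         duration_s = duration_s, assembly_memberships = assembly_memberships,
         assembly_event_rate_hz = assembly_event_rate_hz,
         background_rate_hz = background_rate_hz,
         movement_rate_gain = movement_rate_gain, tau_s = tau_s,
         transient_amplitude = transient_amplitude, noise_sd = noise_sd,
         drift_amplitude = drift_amplitude, drift_period_s = drift_period_s,
         neuropil_coefficient_true = neuropil_coefficient_true,
         seed = as.integer(seed)),
    class = "ca_ground_truth")
}

#' Default planted assembly memberships
#'
#' Five disjoint blocks of ten neurons (or as many complete blocks as the
#' population allows for small populations).
#'
#' @param n_neurons Population size.
#' @param n_assemblies Number of assemblies.
#' @param size Members per assembly.
#' @return List of integer vectors.
#' @export
default_assemblies <- function(n_neurons, n_assemblies = 5, size = 10) {
  n_fit <- min(n_assemblies, n_neurons %/% size)
  lapply(seq_len(n_fit), function(a) ((a - 1L) * size + 1L):(a * size))
}

#' Simulate a population recording with known ground truth
#'
#' Generates spikes (background Poisson plus assembly co-activation events
#' that recruit at least 90% of each assembly's members in a single frame),
#' convolves them with a single-exponential GCaMP kernel, and assembles raw
#' ROI and neuropil fluorescence:
#' `F_roi = B (1 + A (spikes * exp(-t/tau))) + drift + noise + alpha_true F_neuropil`.
#' The contamination enters linearly so that the standard correction
#' `F_roi - alpha F_neuropil` with `alpha = alpha_true` recovers the clean
#' trace exactly.
#'
#' @param gt A [ground_truth()] configuration.
#' @param bouts Optional movement-bout schedule (two-column `start`,`end`
#'   frame table at the acquisition rate). Defaults to a regular
#'   10-s-on / 20-s-off pattern starting at 15 s.
#' @return A `ca_recording`: raw ROI and neuropil matrices (neurons x
#'   frames), ROI centroids (um), a 25-Hz speed trace, the true spike
#'   raster, and the `ground_truth` used.
#' @export
simulate_population <- function(gt, bouts = NULL) {
  stopifnot(inherits(gt, "ca_ground_truth"))
  fs <- gt$frame_rate_hz
  n <- gt$n_neurons
  n_frames <- round(gt$duration_s * fs)
  if (n_frames < 2) abort("Recording too short.", class = "catraces_invalid_config")
  set.seed(gt$seed)

  if (is.null(bouts)) bouts <- default_bout_schedule(n_frames, fs)
  sp <- simulate_speed(gt$duration_s, fs, bouts = bouts,
                       seed = stage_seed(gt$seed, 1L))
  gain <- ifelse(sp$moving_truth, gt$movement_rate_gain, 1)

  dt <- 1 / fs
  # background spikes: per-frame Bernoulli at rate * dt (* gain when moving)
  p_bg <- pmin(gt$background_rate_hz * dt * gain, 1)
  raster <- matrix(runif(n * n_frames) < rep(p_bg, each = n), n, n_frames)

  # assembly events: at each event frame recruit >= 90% of members
  for (members in gt$assembly_memberships) {
    m <- length(members)
    p_ev <- pmin(gt$assembly_event_rate_hz * dt * gain, 1)
    ev_frames <- which(runif(n_frames) < p_ev)
    max_drop <- floor(0.1 * m)
    for (f in ev_frames) {
      drop_k <- if (max_drop > 0) sample.int(max_drop + 1L, 1L) - 1L else 0L
      act <- if (drop_k > 0) members[-sample.int(m, drop_k)] else members
      raster[act, f] <- TRUE
    }
  }

  # fluorescence: recursive filter realises spikes convolved with exp(-t/tau)
  decay <- exp(-1 / (gt$tau_s * fs))
  conv <- t(apply(raster, 1, function(s)
    as.numeric(stats::filter(as.numeric(s), decay, method = "recursive"))))

  baseline <- runif(n, 80, 120)
  t_s <- (seq_len(n_frames) - 1) / fs
  phase <- runif(n, 0, 2 * pi)
  drift <- (baseline * gt$drift_amplitude) *
    sin(outer(phase, rep(1, n_frames)) + outer(rep(2 * pi / gt$drift_period_s, n), t_s) * 1)
  noise <- matrix(rnorm(n * n_frames, sd = 1), n, n_frames) * (baseline * gt$noise_sd)

  np_base <- runif(n, 60, 90)
  np_phase <- outer(runif(n, 0, 2 * pi), rep(1, n_frames))
  np_drift <- (np_base * gt$drift_amplitude) *
    sin(np_phase + outer(rep(2 * pi / gt$drift_period_s, n), t_s))
  np_noise <- matrix(rnorm(n * n_frames), n, n_frames) * (np_base * gt$noise_sd)
  neuropil <- np_base + np_drift + np_noise

  clean <- baseline * (1 + gt$transient_amplitude * conv)
  roi <- clean + drift + noise + gt$neuropil_coefficient_true * neuropil
  roi <- pmax(roi, 1e-6)
  neuropil <- pmax(neuropil, 1e-6)

  centroids <- tibble(id = seq_len(n),
                      x_um = runif(n, 0, 434), y_um = runif(n, 0, 434))

  structure(
    list(roi_fluorescence = roi, neuropil_fluorescence = neuropil,
         roi_centroids = centroids, speed = sp$speed,
         speed_frame_rate_hz = fs, moving_truth = sp$moving_truth,
         bouts = sp$bouts, true_spike_raster = raster,
         clean_fluorescence = clean, frame_rate_hz = fs, ground_truth = gt),
    class = "ca_recording")
}

#' Regular movement-bout schedule
#'
#' 10-s movement bouts every 30 s beginning at 15 s, mirroring the
#' alternation of rest and locomotion typical of head-fixed mice in a
#' floating homecage.
#'
#' @param n_frames Frames in the recording.
#' @param frame_rate_hz Tracking/imaging rate, Hz.
#' @param bout_s,cycle_s,start_s Bout length, cycle length and first onset
#'   in seconds.
#' @return Tibble with `start` and `end` frame columns.
#' @export
default_bout_schedule <- function(n_frames, frame_rate_hz,
                                  bout_s = 10, cycle_s = 30, start_s = 15) {
  starts <- seq(round(start_s * frame_rate_hz) + 1, n_frames,
                by = round(cycle_s * frame_rate_hz))
  ends <- pmin(starts + round(bout_s * frame_rate_hz) - 1, n_frames)
  keep <- starts <= n_frames & ends >= starts
  tibble(start = as.integer(starts[keep]), end = as.integer(ends[keep]))
}

#' Simulate an animal speed trace
#'
#' Piecewise-constant speed (resting level with movement bouts at a higher
#' level) plus optional Gaussian jitter, clipped at zero. Bout boundaries
#' are returned as ground truth.
#'
#' @param duration_s Length in seconds.
#' @param frame_rate_hz Tracking rate, Hz (25 Hz matches frame-synchronous
#'   homecage tracking).
#' @param bouts Two-column table (`start`, `end`, frames, inclusive) of
#'   movement bouts; `NULL` means no movement.
#' @param moving_speed_mms,resting_speed_mms Speed levels, mm/s.
#' @param jitter_sd_mms Gaussian jitter sd, mm/s.
#' @param seed Integer seed.
#' @return A `ca_speed` list: `speed`, logical `moving_truth`, `bouts`,
#'   `frame_rate_hz`.
#' @export
simulate_speed <- function(duration_s, frame_rate_hz = 25, bouts = NULL,
                           moving_speed_mms = 60, resting_speed_mms = 5,
                           jitter_sd_mms = 1, seed = 1L) {
  if (moving_speed_mms < 0 || resting_speed_mms < 0) {
    abort("Speeds must be non-negative.", class = "catraces_invalid_config")
  }
  n_frames <- round(duration_s * frame_rate_hz)
  moving <- rep(FALSE, n_frames)
  if (!is.null(bouts) && nrow(bouts) > 0) {
    b <- as.data.frame(bouts)[order(bouts$start), , drop = FALSE]
    if (any(b$end < b$start) || any(b$start < 1) || any(b$end > n_frames)) {
      abort("Bout indices out of range.", class = "catraces_invalid_config")
    }
    if (nrow(b) > 1 && any(b$start[-1] <= b$end[-nrow(b)])) {
      abort("Movement bouts overlap.", class = "catraces_invalid_config")
    }
    for (i in seq_len(nrow(b))) moving[b$start[i]:b$end[i]] <- TRUE
  }
  set.seed(seed)
  speed <- ifelse(moving, moving_speed_mms, resting_speed_mms)
  if (jitter_sd_mms > 0) speed <- speed + rnorm(n_frames, sd = jitter_sd_mms)
  structure(list(speed = pmax(speed, 0), moving_truth = moving,
                 bouts = if (is.null(bouts)) tibble(start = integer(), end = integer())
                         else as_tibble(bouts),
                 frame_rate_hz = frame_rate_hz),
            class = "ca_speed")
}

#' Simulate a widefield sensory-stimulation trial stack
#'
#' Trials of baseline frames followed by a stimulus-evoked 2-D Gaussian
#' response: post-stimulus frames carry a multiplicative bump of fractional
#' amplitude `true_amplitude` centred at `true_center`, emulating a limb
#' representation in mesoscale calcium imaging (10 Hz, 1 s pre / 4 s post).
#'
#' @param n_trials Number of stimulation trials.
#' @param n_frames Frames per trial.
#' @param height,width Image size in pixels.
#' @param stim_onset_frame First post-stimulus frame (1-based).
#' @param pre_frames,post_frames Baseline and response windows, frames.
#' @param true_center `(x, y)` bump centre in 0-based pixel coordinates.
#' @param true_amplitude Peak fractional response (dF/F).
#' @param true_sigma Gaussian width, pixels.
#' @param baseline_level Baseline fluorescence, a.u.
#' @param baseline_noise_sd Additive noise sd, a.u.
#' @param pixel_scale_mm Millimetres per pixel.
#' @param seed Integer seed.
#' @return A `ca_widefield` list with a `trials x frames x H x W` array and
#'   the planted truth.
#' @export
simulate_widefield <- function(n_trials = 20, n_frames = 50,
                               height = 64, width = 64,
                               stim_onset_frame = 11,
                               pre_frames = 10, post_frames = 10,
                               true_center = c((width - 1) / 2, (height - 1) / 2),
                               true_amplitude = 0.05, true_sigma = 10,
                               baseline_level = 100, baseline_noise_sd = 0.5,
                               pixel_scale_mm = 0.01, seed = 1L) {
  if (height <= 0 || width <= 0) abort("Image size must be positive.",
                                       class = "catraces_invalid_config")
  if (true_sigma <= 0) abort("`true_sigma` must be positive.",
                             class = "catraces_invalid_config")
  if (true_amplitude < 0) abort("`true_amplitude` must be non-negative.",
                                class = "catraces_invalid_config")
  if (pre_frames + post_frames > n_frames) {
    abort("pre_frames + post_frames exceeds frames per trial.",
          class = "catraces_invalid_config")
  }
  set.seed(seed)
  xs <- outer(rep(1, height), 0:(width - 1))   # x = column, 0-based
  ys <- outer(0:(height - 1), rep(1, width))   # y = row, 0-based
  bump <- true_amplitude *
    exp(-((xs - true_center[1])^2 + (ys - true_center[2])^2) / (2 * true_sigma^2))
  stack <- array(0, dim = c(n_trials, n_frames, height, width))
  post_idx <- stim_onset_frame:min(n_frames, stim_onset_frame + post_frames - 1)
  for (tr in seq_len(n_trials)) {
    for (f in seq_len(n_frames)) {
      frame <- baseline_level * (1 + if (f %in% post_idx) bump else 0)
      if (baseline_noise_sd > 0) {
        frame <- frame + matrix(rnorm(height * width, sd = baseline_noise_sd),
                                height, width)
      }
      stack[tr, f, , ] <- frame
    }
  }
  structure(list(stack = stack, stim_onset_frame = stim_onset_frame,
                 pre_frames = pre_frames, post_frames = post_frames,
                 pixel_scale_mm = pixel_scale_mm, true_center = true_center,
                 true_amplitude = true_amplitude, true_sigma = true_sigma,
                 baseline_level = baseline_level,
                 baseline_noise_sd = baseline_noise_sd),
            class = "ca_widefield")
}

#' Simulate string-pull paw trajectories
#'
#' Builds left/right paw paths made of straight vertical reach segments
#' with exactly planted path length and peak speed (when `jitter_sd = 0`),
#' separated by stationary gaps. Peak speeds are proportional to segment
#' lengths by default, planting a movement-scaling correlation of 1; the
#' right paw mirrors the left's vertical motion plus an optional linear
#' postural ramp, planting a bimanual correlation of 1 after detrending.
#'
#' @param segment_lengths_px Planted per-reach path lengths, pixels.
#' @param peak_speeds_px Planted per-reach peak speeds, pixels/frame; must
#'   not exceed the segment length.
#' @param gap_frames Stationary frames between reaches.
#' @param ramp_per_frame Linear ramp added to the right paw's y trace.
#' @param jitter_sd Gaussian positional jitter, pixels.
#' @param seed Integer seed.
#' @return A `ca_paws` list: `left`, `right` tibbles (`frame`,`x`,`y`) and a
#'   `segments` tibble with the planted ground truth per paw.
#' @export
simulate_paws <- function(segment_lengths_px = seq(20, 65, length.out = 10),
                          peak_speeds_px = segment_lengths_px / 10,
                          gap_frames = 5, ramp_per_frame = 0,
                          jitter_sd = 0, seed = 1L) {
  if (length(segment_lengths_px) < 1) {
    abort("At least one reach segment is required.",
          class = "catraces_invalid_config")
  }
  if (length(peak_speeds_px) != length(segment_lengths_px)) {
    abort("Lengths and peak speeds must align.", class = "catraces_invalid_config")
  }
  if (any(peak_speeds_px > segment_lengths_px)) {
    abort("Peak speed cannot exceed segment length (single-frame step cap).",
          class = "catraces_invalid_config")
  }
  set.seed(seed)
  y <- 0
  ys <- numeric(0)
  segs <- list()
  for (i in seq_along(segment_lengths_px)) {
    ys <- c(ys, rep(y, gap_frames))
    L <- segment_lengths_px[i]; v <- peak_speeds_px[i]
    rest <- L - v
    n_rest <- if (rest > 0) ceiling(rest / v) else 0
    steps <- if (n_rest > 0) {
      small <- rep(rest / n_rest, n_rest)
      c(small[seq_len(n_rest %/% 2)], v, small[-seq_len(n_rest %/% 2)])
    } else v
    start <- length(ys) + 1L
    ys <- c(ys, y + cumsum(steps))
    y <- y + L
    segs[[i]] <- tibble(segment = i, start = start,
                        end = length(ys),
                        length_px = L, peak_speed_px = v)
  }
  ys <- c(ys, rep(y, gap_frames))
  n <- length(ys)
  jit <- function() if (jitter_sd > 0) rnorm(n, sd = jitter_sd) else 0
  left <- tibble(frame = seq_len(n), x = 100 + jit(), y = ys + jit())
  right <- tibble(frame = seq_len(n), x = 200 + jit(),
                  y = ys + ramp_per_frame * (seq_len(n) - 1) + jit())
  seg_tbl <- bind_rows(
    mutate(bind_rows(segs), paw = "left"),
    mutate(bind_rows(segs), paw = "right"))
  structure(list(left = left, right = right, segments = seg_tbl),
            class = "ca_paws")
}
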