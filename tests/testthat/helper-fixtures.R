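# Shared fixture builders; everything is generated in code at test time.

# Best-match Jaccard of each true membership against the detected ones.
best_match_jaccard <- function(true_sets, detected_sets) {
  vapply(true_sets, function(tr) {
    if (length(detected_sets) == 0) return(0)
    max(vapply(detected_sets, function(dt)
      length(intersect(tr, dt)) / length(union(tr, dt)), numeric(1)))
  }, numeric(1))
}

# Minimal ca_raster built from a logical spike matrix (each TRUE frame is
# an event onset lasting one frame); used to test rate arithmetic without
# running the detector.
raster_from_spikes <- function(spikes, frame_rate_hz) {
  onsets <- lapply(seq_len(nrow(spikes)), function(i) which(spikes[i, ]))
  events <- dplyr::bind_rows(lapply(seq_len(nrow(spikes)), function(i) {
    on <- which(spikes[i, ])
    if (length(on) == 0) return(NULL)
    tibble::tibble(neuron = i, onset = on, duration = 1L,
                   tau_hat_s = NA_real_)
  }))
  if (is.null(events) || nrow(events) == 0) {
    events <- tibble::tibble(neuron = integer(), onset = integer(),
                             duration = integer(), tau_hat_s = numeric())
  }
  duration_min <- ncol(spikes) / frame_rate_hz / 60
  structure(list(active = spikes, onsets = onsets,
                 rate_per_min = lengths(onsets) / duration_min,
                 events = events, frame_rate_hz = frame_rate_hz,
                 n_frames = ncol(spikes)),
            class = "ca_raster")
}

# z-scored traces with planted co-activating groups: members share a
# common event train convolved with an exponential kernel plus private
# noise. Cheap deterministic stand-in for the full generator.
planted_z <- function(memberships, n_neurons, n_frames,
                      n_events = 30, tau_frames = 22, snr = 4, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n_neurons * n_frames), n_neurons, n_frames)
  for (mem in memberships) {
    ev <- sample.int(n_frames, n_events)
    train <- numeric(n_frames)
    train[ev] <- 1
    sig <- as.numeric(stats::filter(train, exp(-1 / tau_frames),
                                    method = "recursive"))
    x[mem, ] <- x[mem, ] + snr * matrix(sig, length(mem), n_frames,
                                        byrow = TRUE)
  }
  zscore_traces(x)
}

expect_no_warning_quietly <- function(expr) {
  expect_silent(suppressMessages(expr))
}
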