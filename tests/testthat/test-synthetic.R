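test_that("zero-rate, zero-noise configuration yields constant fluorescence and an empty raster", {
  gt <- ground_truth(n_neurons = 5, duration_s = 60,
                     assembly_memberships = list(),
                     assembly_event_rate_hz = 0, background_rate_hz = 0,
                     noise_sd = 0, drift_amplitude = 0, seed = 3)
  rec <- simulate_population(gt)
  expect_false(any(rec$true_spike_raster))
  per_neuron_sd <- apply(rec$roi_fluorescence, 1, sd)
  expect_equal(per_neuron_sd, rep(0, 5), tolerance = 1e-12)
})

test_that("background spike counts follow the Poisson mean rate x duration", {
  # 0.1 Hz for 600 s -> expected 60 events; mean over 100 seeds within 3 SE
  counts <- vapply(1:100, function(s) {
    gt <- ground_truth(n_neurons = 1, duration_s = 600,
                       assembly_memberships = list(),
                       background_rate_hz = 0.1, noise_sd = 0,
                       drift_amplitude = 0, seed = s)
    sum(simulate_population(gt)$true_spike_raster)
  }, numeric(1))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 60), 3 * se + 1e-9)
})

test_that("identical seeds reproduce bit-identical recordings", {
  gt <- ground_truth(n_neurons = 10, duration_s = 60, seed = 42,
                     assembly_memberships = default_assemblies(10, 2, 5))
  a <- simulate_population(gt)
  b <- simulate_population(gt)
  expect_identical(a$roi_fluorescence, b$roi_fluorescence)
  expect_identical(a$neuropil_fluorescence, b$neuropil_fluorescence)
  expect_identical(a$true_spike_raster, b$true_spike_raster)
  expect_identical(a$speed, b$speed)
})

test_that("invalid generator configurations are rejected", {
  expect_error(ground_truth(duration_s = 0), class = "catraces_invalid_config")
  expect_error(ground_truth(frame_rate_hz = -1), class = "catraces_invalid_config")
  expect_error(ground_truth(tau_s = 0), class = "catraces_invalid_config")
  expect_error(ground_truth(n_neurons = 5,
                            assembly_memberships = list(1:9)),
               class = "catraces_invalid_config")
})

test_that("planted assembly events recruit at least 90% of members in one frame", {
  # with zero background, any frame with an active member is an event frame
  gt <- ground_truth(n_neurons = 20, duration_s = 300,
                     assembly_memberships = list(1:10),
                     assembly_event_rate_hz = 0.1, background_rate_hz = 0,
                     noise_sd = 0, drift_amplitude = 0, seed = 8)
  rec <- simulate_population(gt)
  co <- colSums(rec$true_spike_raster[1:10, ])
  event_frames <- which(co > 0)
  expect_gt(length(event_frames), 5)
  expect_true(all(co[event_frames] >= ceiling(0.9 * 10)))
  expect_false(any(rec$true_spike_raster[11:20, ]))
})

test_that("noiseless fluorescence deconvolves back to the true spike raster", {
  gt <- ground_truth(n_neurons = 3, duration_s = 120,
                     assembly_memberships = list(),
                     background_rate_hz = 0.05, noise_sd = 0,
                     drift_amplitude = 0, neuropil_coefficient_true = 0,
                     seed = 5)
  rec <- simulate_population(gt)
  decay <- exp(-1 / (gt$tau_s * gt$frame_rate_hz))
  for (i in 1:3) {
    f <- rec$roi_fluorescence[i, ]
    # no spike in frame 1 for this seed, so f[1] is the baseline
    b <- f[1]
    conv <- (f / b - 1) / gt$transient_amplitude
    spikes_rec <- round(conv - decay * c(0, conv[-length(conv)]))
    expect_equal(spikes_rec > 0.5, rec$true_spike_raster[i, ])
  }
})

test_that("speed traces realize the planted bout schedule", {
  # no bouts, no jitter: flat at resting speed
  sp0 <- simulate_speed(10, 25, bouts = NULL, jitter_sd_mms = 0, seed = 1)
  expect_true(all(sp0$speed == 5))
  # one bout at frames 100-200: exactly those frames exceed 30 mm/s
  sp1 <- simulate_speed(20, 25, bouts = tibble::tibble(start = 100, end = 200),
                        moving_speed_mms = 60, resting_speed_mms = 5,
                        jitter_sd_mms = 0, seed = 1)
  expect_identical(which(sp1$speed > 30), 100:200)
  # 1 mm/s jitter on a 5 mm/s rest: crossing 30 mm/s needs a 25-sd excursion
  sp2 <- simulate_speed(600, 25, bouts = NULL, jitter_sd_mms = 1, seed = 2)
  expect_equal(mean(sp2$speed > 30), 0)
  # overlapping bouts rejected
  expect_error(simulate_speed(20, 25,
                              bouts = tibble::tibble(start = c(10, 50),
                                                     end = c(60, 90))),
               class = "catraces_invalid_config")
})

test_that("widefield phantoms place the planted Gaussian response", {
  # amplitude 0, noiseless: post equals pre exactly
  ph0 <- simulate_widefield(n_trials = 2, true_amplitude = 0,
                            baseline_noise_sd = 0, seed = 1)
  m0 <- trial_average_map(ph0)
  expect_equal(max(abs(m0$dff_map)), 0, tolerance = 1e-12)
  # noiseless amplitude A: averaged-post/averaged-pre map equals A at center
  ph <- simulate_widefield(n_trials = 3, true_amplitude = 0.08,
                           true_center = c(20, 30), baseline_noise_sd = 0,
                           seed = 1)
  m <- trial_average_map(ph)
  expect_equal(m$dff_map[31, 21], 0.08, tolerance = 1e-10)  # row = y + 1
  expect_error(simulate_widefield(true_sigma = 0),
               class = "catraces_invalid_config")
})

test_that("paw trajectories realize planted lengths, speeds, and geometry exactly", {
  paws <- simulate_paws(segment_lengths_px = c(10, 20, 30),
                        peak_speeds_px = c(1, 2, 3), jitter_sd = 0, seed = 1)
  segs <- dplyr::filter(paws$segments, paw == "left")
  for (k in seq_len(nrow(segs))) {
    idx <- segs$start[k]:segs$end[k]
    dy <- diff(paws$left$y[c(segs$start[k] - 1, idx)])
    expect_equal(sum(abs(dy)), segs$length_px[k], tolerance = 1e-10)
    expect_equal(max(abs(dy)), segs$peak_speed_px[k], tolerance = 1e-10)
  }
  # straight vertical reaches: circuity exactly 1
  kin <- pull_kinematics(paws)
  expect_true(all(abs(kin$per_event$circuity - 1) < 1e-10))
  # exact proportionality: planted scaling correlation 1
  expect_equal(kin$per_paw$movement_scaling_r, c(1, 1), tolerance = 1e-12)
  # identical left/right y traces: planted bimanual correlation 1
  expect_equal(kin$per_paw$bimanual_r[1], 1, tolerance = 1e-12)
  expect_error(simulate_paws(segment_lengths_px = numeric(0)),
               class = "catraces_invalid_config")
})
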