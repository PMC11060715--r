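test_that("noise estimation is accurate, transient-robust, and scale-equivariant", {
  set.seed(3)
  x <- matrix(rnorm(10000, sd = 0.05), 1)
  nm <- estimate_noise(x)
  expect_lt(abs(nm$sd - 0.05) / 0.05, 0.10)
  # sparse large positive transients leave the estimate within 10%
  y <- x
  idx <- sample.int(10000, 200)
  y[idx] <- y[idx] + 1.0
  expect_lt(abs(estimate_noise(y)$sd - nm$sd) / nm$sd, 0.10)
  # scaling the trace scales the estimate
  expect_equal(estimate_noise(2 * x)$sd, 2 * nm$sd, tolerance = 1e-10)
  expect_error(estimate_noise(matrix(1, 1, 100)),
               class = "catraces_zero_noise")
})

test_that("transient detection finds planted events and nothing in flat traces", {
  fs <- 12.5
  ref_noise <- estimate_noise(matrix(rnorm(2000, sd = 0.05), 1))
  # flat zero trace: no events
  flat <- detect_transients(matrix(0, 1, 2000), ref_noise, frame_rate_hz = fs)
  expect_equal(nrow(flat$events), 0)
  expect_false(any(flat$active))
  # noiseless planted transient at 5x noise sd: exactly one event at onset
  x <- numeric(2000)
  onset <- 500
  x[onset:2000] <- 0.25 * exp(-(0:(2000 - onset)) / (1.8 * fs))
  ras <- detect_transients(matrix(x, 1), ref_noise, frame_rate_hz = fs)
  expect_equal(nrow(ras$events), 1)
  expect_equal(ras$events$onset, onset)
  expect_equal(ras$events$tau_hat_s, 1.8, tolerance = 0.05)
})

test_that("raising the confidence level never increases detected events", {
  fs <- 12.5
  # planted noiseless transients of graded amplitude: a stricter bound can
  # only drop whole events, never add them
  x <- numeric(6000)
  amps <- seq(0.08, 0.40, length.out = 12)
  onsets <- seq(200, 5700, by = 500)
  for (k in seq_along(onsets)) {
    o <- onsets[k]
    x[o:6000] <- x[o:6000] + amps[k] * exp(-(0:(6000 - o)) / (1.8 * fs))
  }
  ref_noise <- function(ci) structure(
    list(sd = 0.05, ci_level = ci, estimation_method = "fixed"),
    class = "ca_noise")
  counts <- vapply(c(0.90, 0.95, 0.98, 0.995), function(ci)
    nrow(detect_transients(matrix(x, 1), ref_noise(ci),
                           frame_rate_hz = fs)$events), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_lt(counts[length(counts)], counts[1])  # some events do drop out
  # on noisy traces the supra-threshold candidate sets are strictly nested
  set.seed(7)
  y <- rnorm(4000, sd = 0.05)
  for (o in seq(200, 3800, by = 400)) {
    y[o:4000] <- y[o:4000] + 0.3 * exp(-(0:(4000 - o)) / (1.8 * fs))
  }
  sd_hat <- estimate_noise(matrix(y, 1))$sd
  masks <- lapply(c(0.90, 0.95, 0.98, 0.995),
                  function(ci) which(y > qnorm(ci) * sd_hat))
  for (k in 2:4) expect_true(all(masks[[k]] %in% masks[[k - 1]]))
})

test_that("movement segmentation thresholds at 30 mm/s with a 6-frame debounce", {
  # all slow: all resting
  seg <- segment_movement(rep(5, 100))
  expect_false(any(seg$moving))
  # 5-frame excursion (below the 6-frame/240 ms debounce) is removed
  sp <- rep(5, 100); sp[50:54] <- 60
  expect_false(any(segment_movement(sp)$moving))
  # 10-frame bout survives exactly
  sp2 <- rep(5, 100); sp2[41:50] <- 60
  expect_identical(which(segment_movement(sp2)$moving), 41:50)
  # debounce also fills short rest gaps inside movement
  sp3 <- rep(60, 100); sp3[50:52] <- 5
  expect_true(all(segment_movement(sp3)$moving))
})

test_that("firing rates split event counts by movement state and conserve totals", {
  fs <- 12.5
  n_frames <- 7500  # 10 min
  spikes <- matrix(FALSE, 1, n_frames)
  spikes[1, seq(100, 3700, length.out = 10)] <- TRUE  # 10 onsets while moving
  ras <- raster_from_spikes(spikes, fs)
  seg <- structure(list(moving = c(rep(TRUE, 3750), rep(FALSE, 3750)),
                        threshold_mms = 30, min_bout_frames = 6,
                        frame_rate_hz = fs, fraction_moving = 0.5),
                   class = "ca_movement")
  rates <- firing_rates(ras, seg)
  expect_equal(rates$rate_moving, 2.0)   # 10 onsets in 5 moving minutes
  expect_equal(rates$rate_resting, 0)
  expect_equal(rates$n_moving + rates$n_resting, 10)
  # empty raster: all rates zero
  rates0 <- firing_rates(raster_from_spikes(matrix(FALSE, 2, n_frames), fs), seg)
  expect_true(all(rates0$rate_overall == 0))
})

test_that("movement-gain-modulated populations show the planted rate ratio", {
  gt <- ground_truth(n_neurons = 100, duration_s = 600,
                     assembly_memberships = list(),
                     background_rate_hz = 0.05, movement_rate_gain = 2,
                     noise_sd = 0, drift_amplitude = 0, seed = 31)
  rec <- simulate_population(gt)
  ras <- raster_from_spikes(rec$true_spike_raster, gt$frame_rate_hz)
  seg <- segment_movement(rec$speed)
  rates <- firing_rates(ras, seg)
  ratio <- mean(rates$rate_moving) / mean(rates$rate_resting)
  expect_lt(abs(ratio - 2) / 2, 0.15)
})

test_that("rate-speed correlation recovers construction and null cases", {
  fs <- 12.5
  n_frames <- 6000
  bins <- 48
  bin_frames <- n_frames / bins
  counts <- rep(seq_len(bins), times = seq_len(bins) %% 3 + 1)[seq_len(bins)]
  spikes <- matrix(FALSE, 1, n_frames)
  speed <- rep(0, n_frames)
  for (b in seq_len(bins)) {
    idx <- ((b - 1) * bin_frames + 1):(b * bin_frames)
    speed[idx] <- counts[b]
    if (counts[b] > 0) spikes[1, idx[seq_len(counts[b])]] <- TRUE
  }
  ras <- raster_from_spikes(spikes, fs)
  r <- rate_speed_correlation(ras, speed, bin_s = bin_frames / fs)
  expect_equal(r$r, 1, tolerance = 1e-10)
  r_neg <- rate_speed_correlation(ras, max(speed) - speed, bin_s = bin_frames / fs)
  expect_equal(r_neg$r, -1, tolerance = 1e-10)
  # independent Poisson events: mean r near 0
  set.seed(10)
  sp_mat <- matrix(runif(100 * n_frames) < 0.004, 100, n_frames)
  ras100 <- raster_from_spikes(sp_mat, fs)
  rr <- rate_speed_correlation(ras100, rnorm(n_frames, 50, 10), bin_s = 10)
  expect_lt(abs(mean(rr$r, na.rm = TRUE)), 0.05)
})
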