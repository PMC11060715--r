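#' Pipeline configuration
#'
#' Collects every stage parameter with defaults equal to the analysis
#' constants used throughout: neuropil alpha 0.4; 30-s / 8th-percentile
#' baseline; pair averaging (k = 2); 98% noise CI; tau 1.8 s; 30 mm/s
#' movement threshold with a 6-frame debounce; 5000 bootstrap iterations
#' with mean block 23 frames and a 99th-percentile cut; strong edges at
#' r > 0.3; Promax power 4; merge dot product 0.6; activation and
#' synchrony p < 0.05; widefield threshold 5 SD.
#'
#' @param ... Named overrides of any default listed above (see the source
#'   for the full set).
#' @param ground_truth Optional [ground_truth()] describing the synthetic
#'   recording to generate when none is supplied to [run_pipeline()].
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return A validated `ca_config` list.
#' @export
ca_config <- function(..., ground_truth = NULL, seed = 1L) {
  cfg <- list(
    group_k = 2L, alpha = 0.4, window_s = 30, percentile = 8,
    ci_level = 0.98, tau_s = 1.8,
    speed_threshold_mms = 30, min_bout_frames = 6L,
    n_bootstrap = 5000L, mean_block_frames = 23L, edge_quantile = 0.99,
    strong_threshold = 0.3,
    promax_power = 4, overlap_threshold = 0.6, z_max = NULL,
    n_surrogates = 1000L, p_synchrony = 0.05, p_activation = 0.05,
    matching_method = "proportion",
    widefield_k = 5, pixel_scale_um = 0.848,
    seed = as.integer(seed))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) abort(paste0("Unknown config field(s): ",
                                    paste(unknown, collapse = ", ")))
  cfg[names(dots)] <- dots
  with(cfg, {
    stopifnot(alpha >= 0, alpha <= 1, window_s > 0,
              percentile >= 0, percentile <= 100,
              ci_level > 0, ci_level < 1, tau_s > 0,
              speed_threshold_mms >= 0, min_bout_frames >= 1,
              n_bootstrap >= 1, mean_block_frames >= 1,
              edge_quantile > 0, edge_quantile < 1,
              strong_threshold >= -1, strong_threshold <= 1,
              overlap_threshold >= 0, overlap_threshold <= 1,
              p_synchrony > 0, p_synchrony < 1,
              p_activation > 0, p_activation < 1, widefield_k > 0)
  })
  # the argument shadows the constructor of the same name inside this frame
  cfg$ground_truth <- ground_truth %||% ground_truth_default(seed = cfg$seed)
  structure(cfg, class = "ca_config")
}

ground_truth_default <- function(...) ground_truth(...)

#' Run the full analysis chain
#'
#' Executes the stages in acquisition order on a recording (simulated from
#' the config's ground truth when none is given): pair-average, neuropil
#' correct, baseline, dF/F, z-score, noise model, transient detection,
#' movement segmentation, movement-conditioned rates, pairwise correlation
#' with a stationary-bootstrap null, graph construction, and PCA-Promax
#' assembly detection with activation statistics. All randomness derives
#' from the config seed, so identical configs reproduce identical results.
#'
#' @param config A [ca_config()].
#' @param recording Optional `ca_recording`; simulated when `NULL`.
#' @return A `ca_run`: stage outputs, a one-row `summary` tibble of the
#'   session-level statistics (population rates moving/resting,
#'   connections per neuron, strong connections, density, assembly count
#'   and sizes, percent of the population in assemblies, mean significant
#'   assembly-assembly r), and a reproducibility `manifest`.
#' @export
run_pipeline <- function(config = ca_config(), recording = NULL) {
  stopifnot(inherits(config, "ca_config"))
  t0 <- Sys.time()
  stage <- "simulate"
  res <- tryCatch({
    if (is.null(recording)) recording <- simulate_population(config$ground_truth)

    stage <- "preprocess"
    dff <- preprocess_traces(recording, k = config$group_k,
                             alpha = config$alpha, window_s = config$window_s,
                             percentile = config$percentile)

    stage <- "detect"
    noise <- estimate_noise(dff, ci_level = config$ci_level)
    raster <- detect_transients(dff, noise, tau_s = config$tau_s)

    stage <- "segment"
    seg <- segment_movement(recording$speed,
                            threshold_mms = config$speed_threshold_mms,
                            min_bout_frames = config$min_bout_frames,
                            frame_rate_hz = recording$speed_frame_rate_hz %||%
                              recording$frame_rate_hz)
    seg_eff <- resample_movement(seg, config$group_k)
    n_eff <- raster$n_frames
    seg_eff$moving <- seg_eff$moving[seq_len(n_eff)]
    rates <- firing_rates(raster, seg_eff)

    stage <- "connect"
    sds <- apply(dff$dff, 1, sd)
    keep <- which(sds > 0)
    z <- zscore_traces(dff$dff[keep, , drop = FALSE])
    corr <- pairwise_correlation(z)
    null <- stationary_bootstrap_null(
      z, n_iterations = config$n_bootstrap,
      mean_block_frames = config$mean_block_frames,
      quantile = config$edge_quantile, seed = stage_seed(config$seed, 11L))
    graph <- build_graph(corr, null, recording$roi_centroids[keep, ],
                         strong_threshold = config$strong_threshold)

    stage <- "assemble"
    raster_keep <- raster$active[keep, , drop = FALSE]
    onsets_keep <- onset_raster(raster)[keep, , drop = FALSE]
    model <- find_assemblies(z, onsets_keep,
                             promax_power = config$promax_power,
                             z_max = config$z_max,
                             overlap_threshold = config$overlap_threshold,
                             n_surrogates = config$n_surrogates,
                             p_synchrony = config$p_synchrony,
                             seed = stage_seed(config$seed, 13L))
    n_asm <- length(model$memberships)
    activation <- if (n_asm > 0) {
      assembly_activation(raster_keep, model,
                          p_threshold = config$p_activation,
                          method = config$matching_method,
                          frame_rate_hz = raster$frame_rate_hz)
    } else NULL
    aa <- if (n_asm >= 2) {
      assembly_assembly_correlation(
        activation, n_iterations = min(config$n_bootstrap, 1000L),
        mean_block_frames = config$mean_block_frames,
        quantile = config$edge_quantile, seed = stage_seed(config$seed, 17L))
    } else NULL

    stage <- "summarise"
    members_all <- unique(unlist(model$memberships))
    summary <- tibble(
      n_neurons = nrow(dff$dff),
      n_frames_effective = n_eff,
      frame_rate_effective_hz = raster$frame_rate_hz,
      fraction_moving = attr(rates, "fraction_moving"),
      rate_moving_per_min = mean(rates$rate_moving, na.rm = TRUE),
      rate_resting_per_min = mean(rates$rate_resting, na.rm = TRUE),
      connections_per_neuron = graph$connections_per_neuron,
      strong_connections_per_neuron = graph$strong_connections_per_neuron,
      density_percent = graph$density_percent,
      n_assemblies = n_asm,
      mean_neurons_per_assembly = if (n_asm > 0)
        mean(lengths(model$memberships)) else NA_real_,
      percent_population_in_assemblies =
        100 * length(members_all) / nrow(dff$dff),
      mean_assembly_assembly_r = if (!is.null(aa)) aa$mean_r_significant
                                 else NA_real_)
    list(recording = recording, dff = dff, noise = noise, raster = raster,
         movement = seg_eff, rates = rates, graph = graph,
         assemblies = model, activation = activation,
         assembly_pairs = aa, kept_neurons = keep, summary = summary)
  }, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)), class = "catraces_stage_error")
  })
  cfg_ser <- unclass(config)
  cfg_ser$ground_truth <- unclass(cfg_ser$ground_truth)
  manifest <- list(
    config_hash = md5_of(cfg_ser), seed = config$seed,
    package_version = as.character(utils::packageVersion("catraces")),
    summary_hash = md5_of(as.list(res$summary)),
    created = format(t0, "%Y-%m-%dT%H:%M:%S%z"))
  res$manifest <- manifest
  res$config <- config
  structure(res, class = "ca_run")
}

#' Write pipeline outputs as tidy delimited tables
#'
#' Writes `summary.csv`, per-neuron `rates.csv`, the graph `edges.csv` and
#' `nodes.csv`, the transient `events.csv`, the assembly membership long
#' table `assemblies.csv`, and `manifest.json` into `dir`.
#'
#' @param run A `ca_run`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "ca_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(run$summary, file.path(dir, "summary.csv"))
  readr::write_csv(as_tibble(run$rates), file.path(dir, "rates.csv"))
  readr::write_csv(run$graph$edges, file.path(dir, "edges.csv"))
  readr::write_csv(run$graph$nodes, file.path(dir, "nodes.csv"))
  readr::write_csv(run$raster$events, file.path(dir, "events.csv"))
  readr::write_csv(tidy(run$assemblies), file.path(dir, "assemblies.csv"))
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# ---- recording I/O -------------------------------------------------------

#' Write a recording to delimited tables with a JSON manifest
#'
#' `roi.csv` and `neuropil.csv` hold one neuron per row (first column
#' `neuron`), `centroids.csv` the `(id, x_um, y_um)` table, `speed.csv` the
#' tracking trace, and `ground_truth.json` the full generator config
#' including the seed.
#'
#' @param rec A `ca_recording`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "ca_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mat_tbl <- function(m) {
    df <- as_tibble(as.data.frame(m), .name_repair = ~ paste0("f", seq_along(.x)))
    df$neuron <- seq_len(nrow(m))
    dplyr::relocate(df, "neuron")
  }
  readr::write_csv(mat_tbl(rec$roi_fluorescence), file.path(dir, "roi.csv"))
  readr::write_csv(mat_tbl(rec$neuropil_fluorescence),
                   file.path(dir, "neuropil.csv"))
  readr::write_csv(rec$roi_centroids, file.path(dir, "centroids.csv"))
  readr::write_csv(tibble(frame = seq_along(rec$speed), speed_mms = rec$speed),
                   file.path(dir, "speed.csv"))
  gt <- unclass(rec$ground_truth)
  gt$frame_rate_hz_check <- rec$frame_rate_hz
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

read_trace_csv <- function(path, what) {
  if (!file.exists(path)) abort(paste0("Missing file: ", path),
                                class = "catraces_schema_error")
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"neuron" %in% names(df)) {
    abort(sprintf("%s: missing required `neuron` column.", path),
          class = "catraces_schema_error")
  }
  m <- as.matrix(df[, setdiff(names(df), "neuron"), drop = FALSE])
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("%s: non-finite %s value at neuron %d, frame %d.",
                  path, what, bad[1, 1], bad[1, 2]),
          class = "catraces_schema_error")
  }
  dimnames(m) <- NULL
  m
}

#' Read a recording written by [write_recording()]
#'
#' Validates the schema (required columns, matching shapes, finite values)
#' and reports the offending file, row or field on failure.
#'
#' @param dir Directory containing `roi.csv`, `neuropil.csv`,
#'   `centroids.csv`, `speed.csv`, `ground_truth.json`.
#' @return A `ca_recording` (without the raster/clean-trace ground-truth
#'   matrices, which live only in memory).
#' @export
read_recording <- function(dir) {
  roi <- read_trace_csv(file.path(dir, "roi.csv"), "fluorescence")
  np <- read_trace_csv(file.path(dir, "neuropil.csv"), "neuropil")
  if (!all(dim(roi) == dim(np))) {
    abort("roi.csv and neuropil.csv differ in shape.",
          class = "catraces_schema_error")
  }
  cent_path <- file.path(dir, "centroids.csv")
  cent <- readr::read_csv(cent_path, show_col_types = FALSE, progress = FALSE)
  for (f in c("id", "x_um", "y_um")) {
    if (!f %in% names(cent)) {
      abort(sprintf("%s: missing required `%s` column.", cent_path, f),
            class = "catraces_schema_error")
    }
  }
  sp <- readr::read_csv(file.path(dir, "speed.csv"), show_col_types = FALSE,
                        progress = FALSE)
  if (!"speed_mms" %in% names(sp)) {
    abort("speed.csv: missing required `speed_mms` column.",
          class = "catraces_schema_error")
  }
  gt_raw <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                                simplifyVector = TRUE)
  gt <- ground_truth(
    n_neurons = gt_raw$n_neurons, frame_rate_hz = gt_raw$frame_rate_hz,
    duration_s = gt_raw$duration_s,
    assembly_memberships = gt_raw$assembly_memberships,
    assembly_event_rate_hz = gt_raw$assembly_event_rate_hz,
    background_rate_hz = gt_raw$background_rate_hz,
    movement_rate_gain = gt_raw$movement_rate_gain, tau_s = gt_raw$tau_s,
    transient_amplitude = gt_raw$transient_amplitude,
    noise_sd = gt_raw$noise_sd, drift_amplitude = gt_raw$drift_amplitude,
    drift_period_s = gt_raw$drift_period_s,
    neuropil_coefficient_true = gt_raw$neuropil_coefficient_true,
    seed = gt_raw$seed)
  structure(list(roi_fluorescence = roi, neuropil_fluorescence = np,
                 roi_centroids = as_tibble(cent), speed = sp$speed_mms,
                 speed_frame_rate_hz = gt$frame_rate_hz,
                 frame_rate_hz = gt$frame_rate_hz, ground_truth = gt),
            class = "ca_recording")
}

#' Read tapered-beam events
#'
#' @param path CSV with columns `trial`, `position_cm`, `side`, `kind`.
#' @return Validated tibble.
#' @export
read_beam_events <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (f in c("trial", "position_cm", "side", "kind")) {
    if (!f %in% names(df)) {
      abort(sprintf("%s: missing required `%s` column.", path, f),
            class = "catraces_schema_error")
    }
  }
  df
}

#' Read paw trajectory paths
#'
#' @param path CSV with columns `frame`, `paw`, `x`, `y`.
#' @return Validated tibble.
#' @export
read_paw_paths <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (f in c("frame", "paw", "x", "y")) {
    if (!f %in% names(df)) {
      abort(sprintf("%s: missing required `%s` column.", path, f),
            class = "catraces_schema_error")
    }
  }
  if (any(!is.finite(df$x)) || any(!is.finite(df$y))) {
    bad <- which(!is.finite(df$x) | !is.finite(df$y))[1]
    abort(sprintf("%s: non-finite coordinate at row %d.", path, bad),
          class = "catraces_schema_error")
  }
  df
}
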