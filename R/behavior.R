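#' Tapered-beam slip metrics
#'
#' Counts foot slips by side and reports the distance along the beam to the
#' first slip. Runs without slips score the full traversed length, which
#' preserves the farther-is-better ordering when averaging trials.
#'
#' @param events Tibble/data frame ordered by traversal with columns
#'   `position_cm`, `side` (`"left"`/`"right"`), `kind` (`"step"`/`"slip"`).
#' @param beam_length_cm Beam length, cm.
#' @return One-row tibble: `left_slips`, `right_slips`,
#'   `distance_to_first_slip_cm`.
#' @export
beam_metrics <- function(events, beam_length_cm) {
  assert_scalar(beam_length_cm, "beam_length_cm", lower = 1e-9)
  ev <- as_tibble(events)
  if (nrow(ev) > 0) {
    if (any(ev$position_cm < 0 | ev$position_cm > beam_length_cm)) {
      abort("Event positions must lie within [0, beam_length_cm].",
            class = "catraces_invalid_config")
    }
    if (!all(ev$side %in% c("left", "right")) ||
        !all(ev$kind %in% c("step", "slip"))) {
      abort("`side` must be left/right and `kind` step/slip.",
            class = "catraces_invalid_config")
    }
  }
  slips <- ev[ev$kind == "slip", , drop = FALSE]
  tibble(
    left_slips = sum(slips$side == "left"),
    right_slips = sum(slips$side == "right"),
    distance_to_first_slip_cm = if (nrow(slips) > 0) slips$position_cm[1]
                                else beam_length_cm)
}

#' Path circuity of a paw movement
#'
#' Total distance travelled divided by the Euclidean distance between the
#' start and end points; 1 indicates a perfectly direct path, larger values
#' a more circuitous one.
#'
#' @param path Two-column matrix or data frame of `(x, y)` positions.
#' @return Circuity ratio (`NA` with a warning when start equals end).
#' @export
path_circuity <- function(path) {
  p <- as.matrix(if (is.data.frame(path)) path[, c("x", "y")] else path)
  if (nrow(p) < 2) abort("Path needs >= 2 points.",
                         class = "catraces_invalid_parameter")
  steps <- sqrt(rowSums(diff(p)^2))
  chord <- sqrt(sum((p[nrow(p), ] - p[1, ])^2))
  if (chord == 0) {
    warn("Start equals end point: circuity undefined.")
    return(NA_real_)
  }
  sum(steps) / chord
}

#' Reach/withdraw movement scaling
#'
#' Pearson correlation between per-event path lengths and per-event peak
#' speeds; 1 indicates that longer movements attain proportionally greater
#' peak speed.
#'
#' @param path_lengths,peak_speeds Numeric vectors, one value per
#'   reach/withdraw event.
#' @return Pearson r (`NA` with a warning for < 3 events or zero variance).
#' @export
movement_scaling <- function(path_lengths, peak_speeds) {
  if (length(path_lengths) != length(peak_speeds)) {
    abort("Event series differ in length.", class = "catraces_dimension_error")
  }
  if (length(path_lengths) < 3 || sd(path_lengths) == 0 ||
      sd(peak_speeds) == 0) {
    warn("Movement scaling undefined (< 3 events or zero variance).")
    return(NA_real_)
  }
  cor(path_lengths, peak_speeds)
}

#' Bimanual correlation of paw height
#'
#' Linearly detrends each paw's vertical position series (removing slow
#' postural change) and correlates the residuals.
#'
#' @param left_y,right_y Equal-length numeric vectors of Y-axis paw
#'   position.
#' @return Pearson r (`NA` with a warning when a detrended series is
#'   constant).
#' @export
bimanual_correlation <- function(left_y, right_y) {
  if (length(left_y) != length(right_y)) {
    abort("Paw series differ in length.", class = "catraces_dimension_error")
  }
  if (length(left_y) < 3) abort("Need >= 3 samples.",
                                class = "catraces_invalid_parameter")
  tt <- seq_along(left_y)
  dl <- residuals(lm(left_y ~ tt))
  dr <- residuals(lm(right_y ~ tt))
  if (sd(dl) == 0 || sd(dr) == 0) {
    warn("Constant detrended series: correlation undefined.")
    return(NA_real_)
  }
  cor(dl, dr)
}

#' Kinematic summary of simulated or segmented string-pull data
#'
#' Convenience wrapper computing per-paw movement scaling, mean reach
#' distance, per-event path circuity, and the bimanual correlation from a
#' `ca_paws` object (or equivalently structured data).
#'
#' @param paws A `ca_paws` from [simulate_paws()].
#' @return List of tidy tibbles: `per_paw` and `per_event`.
#' @export
pull_kinematics <- function(paws) {
  stopifnot(inherits(paws, "ca_paws"))
  traj <- list(left = paws$left, right = paws$right)
  per_event <- paws$segments %>%
    group_by(.data$paw, .data$segment) %>%
    mutate(circuity = {
      tr <- traj[[.data$paw[1]]]
      idx <- (.data$start[1] - 1L):.data$end[1]
      idx <- idx[idx >= 1]
      path_circuity(tr[idx, c("x", "y")])
    }) %>%
    ungroup()
  per_paw <- per_event %>%
    group_by(.data$paw) %>%
    summarise(
      movement_scaling_r = movement_scaling(.data$length_px, .data$peak_speed_px),
      mean_reach_distance_px = mean(.data$length_px),
      mean_circuity = mean(.data$circuity), .groups = "drop") %>%
    mutate(bimanual_r = bimanual_correlation(paws$left$y, paws$right$y))
  list(per_paw = per_paw, per_event = per_event)
}
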