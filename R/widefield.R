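#' Trial-averaged sensory response map
#'
#' Averages the trial stack, then forms the per-pixel response as
#' `(mean post - mean pre) / mean pre` using `post_frames` frames from
#' stimulus onset and `pre_frames` baseline frames before it (the standard
#' 10-frame / 1-s windows at 10 Hz). The baseline sd map is the per-pixel
#' sd of the pre-stimulus dF/F frames of the trial average.
#'
#' @param stack 4-D array `trials x frames x H x W`, or a `ca_widefield`.
#' @param stim_onset_frame First post-stimulus frame (1-based).
#' @param pre_frames,post_frames Window lengths, frames.
#' @param pixel_scale_mm Millimetres per pixel (metadata).
#' @param convention `"difference"` for `(post - pre)/pre` (dF/F, default)
#'   or `"ratio"` for `post/pre`.
#' @return A `ca_map`: `dff_map`, `baseline_sd_map`, `pixel_scale_mm`.
#' @export
trial_average_map <- function(stack, stim_onset_frame = NULL,
                              pre_frames = 10, post_frames = 10,
                              pixel_scale_mm = NULL,
                              convention = c("difference", "ratio")) {
  convention <- match.arg(convention)
  if (inherits(stack, "ca_widefield")) {
    stim_onset_frame <- stim_onset_frame %||% stack$stim_onset_frame
    pixel_scale_mm <- pixel_scale_mm %||% stack$pixel_scale_mm
    pre_frames <- stack$pre_frames
    post_frames <- stack$post_frames
    stack <- stack$stack
  }
  stopifnot(length(dim(stack)) == 4)
  n_frames <- dim(stack)[2]
  if (stim_onset_frame - pre_frames < 1 ||
      stim_onset_frame + post_frames - 1 > n_frames) {
    abort("Stack too short for the requested pre/post windows.",
          class = "catraces_invalid_parameter")
  }
  avg <- apply(stack, c(2, 3, 4), mean)             # frames x H x W
  pre_idx <- (stim_onset_frame - pre_frames):(stim_onset_frame - 1)
  post_idx <- stim_onset_frame:(stim_onset_frame + post_frames - 1)
  mean_pre <- apply(avg[pre_idx, , , drop = FALSE], c(2, 3), mean)
  mean_post <- apply(avg[post_idx, , , drop = FALSE], c(2, 3), mean)
  invalid <- mean_pre == 0
  mean_pre[invalid] <- NA_real_
  dff_map <- if (convention == "difference") (mean_post - mean_pre) / mean_pre
             else mean_post / mean_pre
  pre_dff <- sweep(sweep(avg[pre_idx, , , drop = FALSE], c(2, 3), mean_pre, "-"),
                   c(2, 3), mean_pre, "/")
  baseline_sd_map <- apply(pre_dff, c(2, 3), sd)
  structure(list(dff_map = dff_map, baseline_sd_map = baseline_sd_map,
                 pixel_scale_mm = pixel_scale_mm, convention = convention),
            class = "ca_map")
}

#' Threshold a response map at k baseline standard deviations
#'
#' Masks pixels whose response exceeds `k` (default 5) times the per-pixel
#' baseline sd, and summarises the supra-threshold region: area in mm^2,
#' peak amplitude, and the intensity-weighted centroid in mm (0-based pixel
#' indices, x = column, origin top-left).
#'
#' @param map A `ca_map` (or pass `dff_map` and `baseline_sd_map` matrices).
#' @param k Threshold multiplier.
#' @param pixel_scale_mm Millimetres per pixel; defaults to the map's.
#' @return A `ca_response_map`: `mask`, `area_mm2`, `peak_amplitude`,
#'   `centroid_mm` (NA with a warning when the mask is empty).
#' @export
threshold_map <- function(map, k = 5, pixel_scale_mm = NULL) {
  stopifnot(inherits(map, "ca_map"))
  scale_mm <- pixel_scale_mm %||% map$pixel_scale_mm
  if (is.null(scale_mm)) abort("`pixel_scale_mm` is required.",
                               class = "catraces_invalid_parameter")
  dff <- map$dff_map
  mask <- !is.na(dff) & !is.na(map$baseline_sd_map) &
    dff > k * map$baseline_sd_map
  area_mm2 <- sum(mask) * scale_mm^2
  if (!any(mask)) {
    warn("Empty supra-threshold mask: centroid undefined.")
    peak <- NA_real_; centroid <- c(NA_real_, NA_real_)
  } else {
    peak <- max(dff[mask])
    w <- dff * mask
    w[is.na(w)] <- 0
    cols <- outer(rep(1, nrow(dff)), 0:(ncol(dff) - 1))
    rows <- outer(0:(nrow(dff) - 1), rep(1, ncol(dff)))
    centroid <- c(sum(cols * w), sum(rows * w)) / sum(w) * scale_mm
  }
  structure(list(dff_map = dff, baseline_sd_map = map$baseline_sd_map,
                 mask = mask, k = k, area_mm2 = area_mm2,
                 peak_amplitude = peak, centroid_mm = centroid,
                 pixel_scale_mm = scale_mm),
            class = "ca_response_map")
}

#' Centroid shift between two response maps
#'
#' Euclidean distance between the intensity-weighted centroids of two
#' thresholded maps, in millimetres — the map-displacement statistic for
#' longitudinal comparisons.
#'
#' @param map_a,map_b `ca_response_map` objects with the same pixel scale.
#' @return Shift in mm.
#' @export
map_shift <- function(map_a, map_b) {
  stopifnot(inherits(map_a, "ca_response_map"),
            inherits(map_b, "ca_response_map"))
  if (any(is.na(map_a$centroid_mm)) || any(is.na(map_b$centroid_mm))) {
    abort("Undefined centroid in one of the maps.",
          class = "catraces_undefined_centroid")
  }
  if (!isTRUE(all.equal(map_a$pixel_scale_mm, map_b$pixel_scale_mm))) {
    abort("Maps have different pixel scales.", class = "catraces_invalid_parameter")
  }
  sqrt(sum((map_a$centroid_mm - map_b$centroid_mm)^2))
}

# Even-odd (ray casting) point-in-polygon test; vertices as (x, y) rows.
points_in_polygon <- function(px, py, poly_x, poly_y) {
  n <- length(poly_x)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((poly_y[i] > py) != (poly_y[j] > py)) &
      (px < (poly_x[j] - poly_x[i]) * (py - poly_y[i]) /
         (poly_y[j] - poly_y[i]) + poly_x[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Response amplitude within a fixed ROI polygon
#'
#' Peak and mean dF/F over the pixels inside a polygon (0-based pixel
#' coordinates, x = column), e.g. a distal region held fixed relative to
#' vasculature across sessions.
#'
#' @param dff_map Response matrix (H x W) or a `ca_map`.
#' @param roi_polygon Two-column matrix of `(x, y)` vertices.
#' @return List with `peak` and `mean` dF/F.
#' @export
roi_amplitude <- function(dff_map, roi_polygon) {
  if (inherits(dff_map, "ca_map")) dff_map <- dff_map$dff_map
  poly <- as.matrix(roi_polygon)
  if (nrow(poly) < 3) abort("Polygon needs >= 3 vertices.",
                            class = "catraces_invalid_parameter")
  if (min(poly[, 1]) < 0 || max(poly[, 1]) > ncol(dff_map) - 1 ||
      min(poly[, 2]) < 0 || max(poly[, 2]) > nrow(dff_map) - 1) {
    abort("Polygon extends outside the image bounds.",
          class = "catraces_invalid_parameter")
  }
  cols <- as.vector(outer(rep(1, nrow(dff_map)), 0:(ncol(dff_map) - 1)))
  rows <- as.vector(outer(0:(nrow(dff_map) - 1), rep(1, ncol(dff_map))))
  inside <- points_in_polygon(cols, rows, poly[, 1], poly[, 2])
  vals <- as.vector(dff_map)[inside]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) abort("Polygon contains no pixels.",
                               class = "catraces_empty_roi")
  list(peak = max(vals), mean = mean(vals))
}
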