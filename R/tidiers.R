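#' Tidy a transient raster into an event table
#'
#' @param x A `ca_raster`.
#' @param ... Unused.
#' @return Tibble `(neuron, onset, duration, tau_hat_s)`.
#' @export
tidy.ca_raster <- function(x, ...) x$events

#' @rdname glance-methods
#' @export
glance.ca_raster <- function(x, ...) {
  tibble(n_neurons = nrow(x$active), n_frames = x$n_frames,
         n_events = nrow(x$events),
         mean_rate_per_min = mean(x$rate_per_min),
         active_frame_fraction = mean(x$active))
}

#' Tidy a functional graph into its edge list
#'
#' @param x A `ca_graph`.
#' @param ... Unused.
#' @return The `(i, j, r, threshold, strong, distance_um)` edge tibble.
#' @export
tidy.ca_graph <- function(x, ...) x$edges

#' One-row summaries of fitted objects
#'
#' `glance()` methods return the session-level scalar statistics of each
#' result type, one row per object, in the style of model tidiers.
#'
#' @param x A fitted catraces object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @name glance-methods
#' @export
glance.ca_graph <- function(x, ...) {
  tibble(n_neurons = x$n_neurons, n_edges = nrow(x$edges),
         connections_per_neuron = x$connections_per_neuron,
         strong_connections_per_neuron = x$strong_connections_per_neuron,
         density_percent = x$density_percent)
}

#' Tidy an assembly model into a long membership table
#'
#' @param x A `ca_assemblies`.
#' @param ... Unused.
#' @return Tibble `(assembly, neuron)` with one row per membership.
#' @export
tidy.ca_assemblies <- function(x, ...) {
  if (length(x$memberships) == 0) {
    return(tibble(assembly = integer(), neuron = integer()))
  }
  bind_rows(imap(x$memberships, function(mem, a)
    tibble(assembly = a, neuron = mem)))
}

#' @rdname glance-methods
#' @export
glance.ca_assemblies <- function(x, ...) {
  tibble(n_assemblies = length(x$memberships),
         n_pcs = x$n_pcs, z_max = x$z_max,
         mean_size = if (length(x$memberships)) mean(lengths(x$memberships))
                     else NA_real_,
         n_merged = nrow(x$merge_log),
         max_synchrony_p = if (length(x$synchrony_p)) max(x$synchrony_p)
                           else NA_real_)
}

#' @rdname glance-methods
#' @export
glance.ca_rates <- function(x, ...) {
  tibble(rate_moving_per_min = mean(x$rate_moving, na.rm = TRUE),
         rate_resting_per_min = mean(x$rate_resting, na.rm = TRUE),
         rate_overall_per_min = mean(x$rate_overall),
         fraction_moving = attr(x, "fraction_moving"))
}

#' @rdname glance-methods
#' @export
glance.ca_response_map <- function(x, ...) {
  tibble(area_mm2 = x$area_mm2, peak_amplitude = x$peak_amplitude,
         centroid_x_mm = x$centroid_mm[1], centroid_y_mm = x$centroid_mm[2],
         k = x$k)
}

#' @rdname glance-methods
#' @export
glance.ca_run <- function(x, ...) x$summary

#' @export
print.ca_ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ca_ground_truth> %d neurons, %.0f s @ %g Hz, %d assemblies, seed %d\n",
    x$n_neurons, x$duration_s, x$frame_rate_hz,
    length(x$assembly_memberships), x$seed))
  invisible(x)
}

#' @export
print.ca_recording <- function(x, ...) {
  cat(sprintf("<ca_recording> %d neurons x %d frames @ %g Hz\n",
              nrow(x$roi_fluorescence), ncol(x$roi_fluorescence),
              x$frame_rate_hz))
  invisible(x)
}

#' @export
print.ca_raster <- function(x, ...) {
  cat(sprintf("<ca_raster> %d neurons x %d frames, %d events (%.2f/min mean)\n",
              nrow(x$active), x$n_frames, nrow(x$events),
              mean(x$rate_per_min)))
  invisible(x)
}

#' @export
print.ca_graph <- function(x, ...) {
  cat(sprintf("<ca_graph> %d neurons, %d edges, density %.1f%%\n",
              x$n_neurons, nrow(x$edges), x$density_percent))
  invisible(x)
}

#' @export
print.ca_assemblies <- function(x, ...) {
  cat(sprintf("<ca_assemblies> %d assemblies (sizes: %s), n_pcs %d, z_max %.2f\n",
              length(x$memberships),
              paste(lengths(x$memberships), collapse = ", "),
              x$n_pcs, x$z_max))
  invisible(x)
}
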