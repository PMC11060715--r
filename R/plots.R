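#' Plot dF/F traces as a stacked raster of lines
#'
#' @param object A `ca_dff`.
#' @param neurons Indices of neurons to draw (default first 10).
#' @param offset Vertical offset between traces, dF/F units.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ca_dff <- function(object, neurons = seq_len(min(10, nrow(object$dff))),
                            offset = 1, ...) {
  fs <- object$frame_rate_hz
  df <- bind_rows(imap(as.list(neurons), function(nn, k)
    tibble(neuron = nn, time_s = (seq_len(ncol(object$dff)) - 1) / fs,
           dff = object$dff[nn, ] + (k - 1) * offset)))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$dff,
                                   group = .data$neuron)) +
    ggplot2::geom_line(linewidth = 0.25) +
    ggplot2::labs(x = "Time (s)", y = sprintf("dF/F (offset %g)", offset)) +
    ggplot2::theme_minimal()
}

#' Plot a transient raster
#'
#' @param object A `ca_raster`.
#' @param ... Unused.
#' @return A ggplot object with one tick per significant-transient frame.
#' @export
autoplot.ca_raster <- function(object, ...) {
  idx <- which(object$active, arr.ind = TRUE)
  df <- tibble(neuron = idx[, 1],
               time_s = (idx[, 2] - 1) / object$frame_rate_hz)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$neuron)) +
    ggplot2::geom_point(shape = 15, size = 0.3, colour = "firebrick") +
    ggplot2::labs(x = "Time (s)", y = "Neuron") +
    ggplot2::theme_minimal()
}

#' Plot a functional connectivity graph in anatomical coordinates
#'
#' Nodes at ROI centroids; edges drawn for significant pairs with line
#' width scaled by correlation strength.
#'
#' @param object A `ca_graph` built with centroids.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ca_graph <- function(object, ...) {
  e <- object$edges %>%
    left_join(rename(object$nodes, xi = "x_um", yi = "y_um"),
              by = c(i = "neuron")) %>%
    left_join(rename(object$nodes, xj = "x_um", yj = "y_um"),
              by = c(j = "neuron"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = e,
                          ggplot2::aes(x = .data$xi, y = .data$yi,
                                       xend = .data$xj, yend = .data$yj,
                                       linewidth = .data$r, colour = .data$r),
                          alpha = 0.6) +
    ggplot2::geom_point(data = object$nodes,
                        ggplot2::aes(.data$x_um, .data$y_um),
                        colour = "red", size = 1) +
    ggplot2::scale_linewidth(range = c(0.1, 1.2)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()
}

#' Plot a thresholded widefield response map
#'
#' @param object A `ca_response_map`.
#' @param ... Unused.
#' @return A ggplot object (dF/F heat map with the supra-threshold mask
#'   outlined by its pixels).
#' @export
autoplot.ca_response_map <- function(object, ...) {
  H <- nrow(object$dff_map); W <- ncol(object$dff_map)
  df <- tibble(x = rep(0:(W - 1), each = H), y = rep(0:(H - 1), W),
               dff = as.vector(object$dff_map),
               masked = as.vector(object$mask))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$dff)) +
    ggplot2::geom_raster() +
    ggplot2::geom_point(data = filter(df, .data$masked),
                        ggplot2::aes(.data$x, .data$y),
                        inherit.aes = FALSE, size = 0.1, alpha = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)", fill = "dF/F") +
    ggplot2::theme_minimal()
}

#' Plot assembly activation time courses
#'
#' Percent-of-maximum activation (significance-masked matching index) per
#' assembly over time.
#'
#' @param object A `ca_activation`.
#' @param ... Unused.
#' @return A ggplot object, one facet per assembly.
#' @export
autoplot.ca_activation <- function(object, ...) {
  fs <- if (is.na(object$frame_rate_hz)) 1 else object$frame_rate_hz
  n_frames <- ncol(object$percent_of_max)
  df <- bind_rows(lapply(seq_len(nrow(object$percent_of_max)), function(a)
    tibble(assembly = a, time_s = (seq_len(n_frames) - 1) / fs,
           pct = object$percent_of_max[a, ])))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$pct)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$assembly)) +
    ggplot2::labs(x = "Time (s)", y = "% of max activation") +
    ggplot2::theme_minimal()
}
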