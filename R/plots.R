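motion_palette <- function() {
  c(directed = "#C837AB", anomalous = "#2E8B57", confined = "#DAA520",
    normal = "#C0392B")
}

#' Plot segmented trajectories
#'
#' Draws each trajectory path with positions coloured by the assigned motion
#' class, one facet per trajectory.
#'
#' @param object A `motion_segmentation` from [classify_tracks()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot motion_segmentation
#' @export
autoplot.motion_segmentation <- function(object, ...) {
  pos <- object$positions
  ggplot2::ggplot(pos, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path(ggplot2::aes(group = .data$id), colour = "grey70",
                       linewidth = 0.3) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$class), size = 0.8) +
    ggplot2::scale_colour_manual(values = motion_palette(), drop = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(ggplot2::vars(.data$id), scales = "free") +
    ggplot2::labs(x = "x [µm]", y = "y [µm]", colour = "class")
}

#' Plot a sensitivity grid
#'
#' Heat map of classification sensitivity over the simulated condition grid
#' (signal-to-noise ratio against the class parameter).
#'
#' @param object A `motion_sensitivity` tibble from [sensitivity_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot motion_sensitivity
#' @export
autoplot.motion_sensitivity <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(factor(.data$snr), factor(.data$param),
                                       fill = .data$sensitivity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "SNR", y = "class parameter", fill = "sensitivity",
                  title = unique(object$class))
}

#' Plot an MSD model fit
#'
#' Empirical MSD points with the fitted motion-model curve.
#'
#' @param object An `msd_model_fit` from [fit_msd_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot msd_model_fit
#' @export
autoplot.msd_model_fit <- function(object, ...) {
  df <- object$curve
  df$fitted <- object$fitted
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$msd)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "#C0392B") +
    ggplot2::labs(x = "lag time [s]", y = "MSD [µm²]",
                  title = paste("model:", object$model))
}

#' Plot out-of-bag confusion
#'
#' Row-normalized out-of-bag confusion matrix as a tile plot (rows =
#' reference class, columns = prediction, in percent).
#'
#' @param object A `motion_oob` from [oob_evaluation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot motion_oob
#' @export
autoplot.motion_oob <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("reference", "prediction", "pct")
  ggplot2::ggplot(df, ggplot2::aes(.data$prediction, .data$reference,
                                   fill = .data$pct)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$pct)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2E8B57") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(fill = "%")
}

#' Plot empirical MSD curves
#'
#' Convenience line plot of per-trajectory MSD curves, optionally on
#' log-log axes where the anomalous exponent is the slope.
#'
#' @param tracks A track table.
#' @param max_lag Largest lag to show (default `N/2` per trajectory).
#' @param log Use log-log axes.
#' @return A ggplot object.
#' @export
plot_track_msd <- function(tracks, max_lag = NULL, log = FALSE) {
  validate_tracks(tracks)
  curves <- dplyr::bind_rows(lapply(track_list(tracks), function(tr) {
    N <- length(tr$x)
    ml <- min(max_lag %||% floor(N / 2), N - 1L)
    track_msd(tracks[tr$rows, ], lags = seq_len(ml))
  }))
  p <- ggplot2::ggplot(curves, ggplot2::aes(.data$time, .data$msd,
                                            group = .data$id,
                                            colour = factor(.data$id))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "lag time [s]", y = "MSD [µm²]",
                  colour = "trajectory")
  if (log) p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  p
}
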