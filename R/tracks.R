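#' Build a validated trajectory table
#'
#' Trajectories are stored in ordinary tibbles with one row per recorded
#' position and columns `id` (trajectory identifier), `frame` (0-based frame
#' index, gap-free within a trajectory), `x`, `y` (coordinates in micrometres)
#' and `dt` (frame interval in seconds, constant within a trajectory). All
#' functions in the package consume and return this shape, so trajectory sets
#' compose with the usual dplyr verbs.
#'
#' @param data A data frame with at least `id` (or `trajectory_id`), `frame`,
#'   `x` (or `x_um`) and `y` (or `y_um`) columns. A `dt` column is used when
#'   present.
#' @param dt Frame interval in seconds. Required when `data` carries no `dt`
#'   column; when `frame_rate` is given, `dt = 1/frame_rate`.
#' @param pixel_size Optional pixel size in micrometres per pixel. When given,
#'   coordinates are multiplied by it (use for pixel-unit inputs).
#' @param frame_rate Optional frame rate in Hz, an alternative to `dt`.
#' @return A tibble with columns `id`, `frame`, `x`, `y`, `dt` (plus any
#'   extra columns of `data`), ordered by `id` and `frame`.
#' @examples
#' df <- data.frame(id = 1, frame = 0:3, x = c(0, 1, 2, 3), y = 0)
#' as_tracks(df, dt = 1 / 30)
#' @export
as_tracks <- function(data, dt = NULL, pixel_size = NULL, frame_rate = NULL) {
  data <- as_tibble(data)
  nm <- names(data)
  ren <- c(id = "trajectory_id", x = "x_um", y = "y_um")
  for (to in names(ren)) {
    if (!to %in% nm && ren[[to]] %in% nm) {
      names(data)[names(data) == ren[[to]]] <- to
      nm <- names(data)
    }
  }
  missing_cols <- setdiff(c("id", "frame", "x", "y"), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "sptmotion_schema_error")
  }
  if (!is.null(frame_rate)) {
    if (!is.null(dt)) abort("give either `dt` or `frame_rate`, not both")
    dt <- 1 / frame_rate
  }
  if (!"dt" %in% names(data)) {
    if (is.null(dt)) {
      abort("`dt` is required (no `dt` column present)",
            class = "sptmotion_schema_error")
    }
    data$dt <- dt
  }
  if (!is.null(pixel_size)) {
    data$x <- data$x * pixel_size
    data$y <- data$y * pixel_size
  }
  data$frame <- as.integer(data$frame)
  data <- dplyr::arrange(data, .data$id, .data$frame)
  validate_tracks(data)
  data
}

validate_tracks <- function(tracks) {
  if (!all(c("id", "frame", "x", "y", "dt") %in% names(tracks))) {
    abort("not a track table: need columns id, frame, x, y, dt",
          class = "sptmotion_schema_error")
  }
  if (!all(is.finite(tracks$x)) || !all(is.finite(tracks$y))) {
    abort("all coordinates must be finite", class = "sptmotion_schema_error")
  }
  if (any(tracks$dt <= 0)) {
    abort("dt must be positive", class = "sptmotion_schema_error")
  }
  by_id <- split(seq_len(nrow(tracks)), tracks$id)
  for (idx in by_id) {
    if (length(idx) < 2) {
      abort("every trajectory needs at least 2 positions",
            class = "sptmotion_degenerate_error")
    }
    fr <- tracks$frame[idx]
    if (any(diff(fr) != 1L)) {
      abort("frames must be gap-free and strictly increasing within a trajectory",
            class = "sptmotion_schema_error")
    }
    if (length(unique(tracks$dt[idx])) != 1L) {
      abort("dt must be constant within a trajectory",
            class = "sptmotion_schema_error")
    }
  }
  invisible(tracks)
}

# Construct a single-trajectory tibble from coordinate vectors.
new_track <- function(x, y, dt, id = 1L) {
  tibble(id = id, frame = seq_along(x) - 1L, x = x, y = y, dt = dt)
}

# Split a track table into a named list of (x, y, dt, id) lists, in id order.
track_list <- function(tracks) {
  idx <- split(seq_len(nrow(tracks)), factor(tracks$id, unique(tracks$id)))
  lapply(idx, function(i) {
    list(x = tracks$x[i], y = tracks$y[i], dt = tracks$dt[i][1],
         id = tracks$id[i][1], rows = i)
  })
}

#' Empirical mean squared displacement
#'
#' Computes the time-averaged MSD of each trajectory,
#' \deqn{\langle r^2(n)\rangle = \frac{1}{N-n}\sum_{i=1}^{N-n}
#'   |x_{i+n} - x_i|^2,}
#' for the requested integer lags. The fourth displacement moment
#' \eqn{\langle r^4(n)\rangle} is returned alongside because several
#' trajectory features need it.
#'
#' @param tracks A track table (see [as_tracks()]).
#' @param lags Integer lags to evaluate; default all lags `1:(N-1)` per
#'   trajectory.
#' @return A tibble with columns `id`, `lag`, `time` (lag times `dt`), `msd`,
#'   `m4` and `n_pairs` (the `N - n` averaged displacement pairs).
#' @examples
#' tr <- as_tracks(data.frame(id = 1, frame = 0:3, x = 0:3, y = 0), dt = 1)
#' track_msd(tr)
#' @export
track_msd <- function(tracks, lags = NULL) {
  validate_tracks(tracks)
  out <- lapply(track_list(tracks), function(tr) {
    N <- length(tr$x)
    lg <- if (is.null(lags)) seq_len(N - 1L) else as.integer(lags)
    if (any(lg < 1L) || any(lg > N - 1L)) {
      abort(sprintf("lags must lie in [1, %d] for trajectory '%s'",
                    N - 1L, tr$id),
            class = "sptmotion_range_error")
    }
    mm <- msd_moments_cpp(tr$x, tr$y, max(lg))
    tibble(id = tr$id, lag = lg, time = lg * tr$dt,
           msd = mm[lg, 1], m4 = mm[lg, 2], n_pairs = as.integer(mm[lg, 3]))
  })
  dplyr::bind_rows(out)
}

#' Resample trajectories by keeping every i-th position
#'
#' Resampling enlarges the effective time lag: positions `0, i, 2i, ...` are
#' kept and the frame interval becomes `i * dt`. This trades time resolution
#' for signal-to-noise ratio, since the displacement per retained step grows
#' while the localization noise does not. `rate = 1` returns the input
#' unchanged.
#'
#' @param tracks A track table.
#' @param rate Positive integer resampling rate.
#' @return A track table with renumbered frames and `dt` multiplied by `rate`.
#' @export
resample_tracks <- function(tracks, rate) {
  validate_tracks(tracks)
  rate <- as.integer(rate)
  if (length(rate) != 1L || is.na(rate) || rate < 1L) {
    abort("`rate` must be a positive integer", class = "sptmotion_range_error")
  }
  if (rate == 1L) return(tracks)
  out <- lapply(track_list(tracks), function(tr) {
    keep <- seq(1L, length(tr$x), by = rate)
    if (length(keep) < 2L) {
      abort(sprintf(
        "resampling trajectory '%s' at rate %d leaves fewer than 2 positions",
        tr$id, rate), class = "sptmotion_degenerate_error")
    }
    rows <- tracks[tr$rows[keep], ]
    rows$frame <- seq_along(keep) - 1L
    rows$dt <- tr$dt * rate
    rows
  })
  dplyr::bind_rows(out)
}

#' Sliding-window sub-trajectories
#'
#' Slices each trajectory of `N` positions into `K = N - window + 1`
#' overlapping sub-trajectories of `window` consecutive positions. Window `k`
#' covers positions `k ... k + window - 1`; every original position is covered
#' by at least one window.
#'
#' @param tracks A track table.
#' @param window Window length in positions, between 2 and `N`.
#' @return A track table whose `id` identifies the window, with `parent_id`
#'   (source trajectory) and `start` (1-based index of the window's first
#'   position in the parent) columns.
#' @export
track_windows <- function(tracks, window) {
  validate_tracks(tracks)
  window <- as.integer(window)
  if (length(window) != 1L || is.na(window) || window < 2L) {
    abort("`window` must be an integer >= 2", class = "sptmotion_range_error")
  }
  out <- lapply(track_list(tracks), function(tr) {
    N <- length(tr$x)
    if (window > N) {
      abort(sprintf(
        "window length %d exceeds trajectory '%s' length %d",
        window, tr$id, N), class = "sptmotion_window_error")
    }
    K <- N - window + 1L
    dplyr::bind_rows(lapply(seq_len(K), function(k) {
      rows <- tracks[tr$rows[k:(k + window - 1L)], ]
      rows$parent_id <- rows$id
      rows$id <- paste0(tr$id, ".w", k)
      rows$start <- k
      rows$frame <- seq_len(window) - 1L
      rows
    }))
  })
  dplyr::bind_rows(out)
}
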