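#' Classify and segment trajectories with a sliding window
#'
#' Slices each trajectory into `K = N - window + 1` overlapping windows,
#' optionally resamples each window (keeping every `resample`-th position,
#' which enlarges the effective time lag and improves the signal-to-noise
#' ratio), computes the nine features per window and classifies it with the
#' forest. Every original position covered by a window - including positions
#' skipped by resampling - receives a vote for the window's class, weighted
#' by the window's vote fraction `p_c`. Per position the class with the
#' largest total vote weight wins (ties go to the earlier class in the fixed
#' order directed, anomalous, confined, normal, and are reported); the
#' position confidence is the mean weight of the votes for the winning
#' class. Runs of equal-class positions are merged into segments whose
#' confidence is the mean of their position confidences, and each segment's
#' class-specific MSD model is fitted ([fit_msd_model()]).
#'
#' Trajectories shorter than `min_track_length` are skipped with a warning;
#' a trajectory at least that long but shorter than `window` is an error.
#' The resampled window must keep at least 30 positions
#' (`ceiling(window / resample) >= 30`) so that the features stay stable.
#'
#' @param tracks A track table.
#' @param clf A `motion_classifier`.
#' @param window Window length in positions (default 90).
#' @param resample Integer resampling rate applied inside each window
#'   (default 1, no resampling).
#' @param min_track_length Trajectories shorter than this are skipped
#'   (default: the window length).
#' @param fit_models Fit the class-specific MSD model of each segment
#'   (segments shorter than 10 positions, or failing fits, get `NA`
#'   parameters).
#' @return An object of class `motion_segmentation`: a list with
#'   `positions` (tibble: `id`, `frame`, `x`, `y`, `index`, `class`,
#'   `confidence`), `segments` (tibble: `id`, `segment`, `start`, `end`,
#'   `n`, `class`, `confidence` and fitted parameters `D`, `alpha`, `v`,
#'   `r_c`, `A1`, `A2`), the settings used, and `skipped` ids. `tidy()`
#'   returns the segment table; `autoplot()` draws the labelled paths.
#' @export
classify_tracks <- function(tracks, clf, window = 90, resample = 1,
                            min_track_length = window, fit_models = TRUE) {
  validate_tracks(tracks)
  stopifnot(inherits(clf, "motion_classifier"))
  window <- as.integer(window)
  resample <- as.integer(resample)
  if (resample < 1) abort("`resample` must be >= 1",
                          class = "sptmotion_range_error")
  if (ceiling(window / resample) < 30) {
    abort("resampled window would keep fewer than 30 positions",
          class = "sptmotion_config_error")
  }
  classes <- clf$classes
  skipped <- character(0)
  pos_parts <- list()
  seg_parts <- list()
  for (tr in track_list(tracks)) {
    N <- length(tr$x)
    if (N < min_track_length) {
      skipped <- c(skipped, as.character(tr$id))
      next
    }
    if (window > N) {
      abort(sprintf("window length %d exceeds trajectory '%s' length %d",
                    window, tr$id, N), class = "sptmotion_window_error")
    }
    K <- N - window + 1L
    keep <- seq(1L, window, by = resample)
    feat <- matrix(NA_real_, K, length(clf$feature_names),
                   dimnames = list(NULL, clf$feature_names))
    for (k in seq_len(K)) {
      sub <- k:(k + window - 1L)
      f <- features_xy(tr$x[sub][keep], tr$y[sub][keep], tr$dt * resample)
      feat[k, ] <- unlist(f[clf$feature_names])
    }
    usable <- stats::complete.cases(feat)
    if (!any(usable)) {
      warn(sprintf("trajectory '%s': no classifiable windows, skipped", tr$id))
      skipped <- c(skipped, as.character(tr$id))
      next
    }
    if (!all(usable)) {
      warn(sprintf("trajectory '%s': %d windows with degenerate features ignored",
                   tr$id, sum(!usable)))
    }
    votes <- predict(clf$forest, feat[usable, , drop = FALSE],
                     type = "vote", norm.votes = TRUE)
    win_class <- max.col(votes, ties.method = "first")
    win_p <- votes[cbind(seq_len(nrow(votes)), win_class)]
    starts <- which(usable)
    # accumulate weights and counts per position x class with a
    # difference-array: each window adds p_c over its index span
    W <- matrix(0, N, length(classes))
    C <- matrix(0, N, length(classes))
    for (j in seq_along(classes)) {
      sel <- win_class == j
      if (!any(sel)) next
      dW <- numeric(N + 1L)
      dC <- numeric(N + 1L)
      s <- starts[sel]
      p <- win_p[sel]
      for (q in seq_along(s)) {
        dW[s[q]] <- dW[s[q]] + p[q]
        dW[s[q] + window] <- dW[s[q] + window] - p[q]
        dC[s[q]] <- dC[s[q]] + 1
        dC[s[q] + window] <- dC[s[q] + window] - 1
      }
      W[, j] <- cumsum(dW[seq_len(N)])
      C[, j] <- cumsum(dC[seq_len(N)])
    }
    covered <- rowSums(C) > 0
    winner <- max.col(W, ties.method = "first")
    tie <- rowSums(W == W[cbind(seq_len(N), winner)]) > 1
    if (any(tie & covered)) {
      inform(sprintf("trajectory '%s': %d positions with tied votes resolved by class order",
                     tr$id, sum(tie & covered)))
    }
    conf <- ifelse(covered,
                   W[cbind(seq_len(N), winner)] /
                     pmax(C[cbind(seq_len(N), winner)], 1), NA_real_)
    cls <- ifelse(covered, classes[winner], NA_character_)
    pos_parts[[length(pos_parts) + 1L]] <-
      tibble(id = tr$id, frame = tracks$frame[tr$rows],
             x = tr$x, y = tr$y, dt = tr$dt, index = seq_len(N),
             class = factor(cls, levels = classes), confidence = conf)
    # merge runs of equal class into segments
    r <- rle(as.integer(factor(cls, levels = classes)))
    ends <- cumsum(r$lengths)
    starts_seg <- ends - r$lengths + 1L
    segs <- tibble(id = tr$id, segment = seq_along(r$values),
                   start = starts_seg, end = ends, n = r$lengths,
                   class = factor(classes[r$values], levels = classes),
                   confidence = vapply(seq_along(r$values), function(s)
                     mean(conf[starts_seg[s]:ends[s]]), numeric(1)))
    if (fit_models) {
      fits <- lapply(seq_len(nrow(segs)), function(s) {
        idx <- segs$start[s]:segs$end[s]
        fit_segment_model(tr$x[idx], tr$y[idx], tr$dt,
                          as.character(segs$class[s]))
      })
      segs <- dplyr::bind_cols(segs, dplyr::bind_rows(fits))
    }
    seg_parts[[length(seg_parts) + 1L]] <- segs
  }
  if (length(skipped) > 0) {
    warn(sprintf("%d trajectories shorter than min_track_length (%d) skipped: %s",
                 length(skipped), min_track_length,
                 paste(head(skipped, 5), collapse = ", ")))
  }
  structure(list(positions = dplyr::bind_rows(pos_parts),
                 segments = dplyr::bind_rows(seg_parts),
                 window = window, resample = resample,
                 min_track_length = min_track_length,
                 classes = classes, skipped = skipped),
            class = "motion_segmentation")
}

# Fit the MSD model matching a segment's class; NA parameters when the
# segment is too short or the fit fails.
fit_segment_model <- function(x, y, dt, class) {
  out <- tibble(D = NA_real_, alpha = NA_real_, v = NA_real_,
                r_c = NA_real_, A1 = NA_real_, A2 = NA_real_)
  if (length(x) < 10) return(out)
  fit <- tryCatch(
    suppressWarnings(fit_msd_model(new_track(x, y, dt),
                                   class_to_model(class))),
    error = function(e) NULL)
  if (is.null(fit)) return(out)
  for (p in names(fit$params)) out[[p]] <- fit$params[[p]]
  out
}

#' @export
print.motion_segmentation <- function(x, ...) {
  cat("<motion_segmentation>", length(unique(x$positions$id)),
      "trajectories,", nrow(x$segments), "segments\n")
  cat("  window =", x$window, ", resample =", x$resample, "\n")
  print(dplyr::count(x$segments, .data$class, .drop = FALSE))
  invisible(x)
}

#' @describeIn classify_tracks The segment table.
#' @param x A `motion_segmentation` object.
#' @param ... Unused.
#' @method tidy motion_segmentation
#' @export
tidy.motion_segmentation <- function(x, ...) x$segments

#' @describeIn classify_tracks One row per trajectory: number of segments,
#'   dominant class and mean confidence.
#' @method glance motion_segmentation
#' @export
glance.motion_segmentation <- function(x, ...) {
  x$segments |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      n_segments = dplyr::n(),
      n_positions = sum(.data$n),
      dominant_class = factor(names(which.max(tapply(.data$n, .data$class, sum))),
                              levels = levels(.data$class)),
      confidence = stats::weighted.mean(.data$confidence, .data$n),
      .groups = "drop")
}

#' Motion-class histogram of classified positions
#'
#' Proportion of classified positions per motion class, used to compare
#' classification outcomes across resampling rates.
#'
#' @param x A `motion_segmentation` or its `positions` tibble.
#' @return A named numeric vector of proportions over the four classes
#'   (summing to 1 when any position is classified).
#' @export
class_histogram <- function(x) {
  pos <- if (inherits(x, "motion_segmentation")) x$positions else x
  cls <- pos$class[!is.na(pos$class)]
  tab <- table(factor(cls, levels = levels(pos$class)))
  as.vector(tab / max(sum(tab), 1)) |> setNames(names(tab))
}

#' Distance between two motion-class histograms
#'
#' Mean absolute difference of the class proportions,
#' \eqn{\Delta H = \sum_k |H_a(c_k) - H_b(c_k)| / N_c} with \eqn{N_c} the
#' number of classes.
#'
#' @param h_a,h_b Named proportion vectors over the same classes (see
#'   [class_histogram()]).
#' @return The scalar distance.
#' @export
histogram_distance <- function(h_a, h_b) {
  if (!setequal(names(h_a), names(h_b)) || is.null(names(h_a))) {
    abort("histograms must cover the same named classes",
          class = "sptmotion_schema_error")
  }
  sum(abs(h_a - h_b[names(h_a)])) / length(h_a)
}

#' Choose a resampling rate for a trajectory corpus
#'
#' Classifies the corpus at resampling rates `1 ... max_rate + 1` with a wide
#' window (default 120), pools the position-class histogram per rate, and
#' computes the histogram distance between successive rates. Once the
#' signal-to-noise ratio stops limiting the classification, raising the rate
#' no longer changes the class mixture, so the rate with the smallest
#' successive distance (ties toward the smallest rate) is selected.
#'
#' @param tracks A track table.
#' @param clf A `motion_classifier`.
#' @param window Window length used during rate selection.
#' @param max_rate Largest candidate rate.
#' @param min_track_length Passed to [classify_tracks()].
#' @return A list with `rate` (the selected rate) and `delta_h` (a tibble
#'   with columns `rate` and `delta_h`).
#' @export
choose_resampling_rate <- function(tracks, clf, window = 120, max_rate = 3,
                                   min_track_length = window) {
  if (max_rate < 1) abort("`max_rate` must be >= 1",
                          class = "sptmotion_range_error")
  if (ceiling(window / (max_rate + 1)) < 30) {
    abort(sprintf("window %d cannot support resampling rates up to %d",
                  window, max_rate + 1), class = "sptmotion_config_error")
  }
  hists <- lapply(seq_len(max_rate + 1L), function(i) {
    seg <- classify_tracks(tracks, clf, window = window, resample = i,
                           min_track_length = min_track_length,
                           fit_models = FALSE)
    if (nrow(seg$positions) == 0) {
      abort("no trajectory is long enough for rate selection",
            class = "sptmotion_degenerate_error")
    }
    class_histogram(seg)
  })
  dh <- vapply(seq_len(max_rate), function(i)
    histogram_distance(hists[[i]], hists[[i + 1L]]), numeric(1))
  list(rate = which.min(dh),
       delta_h = tibble(rate = seq_len(max_rate), delta_h = dh))
}
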