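#' Read and write trajectory CSV files
#'
#' The CSV dialect has one row per position with columns `trajectory_id`,
#' `frame`, `x_um`, `y_um`, `dt` and optionally `true_class`; extra columns
#' are preserved untouched. `read_tracks_csv()` validates the table with
#' [as_tracks()].
#'
#' @param path File path.
#' @param dt Frame interval in seconds, required when the file has no `dt`
#'   column.
#' @param pixel_size Optional pixel size (um/pixel) applied to coordinates.
#' @return `read_tracks_csv()` returns a track table;
#'   `write_tracks_csv()` returns `path` invisibly.
#' @export
read_tracks_csv <- function(path, dt = NULL, pixel_size = NULL) {
  if (!file.exists(path) || file.size(path) == 0) {
    abort(paste0("empty or missing trajectory file: ", path),
          class = "sptmotion_schema_error")
  }
  data <- readr::read_csv(path, show_col_types = FALSE)
  if (nrow(data) == 0) {
    abort("trajectory file has no rows", class = "sptmotion_schema_error")
  }
  tracks <- as_tracks(data, dt = dt, pixel_size = pixel_size)
  if ("true_class" %in% names(tracks)) {
    tracks$true_class <- factor(tracks$true_class, levels = motion_classes())
  }
  tracks
}

#' @param tracks A track table.
#' @rdname read_tracks_csv
#' @export
write_tracks_csv <- function(tracks, path) {
  validate_tracks(tracks)
  out <- tracks
  names(out)[match(c("id", "x", "y"), names(out))] <-
    c("trajectory_id", "x_um", "y_um")
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a TrackMate XML trajectory export
#'
#' Parses the TrackMate "tracks" XML dialect (root `<Tracks>` with one
#' `<particle>` element per trajectory and one `<detection t=".." x=".."
#' y=".."/>` per position). Coordinates are taken as micrometres unless a
#' `pixel_size` is given; the frame interval comes from the file's
#' `frameInterval` attribute unless overridden.
#'
#' @param path Path to the XML file.
#' @param dt Frame interval in seconds (overrides the file attribute).
#' @param pixel_size Optional pixel size in um/pixel.
#' @param gap_action What to do with tracks whose frames are not gap-free:
#'   `"error"` (default), `"skip"` (drop the track with a warning) or
#'   `"split"` (split it into gap-free pieces `<id>.1`, `<id>.2`, ...).
#' @return A track table.
#' @export
read_trackmate_xml <- function(path, dt = NULL, pixel_size = NULL,
                               gap_action = c("error", "skip", "split")) {
  gap_action <- match.arg(gap_action)
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    abort(paste0("cannot parse XML: ", conditionMessage(e)),
          class = "sptmotion_parse_error")
  })
  root <- xml2::xml_name(doc)
  if (!identical(root, "Tracks")) {
    abort(sprintf(
      "unsupported XML root '%s' (expected a TrackMate <Tracks> export)",
      root), class = "sptmotion_parse_error")
  }
  if (is.null(dt)) {
    fi <- xml2::xml_attr(doc, "frameInterval")
    if (is.na(fi)) {
      abort("no frameInterval attribute in file; supply `dt`",
            class = "sptmotion_schema_error")
    }
    dt <- as.numeric(fi)
  }
  particles <- xml2::xml_find_all(doc, "./particle")
  if (length(particles) == 0) {
    abort("no <particle> tracks found", class = "sptmotion_parse_error")
  }
  parts <- list()
  for (i in seq_along(particles)) {
    det <- xml2::xml_find_all(particles[[i]], "./detection")
    tb <- tibble(
      id = as.character(i),
      frame = as.integer(round(as.numeric(xml2::xml_attr(det, "t")))),
      x = as.numeric(xml2::xml_attr(det, "x")),
      y = as.numeric(xml2::xml_attr(det, "y")))
    tb <- dplyr::arrange(tb, .data$frame)
    gaps <- which(diff(tb$frame) != 1L)
    if (length(gaps) > 0) {
      if (gap_action == "error") {
        abort(sprintf("track %d has frame gaps (use gap_action)", i),
              class = "sptmotion_parse_error")
      } else if (gap_action == "skip") {
        warn(sprintf("track %d has frame gaps, skipped", i))
        next
      } else {
        piece <- cumsum(c(1L, as.integer(diff(tb$frame) != 1L)))
        tb$id <- paste0(tb$id, ".", piece)
        tb <- tb[tb$id %in% names(which(table(tb$id) >= 2)), ]
        if (nrow(tb) == 0) next
        tb <- dplyr::group_by(tb, .data$id) |>
          dplyr::mutate(frame = .data$frame - min(.data$frame)) |>
          dplyr::ungroup()
      }
    }
    parts[[length(parts) + 1L]] <- tb
  }
  if (length(parts) == 0) {
    abort("no usable tracks after gap handling", class = "sptmotion_parse_error")
  }
  as_tracks(dplyr::bind_rows(parts), dt = dt, pixel_size = pixel_size)
}

#' Write a TrackMate-style XML export
#'
#' Writes tracks in the `<Tracks>/<particle>/<detection>` dialect read by
#' [read_trackmate_xml()]; mainly used to build small example files.
#'
#' @param tracks A track table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trackmate_xml <- function(tracks, path) {
  validate_tracks(tracks)
  doc <- xml2::xml_new_root("Tracks",
                            nTracks = as.character(length(unique(tracks$id))),
                            frameInterval = format(tracks$dt[1], digits = 10),
                            spaceUnits = "micron", timeUnits = "sec")
  for (tr in track_list(tracks)) {
    p <- xml2::xml_add_child(doc, "particle",
                             nSpots = as.character(length(tr$x)))
    fr <- tracks$frame[tr$rows]
    for (i in seq_along(tr$x)) {
      xml2::xml_add_child(p, "detection", t = as.character(fr[i]),
                          x = format(tr$x[i], digits = 10),
                          y = format(tr$y[i], digits = 10), z = "0")
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Write the five segment report tables
#'
#' Writes one CSV per motion type - each row a segment of that type with its
#' parent and segment identifiers, index span, confidence, the nine features
#' of the segment sub-trajectory (when it has at least 30 positions) and the
#' fitted MSD-model parameters - plus a fifth summary table with one row per
#' parent trajectory.
#'
#' @param segmentation A `motion_segmentation` from [classify_tracks()].
#' @param dir Output directory (created when missing).
#' @param prefix File-name prefix.
#' @return Named character vector of the five file paths, invisibly.
#' @export
write_motion_reports <- function(segmentation, dir, prefix = "motion") {
  stopifnot(inherits(segmentation, "motion_segmentation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  segs <- segmentation$segments
  pos <- segmentation$positions
  na_feats <- tibble(!!!setNames(as.list(rep(NA_real_, 9)), feature_names()))
  feat_rows <- lapply(seq_len(nrow(segs)), function(s) {
    idx <- pos$id == segs$id[s] &
      pos$index >= segs$start[s] & pos$index <= segs$end[s]
    if (sum(idx) >= 30) {
      features_xy(pos$x[idx], pos$y[idx], pos$dt[idx][1])
    } else {
      na_feats
    }
  })
  segs <- dplyr::bind_cols(
    tibble(segment_uid = paste0(segs$id, ".s", segs$segment),
           parent_id = segs$id),
    segs[setdiff(names(segs), "id")],
    dplyr::bind_rows(feat_rows))
  paths <- character(0)
  for (cl in segmentation$classes) {
    p <- file.path(dir, paste0(prefix, "_", cl, ".csv"))
    readr::write_csv(segs[!is.na(segs$class) & segs$class == cl, ], p)
    paths[cl] <- p
  }
  summary_tab <- glance(segmentation)
  p <- file.path(dir, paste0(prefix, "_trajectories.csv"))
  readr::write_csv(summary_tab, p)
  paths["trajectories"] <- p
  invisible(paths)
}

#' Generate small bundled example datasets
#'
#' Writes deterministic toy datasets used in tests and documentation: one
#' short trajectory per motion type (CSV with a `true_class` column), a
#' switching trajectory (normal diffusion followed by directed motion) with
#' its ground-truth boundary, and a small TrackMate-style XML file.
#'
#' @param dir Output directory.
#' @param seed Integer seed; identical seeds give identical files.
#' @return Named list of the file paths, invisibly.
#' @export
make_fixtures <- function(dir, seed = 42) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  withr::with_seed(seed, {
    classes <- dplyr::bind_rows(
      dplyr::mutate(simulate_nd(120, id = "nd"), true_class = "normal"),
      dplyr::mutate(simulate_ad(120, alpha = 0.5, id = "ad"),
                    true_class = "anomalous"),
      dplyr::mutate(simulate_cd(120, B = 4, id = "cd"),
                    true_class = "confined"),
      dplyr::mutate(simulate_dm(120, R = 10, id = "dm"),
                    true_class = "directed"))
    p_classes <- file.path(dir, "motion_types.csv")
    write_tracks_csv(classes, p_classes)

    nd <- simulate_nd(150, id = "switch")
    dm <- simulate_dm(150, R = 15, id = "switch")
    sw <- new_track(c(nd$x, nd$x[151] + dm$x[-1]),
                    c(nd$y, nd$y[151] + dm$y[-1]), 1 / 30, "switch")
    p_switch <- file.path(dir, "switching.csv")
    write_tracks_csv(sw, p_switch)
    p_truth <- file.path(dir, "switching_truth.csv")
    readr::write_csv(tibble(id = "switch", boundary_index = 151,
                            class_before = "normal", class_after = "directed"),
                     p_truth)

    p_xml <- file.path(dir, "tracks_sample.xml")
    write_trackmate_xml(simulate_nd(40, id = "xml1"), p_xml)
    invisible(list(motion_types = p_classes, switching = p_switch,
                   switching_truth = p_truth, trackmate = p_xml))
  })
}
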