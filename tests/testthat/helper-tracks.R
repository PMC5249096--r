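# Builders and shared fixtures for the test suite. Everything is generated
# in code under fixed seeds; no data files are shipped.

straight_track <- function(n = 31, step = 1, dt = 1, id = "line") {
  new_tracks_df(x = step * (0:(n - 1)), y = rep(0, n), dt = dt, id = id)
}

new_tracks_df <- function(x, y, dt = 1, id = "t") {
  tibble::tibble(id = id, frame = seq_along(x) - 1L, x = x, y = y, dt = dt)
}

random_track <- function(n = 50, dt = 1, id = "rnd", scale = 1) {
  new_tracks_df(x = cumsum(stats::rnorm(n, 0, scale)),
                y = cumsum(stats::rnorm(n, 0, scale)), dt = dt, id = id)
}

# Brute-force MSD oracle: literal double loop over displacement pairs.
msd_brute <- function(x, y, n) {
  N <- length(x)
  s <- 0
  for (i in 1:(N - n)) {
    s <- s + (x[i + n] - x[i])^2 + (y[i + n] - y[i])^2
  }
  s / (N - n)
}

# A small but usable classifier shared across tests (trained once per run).
.test_env <- new.env(parent = emptyenv())

small_classifier <- function() {
  if (is.null(.test_env$clf)) {
    feats <- suppressWarnings(
      track_features(simulate_training_set(400, seed = 7101)))
    .test_env$clf <- train_motion_classifier(feats, ntree = 200, seed = 7102)
  }
  .test_env$clf
}

# Concatenate two single-track tables into one trajectory (motion switch).
concat_tracks <- function(a, b, id = "switch") {
  offx <- a$x[nrow(a)]
  offy <- a$y[nrow(a)]
  new_tracks_df(x = c(a$x, offx + b$x[-1]), y = c(a$y, offy + b$y[-1]),
                dt = a$dt[1], id = id)
}
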