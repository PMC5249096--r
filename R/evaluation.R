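#' Classification sensitivity over a parameter grid
#'
#' Measures the fraction of simulated trajectories of one motion class that
#' the classifier labels correctly, over a grid of simulation conditions.
#' Every supplied axis (`snr`, the class parameter, `window`) may be a
#' vector; the grid is their crossing. Trajectory lengths are drawn
#' uniformly from `steps` for every replicate. Without a window the whole
#' trajectory is classified once; with a window, [classify_tracks()] labels
#' every position and the sensitivity is the fraction of correctly labelled
#' positions.
#'
#' @param clf A `motion_classifier`.
#' @param class Motion class to probe: `"directed"`, `"anomalous"`,
#'   `"confined"` or `"normal"`.
#' @param snr Signal-to-noise ratio axis.
#' @param param Class-parameter axis: the directed-motion ratio R
#'   (directed), anomalous exponent (anomalous) or boundedness (confined);
#'   ignored for normal diffusion.
#' @param window Optional window-length axis; `NA` entries (and the default)
#'   classify full trajectories.
#' @param n_reps Simulated trajectories per grid cell.
#' @param steps Range of steps per trajectory (drawn uniformly).
#' @param D,dt Diffusion coefficient and frame interval of the simulations.
#' @param seed Optional integer seed.
#' @return A tibble of class `motion_sensitivity` with one row per grid
#'   cell: `class`, `snr`, `param`, `window`, `sensitivity`, `n`.
#' @export
sensitivity_grid <- function(clf, class = c("directed", "anomalous",
                                            "confined", "normal"),
                             snr = c(1, 3, 5, 7, 9), param = NULL,
                             window = NA, n_reps = 200,
                             steps = c(30L, 600L), D = 9.02, dt = 1 / 30,
                             seed = NULL) {
  class <- match.arg(class)
  stopifnot(inherits(clf, "motion_classifier"))
  if (is.null(param)) {
    param <- switch(class, directed = 9, anomalous = 0.5, confined = 3,
                    normal = NA_real_)
  }
  grid <- tidyr::expand_grid(snr = snr, param = param, window = window)
  with_seed_if(seed, {
    grid$sensitivity <- NA_real_
    grid$n <- NA_integer_
    for (g in seq_len(nrow(grid))) {
      w <- grid$window[g]
      lo <- if (is.na(w)) steps[1] else max(steps[1], w)
      n_steps <- sample(seq(lo, max(steps[2], lo)), n_reps, replace = TRUE)
      sims <- vector("list", n_reps)
      for (j in seq_len(n_reps)) {
        tr <- switch(class,
          directed  = simulate_dm(n_steps[j], R = grid$param[g], D = D,
                                  dt = dt, id = j),
          anomalous = simulate_ad(n_steps[j], alpha = grid$param[g], D = D,
                                  dt = dt, id = j),
          confined  = simulate_cd(n_steps[j], B = grid$param[g], D = D,
                                  dt = dt, id = j),
          normal    = simulate_nd(n_steps[j], D = D, dt = dt, id = j))
        v <- if (class == "directed") {
          velocity_from_ratio(grid$param[g], D, n_steps[j] * dt)
        } else NULL
        sims[[j]] <- add_localization_noise(
          tr, sigma_from_snr(grid$snr[g], D, dt, v))
      }
      tracks <- dplyr::bind_rows(sims)
      if (is.na(w)) {
        pred <- predict(clf, suppressWarnings(track_features(tracks)))
        ok <- !is.na(pred$class)
        grid$sensitivity[g] <- mean(pred$class[ok] == class)
        grid$n[g] <- sum(ok)
      } else {
        seg <- suppressWarnings(classify_tracks(tracks, clf, window = w,
                                                fit_models = FALSE))
        lab <- seg$positions$class
        grid$sensitivity[g] <- mean(lab[!is.na(lab)] == class)
        grid$n[g] <- sum(!is.na(lab))
      }
    }
    out <- dplyr::bind_cols(tibble(class = class), grid)
    class(out) <- c("motion_sensitivity", class(out))
    out
  })
}

#' Anomalous-exponent distribution of pure localization noise
#'
#' Immobile particles observed with localization noise produce trajectories
#' whose coordinates are independent Gaussian draws; their flat MSD yields
#' small fitted anomalous exponents. This Monte-Carlo helper simulates such
#' pure-noise trajectories (i.i.d. standard normal coordinates, unit frame
#' interval - the exponent is scale-free) and returns percentiles of the
#' fitted exponent, a reference threshold for flagging apparent anomalous
#' diffusion that is in fact noise.
#'
#' @param n_positions Positions per trajectory.
#' @param n_reps Number of simulated trajectories (>= 1000 recommended).
#' @param probs Percentile(s) to report.
#' @param seed Optional integer seed.
#' @return A tibble with columns `prob` and `alpha`.
#' @export
noise_alpha_percentile <- function(n_positions = 60, n_reps = 10000,
                                   probs = 0.95, seed = NULL) {
  if (n_reps < 2) abort("`n_reps` must be >= 2", class = "sptmotion_config_error")
  with_seed_if(seed, {
    n3 <- max(2L, floor(n_positions / 3))
    lt <- log(seq_len(n3))
    a <- vapply(seq_len(n_reps), function(i) {
      msd <- msd_moments_cpp(rnorm(n_positions), rnorm(n_positions), n3)[, 1]
      ols_slope(lt, log(msd))
    }, numeric(1))
    tibble(prob = probs, alpha = unname(quantile(a, probs)))
  })
}
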