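#' Trajectory features for motion-type classification
#'
#' Computes the nine dimensionless features that feed the random-forest
#' classifier, one row per trajectory:
#'
#' * `alpha` - exponent of the anomalous-diffusion MSD model, from a
#'   log-log straight-line fit of the empirical MSD over lags
#'   `1 ... floor(N/3)`; near 1 for normal diffusion, above 1 for directed
#'   motion, below 1 for anomalous and confined diffusion.
#' * `asymmetry` - `-log(1 - (l1 - l2)^2 / (2 (l1 + l2)^2))` from the
#'   eigenvalues `l1 >= l2` of the radius-of-gyration tensor; 0 for
#'   rotationally symmetric clouds, `log 2` for collinear tracks.
#' * `efficiency` - squared net displacement over `(N-1)` times the sum of
#'   squared step lengths; 1 for a straight equal-step line.
#' * `fractal_dimension` - the Katz-George path dimension
#'   `log(N) / log(N d / L)` with `N` steps, total path length `L` and
#'   largest pairwise distance `d`; near 1 for straight, 2 for random and 3
#'   for constrained paths.
#' * `gaussianity` - `<r^4(n)> / (2 <r^2(n)>^2) - 1` averaged over lags
#'   `1 ... floor(N/3)`; 0 in expectation for Gaussian (normal-diffusion)
#'   increments.
#' * `kurtosis` - fourth standardized moment of the positions projected on
#'   the dominant eigenvector of the gyration tensor.
#' * `msd_ratio` - `<r^2(n1)>/<r^2(n2)> - n1/n2` with `n1 = 1`,
#'   `n2 = min(10, N - 1)`; 0 for a linear MSD, positive for sub-linear
#'   (anomalous/confined), negative for super-linear (directed) curves. A
#'   short fixed second lag keeps the ratio in the well-averaged part of the
#'   MSD curve for every trajectory length.
#' * `straightness` - net displacement over the sum of step lengths, in
#'   `[0, 1]`.
#' * `trappedness` - the probability
#'   `1 - exp(0.2048 - 0.25117 D t / r0^2)` that a particle with short-time
#'   diffusion coefficient `D` (from the first two MSD lags) stays within a
#'   disc of radius `r0` (half the largest pairwise distance) for the
#'   trajectory duration `t`, clamped to `[0, 1]`.
#'
#' Trajectories should have at least 30 positions for stable estimates.
#' Degenerate inputs (for example all positions identical) yield `NA` in the
#' affected features with a warning.
#'
#' @param tracks A track table (see [as_tracks()]); a `true_class` column, if
#'   present, is carried through.
#' @return A tibble with one row per trajectory: `id`, the nine feature
#'   columns above and optionally `true_class`.
#' @examples
#' set.seed(1)
#' track_features(simulate_nd(100))
#' @export
track_features <- function(tracks) {
  validate_tracks(tracks)
  trs <- track_list(tracks)
  rows <- lapply(trs, function(tr) features_xy(tr$x, tr$y, tr$dt))
  out <- tibble(id = unlist(lapply(trs, `[[`, "id"), use.names = FALSE))
  out <- dplyr::bind_cols(out, dplyr::bind_rows(rows))
  if ("true_class" %in% names(tracks)) {
    cls <- vapply(trs, function(tr) as.character(tracks$true_class[tr$rows[1]]),
                  character(1))
    out$true_class <- factor(cls, levels = motion_classes())
  }
  n_bad <- sum(!stats::complete.cases(out[feature_names()]))
  if (n_bad > 0) {
    warn(sprintf("%d trajectories produced degenerate (NA) features", n_bad))
  }
  out
}

feature_names <- function() {
  c("alpha", "asymmetry", "efficiency", "fractal_dimension", "gaussianity",
    "kurtosis", "msd_ratio", "straightness", "trappedness")
}

# All nine features for one coordinate pair. Returns a one-row tibble.
features_xy <- function(x, y, dt) {
  N <- length(x)
  max_lag <- min(N - 1L, max(10L, floor(N / 2)))
  mm <- msd_moments_cpp(x, y, max_lag)
  msd <- mm[, 1]
  m4 <- mm[, 2]
  n3 <- min(max(2L, floor(N / 3)), max_lag)

  # log-log MSD fit over short lags
  alpha <- NA_real_
  gaussianity <- NA_real_
  if (all(msd[1:n3] > 0)) {
    alpha <- ols_slope(log((1:n3) * dt), log(msd[1:n3]))
    gaussianity <- mean(m4[1:n3] / (2 * msd[1:n3]^2) - 1)
  }

  # gyration tensor (population covariance of the positions)
  cxx <- mean(x^2) - mean(x)^2
  cyy <- mean(y^2) - mean(y)^2
  cxy <- mean(x * y) - mean(x) * mean(y)
  tr2 <- cxx + cyy
  disc <- sqrt(max((cxx - cyy)^2 + 4 * cxy^2, 0))
  l1 <- (tr2 + disc) / 2
  l2 <- (tr2 - disc) / 2
  asymmetry <- if (tr2 > 0) -log(1 - (l1 - l2)^2 / (2 * (l1 + l2)^2)) else NA_real_

  # steps and net displacement
  dx <- diff(x)
  dy <- diff(y)
  step2 <- dx^2 + dy^2
  steplen <- sqrt(step2)
  L <- sum(steplen)
  net2 <- (x[N] - x[1])^2 + (y[N] - y[1])^2
  efficiency <- if (sum(step2) > 0) net2 / ((N - 1) * sum(step2)) else NA_real_
  straightness <- if (L > 0) sqrt(net2) / L else NA_real_

  # largest pairwise distance via the convex hull (the diameter is attained
  # at hull vertices)
  d <- max_pairwise_distance(x, y)
  n_steps <- N - 1
  fractal_dimension <- if (d > 0 && L > 0 && abs(log(n_steps * d / L)) > 0) {
    log(n_steps) / log(n_steps * d / L)
  } else NA_real_

  # kurtosis of positions projected on the dominant eigenvector
  kurtosis <- NA_real_
  if (l1 > 0) {
    ev <- if (abs(cxy) > 0) c(cxy, l1 - cxx) else if (cxx >= cyy) c(1, 0) else c(0, 1)
    ev <- ev / sqrt(sum(ev^2))
    p <- x * ev[1] + y * ev[2]
    vp <- mean(p^2) - mean(p)^2
    if (vp > 0) kurtosis <- mean((p - mean(p))^4) / vp^2
  }

  n2 <- min(10L, max_lag)
  msd_ratio <- if (msd[n2] > 0) msd[1] / msd[n2] - 1 / n2 else NA_real_

  trappedness <- NA_real_
  if (d > 0) {
    D_short <- ((msd[2] - msd[1]) / dt) / 4
    trappedness <- trappedness_raw(D_short, (N - 1) * dt, d / 2)
  }

  tibble(alpha = unname(alpha), asymmetry = asymmetry,
         efficiency = efficiency, fractal_dimension = fractal_dimension,
         gaussianity = gaussianity, kurtosis = kurtosis,
         msd_ratio = msd_ratio, straightness = straightness,
         trappedness = trappedness)
}

# Trapping probability, clamped to [0, 1]; crosses zero at
# D t / r0^2 = 0.2048 / 0.25117.
trappedness_raw <- function(D, t, r0) {
  p <- 1 - exp(0.2048 - 0.25117 * (D * t / r0^2))
  min(max(p, 0), 1)
}

ols_slope <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * (y - mean(y))) / sum(xc^2)
}

max_pairwise_distance <- function(x, y) {
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 2) return(0)
  if (nrow(pts) > 3) {
    h <- tryCatch(grDevices::chull(pts[, 1], pts[, 2]), error = function(e) NULL)
    if (!is.null(h) && length(h) >= 2) pts <- pts[h, , drop = FALSE]
  }
  max(stats::dist(pts))
}

#' Fitted anomalous exponent of a trajectory
#'
#' Straight-line fit of `log <r^2(n)>` against `log(n dt)` over lags
#' `1 ... floor(N/3)`, the `alpha` entry of [track_features()] exposed on its
#' own (it doubles as an MSD-shape diagnostic, for example on pure-noise
#' trajectories).
#'
#' @param tracks A track table.
#' @return A tibble with columns `id` and `alpha`.
#' @export
fit_alpha <- function(tracks) {
  validate_tracks(tracks)
  out <- lapply(track_list(tracks), function(tr) {
    N <- length(tr$x)
    n3 <- max(2L, floor(N / 3))
    msd <- msd_moments_cpp(tr$x, tr$y, n3)[, 1]
    if (any(msd == 0)) {
      abort(sprintf("trajectory '%s' has zero MSD at a fitted lag", tr$id),
            class = "sptmotion_degenerate_error")
    }
    tibble(id = tr$id, alpha = ols_slope(log((1:n3) * tr$dt), log(msd)))
  })
  dplyr::bind_rows(out)
}
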