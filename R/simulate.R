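#' Simulate normal diffusion
#'
#' A 2-D random walk: each step has a uniform random direction and a step
#' length drawn from the Rayleigh step-length density with
#' \eqn{E[u^2] = 4 D \Delta t}, sampled by inverse transform
#' \eqn{u = \sqrt{-4 D \Delta t \ln U}}.
#'
#' @param n_steps Number of steps; the trajectory has `n_steps + 1` positions.
#' @param D Diffusion coefficient in um^2/s.
#' @param dt Frame interval in seconds.
#' @param id Trajectory identifier.
#' @return A track table with one trajectory starting at the origin.
#' @examples
#' set.seed(1)
#' tr <- simulate_nd(100, D = 9.02, dt = 1 / 30)
#' track_msd(tr, lags = 1)
#' @export
simulate_nd <- function(n_steps, D = 9.02, dt = 1 / 30, id = 1L) {
  check_sim_args(n_steps, D, dt)
  st <- nd_displacements(n_steps, D, dt)
  new_track(c(0, cumsum(st$dx)), c(0, cumsum(st$dy)), dt, id)
}

nd_displacements <- function(n_steps, D, dt) {
  u <- sqrt(-4 * D * dt * log(runif(n_steps)))
  th <- runif(n_steps, 0, 2 * pi)
  list(dx = u * cos(th), dy = u * sin(th))
}

check_sim_args <- function(n_steps, D, dt) {
  if (n_steps < 1) abort("`n_steps` must be >= 1", class = "sptmotion_config_error")
  if (D < 0) abort("`D` must be >= 0", class = "sptmotion_config_error")
  if (dt <= 0) abort("`dt` must be > 0", class = "sptmotion_config_error")
  invisible(TRUE)
}

#' Confinement radius for a given boundedness
#'
#' The boundedness \eqn{B = D N \Delta t / r^2} compares the area an
#' unconfined walk of `N` steps would explore with the area of a circular
#' confinement of radius `r`; inverting it gives the radius
#' \eqn{r = \sqrt{D N \Delta t / B}} used by the confined-diffusion
#' simulator. `B < 1` means the trajectory is on average unaffected by the
#' boundary; values above ~6 no longer change the trajectory features.
#'
#' @param B Boundedness (dimensionless, > 0).
#' @param D Diffusion coefficient in um^2/s.
#' @param n_steps Number of steps.
#' @param dt Frame interval in seconds.
#' @return Confinement radius in micrometres.
#' @export
radius_from_boundedness <- function(B, D = 9.02, n_steps = 300, dt = 1 / 30) {
  if (any(B <= 0) || any(D <= 0) || any(n_steps <= 0) || any(dt <= 0)) {
    abort("all arguments must be positive", class = "sptmotion_config_error")
  }
  sqrt(D * n_steps * dt / B)
}

#' Simulate confined diffusion
#'
#' A random walk inside a circular reflecting boundary centred at the start
#' position. Each recorded step is composed of 100 sub-steps with
#' `dt' = dt/100`, drawn like normal-diffusion steps; a sub-step is accepted
#' only when the proposed position stays strictly inside the confinement
#' radius, otherwise the position is left unchanged. The radius is derived
#' from the boundedness `B` via [radius_from_boundedness()].
#'
#' @inheritParams simulate_nd
#' @param B Boundedness (dimensionless, > 0); larger values confine more.
#' @param n_sub Number of sub-steps per recorded step.
#' @return A track table with one trajectory starting at the confinement
#'   centre (the origin).
#' @export
simulate_cd <- function(n_steps, B = 3, D = 9.02, dt = 1 / 30, n_sub = 100L,
                        id = 1L) {
  check_sim_args(n_steps, D, dt)
  if (B <= 0) abort("`B` must be > 0", class = "sptmotion_config_error")
  r <- radius_from_boundedness(B, D, n_steps, dt)
  pos <- cd_walk_cpp(as.integer(n_steps), as.integer(n_sub),
                     4 * D * dt / n_sub, r)
  new_track(pos[, 1], pos[, 2], dt, id)
}

#' Simulate anomalous (sub-)diffusion
#'
#' Generates x and y as independent increment series of the
#' Weierstrass-Mandelbrot function
#' \deqn{W(t) = \sum_{n=-8}^{48}
#'   \frac{\cos\phi_n - \cos(\gamma^n t^* + \phi_n)}{\gamma^{n\alpha/2}},}
#' with \eqn{t^* = 2\pi t/N}, random phases \eqn{\phi_n \sim U[0, 2\pi)} and
#' scale base `gamma`. The series is oversampled (`oversample * n_steps`
#' points) and only the first `n_steps` increments are kept; each coordinate's
#' increments are then rescaled so that the expected first-lag MSD equals
#' \eqn{4 D \Delta t}.
#'
#' @inheritParams simulate_nd
#' @param alpha Anomalous exponent in (0, 1]; sub-diffusive below 1.
#' @param gamma Scale base of the lacunary series (> 1). The default
#'   `sqrt(pi)` is the standard choice for this generator.
#' @param oversample Oversampling factor `N / N'` of the underlying series.
#' @return A track table with one trajectory starting at the origin.
#' @export
simulate_ad <- function(n_steps, alpha = 0.5, D = 9.02, dt = 1 / 30,
                        gamma = sqrt(pi), oversample = 8L, id = 1L) {
  check_sim_args(n_steps, D, dt)
  if (alpha <= 0 || alpha > 1) {
    abort("`alpha` must lie in (0, 1]", class = "sptmotion_config_error")
  }
  if (gamma <= 1) abort("`gamma` must be > 1", class = "sptmotion_config_error")
  dx <- wmf_increments(n_steps, alpha, gamma, oversample)
  dy <- wmf_increments(n_steps, alpha, gamma, oversample)
  # impose <r^2(1)> = 4 D dt, i.e. 2 D dt per coordinate
  dx <- dx * sqrt(2 * D * dt / mean(dx^2))
  dy <- dy * sqrt(2 * D * dt / mean(dy^2))
  new_track(c(0, cumsum(dx)), c(0, cumsum(dy)), dt, id)
}

# First n_steps increments of an oversampled Weierstrass-Mandelbrot series.
wmf_increments <- function(n_steps, alpha, gamma, oversample) {
  N <- oversample * n_steps
  terms <- -8:48
  phi <- runif(length(terms), 0, 2 * pi)
  tstar <- 2 * pi * (0:N) / N
  amp <- gamma^(-terms * alpha / 2)
  arg <- outer(tstar, gamma^terms) +
    matrix(phi, N + 1L, length(terms), byrow = TRUE)
  W <- drop((cos(matrix(phi, N + 1L, length(terms), byrow = TRUE)) - cos(arg)) %*% amp)
  diff(W)[seq_len(n_steps)]
}

#' Velocity of the active component for a given directed-motion ratio
#'
#' The directed-motion ratio \eqn{R = v^2 T / (4D)} measures the strength of
#' the active transport component relative to diffusion over the trajectory
#' duration `T`; inverting it gives \eqn{v = \sqrt{4 D R / T}}.
#'
#' @param R Directed-motion ratio (dimensionless, >= 0).
#' @param D Diffusion coefficient in um^2/s.
#' @param T_total Trajectory duration in seconds.
#' @return Velocity in um/s.
#' @export
velocity_from_ratio <- function(R, D, T_total) {
  if (any(R < 0) || any(D < 0) || any(T_total <= 0)) {
    abort("need R >= 0, D >= 0, T_total > 0", class = "sptmotion_config_error")
  }
  sqrt(4 * D * R / T_total)
}

#' Simulate directed motion with diffusion
#'
#' Sums, position-wise, a normal-diffusion trajectory and a pure active track
#' whose per-step displacement is `v * dt`, starting from a uniform-random
#' direction. The transport direction changes at an angular velocity of
#' magnitude `angular_velocity` (default `pi/4` rad/s) whose sign is drawn
#' at random each step, so the heading performs a slow random walk and the
#' track stays directionally persistent over its whole duration (a
#' deterministic rotation at the same rate would wind multi-hundred-step
#' tracks into closed loops whose net transport vanishes). The velocity is
#' derived from the directed-motion ratio `R` via [velocity_from_ratio()]
#' with `T = n_steps * dt`.
#'
#' @inheritParams simulate_nd
#' @param R Directed-motion ratio (>= 0); larger values are more strongly
#'   dominated by active transport.
#' @param angular_velocity Magnitude of the direction-change rate in rad/s.
#' @return A track table with one trajectory starting at the origin.
#' @export
simulate_dm <- function(n_steps, R = 5, D = 9.02, dt = 1 / 30,
                        angular_velocity = pi / 4, id = 1L) {
  check_sim_args(n_steps, D, dt)
  if (R < 0) abort("`R` must be >= 0", class = "sptmotion_config_error")
  v <- velocity_from_ratio(R, D, n_steps * dt)
  turns <- sample(c(-1, 1), max(n_steps - 1L, 0L), replace = TRUE)
  th <- runif(1, 0, 2 * pi) + c(0, cumsum(turns * angular_velocity * dt))
  ax <- v * dt * cos(th)
  ay <- v * dt * sin(th)
  st <- nd_displacements(n_steps, D, dt)
  new_track(c(0, cumsum(st$dx + ax)), c(0, cumsum(st$dy + ay)), dt, id)
}

#' Localization-noise standard deviation for a given signal-to-noise ratio
#'
#' Two signal-to-noise ratios are used: for purely diffusive motion
#' \eqn{SNR_1 = \sqrt{D \Delta t}/\sigma}, and for directed motion (whose
#' first-lag displacement also carries the active component)
#' \eqn{SNR_2 = \sqrt{D \Delta t + v^2 \Delta t^2}/\sigma}. This helper
#' inverts them to the noise standard deviation.
#'
#' @param snr Signal-to-noise ratio (> 0).
#' @param D Diffusion coefficient in um^2/s.
#' @param dt Frame interval in seconds.
#' @param v Optional velocity of an active component in um/s; when given the
#'   directed-motion definition is used.
#' @return Noise standard deviation sigma in micrometres.
#' @export
sigma_from_snr <- function(snr, D, dt, v = NULL) {
  if (any(snr <= 0)) abort("`snr` must be > 0", class = "sptmotion_config_error")
  if (is.null(v)) sqrt(D * dt) / snr else sqrt(D * dt + v^2 * dt^2) / snr
}

#' Add Gaussian localization noise to trajectories
#'
#' Perturbs every coordinate by independent zero-mean Gaussian noise with
#' standard deviation `sigma`, emulating the localization error of a particle
#' detector. `sigma = 0` returns the input unchanged.
#'
#' @param tracks A track table.
#' @param sigma Noise standard deviation in micrometres (>= 0).
#' @return A track table with perturbed coordinates.
#' @export
add_localization_noise <- function(tracks, sigma) {
  validate_tracks(tracks)
  if (sigma < 0) abort("`sigma` must be >= 0", class = "sptmotion_config_error")
  if (sigma == 0) return(tracks)
  n <- nrow(tracks)
  tracks$x <- tracks$x + rnorm(n, 0, sigma)
  tracks$y <- tracks$y + rnorm(n, 0, sigma)
  tracks
}

#' Parameter ranges of the training distribution
#'
#' The simulated training regime: frame interval 1/30 s and diffusion
#' coefficient 9.02 um^2/s (a 50 nm particle diffusing freely in water at
#' 22 C), trajectory lengths uniform between 30 and 600 steps, and per-class
#' motion parameters drawn uniformly: boundedness 1-6 (confined), anomalous
#' exponent 0.3-0.7 (anomalous), directed-motion ratio 1-17 (directed), and
#' signal-to-noise ratio 1-9 for all classes.
#'
#' @param ... Named overrides of the defaults listed above.
#' @return A named list with entries `dt`, `D`, `steps`, `boundedness`,
#'   `alpha`, `ratio`, `snr` (ranges as length-2 numeric vectors).
#' @export
training_ranges <- function(...) {
  defaults <- list(
    dt = 1 / 30, D = 9.02, steps = c(30L, 600L),
    boundedness = c(1, 6), alpha = c(0.3, 0.7), ratio = c(1, 17),
    snr = c(1, 9)
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown range name(s): ", paste(unknown, collapse = ", ")),
          class = "sptmotion_config_error")
  }
  ranges <- modifyList(defaults, over)
  bad <- vapply(c("steps", "boundedness", "alpha", "ratio", "snr"),
                function(k) length(ranges[[k]]) != 2 ||
                  ranges[[k]][1] > ranges[[k]][2], logical(1))
  if (ranges$dt <= 0 || ranges$D <= 0 || any(bad)) {
    abort("invalid training ranges", class = "sptmotion_config_error")
  }
  ranges
}

#' Simulate a labelled training set
#'
#' Draws `n_per_class` trajectories per motion type from the training
#' distribution of [training_ranges()]: lengths uniform over the step range,
#' class parameters uniform over their ranges, and Gaussian localization
#' noise whose standard deviation is derived from a uniform signal-to-noise
#' ratio ([sigma_from_snr()]; the directed-motion definition for the directed
#' class, the diffusive one otherwise).
#'
#' @param n_per_class Number of trajectories per motion type.
#' @param ranges Parameter ranges, see [training_ranges()].
#' @param seed Optional integer seed for reproducible sets.
#' @return A track table with a `true_class` factor column (levels
#'   `directed`, `anomalous`, `confined`, `normal`). The per-trajectory
#'   generating parameters are attached as a tibble in the `sim_params`
#'   attribute (columns `id`, `true_class`, `n_steps`, `param`, `snr`,
#'   `sigma`; `param` is R, alpha or B depending on the class).
#' @examples
#' ts <- simulate_training_set(2, seed = 1)
#' dplyr::count(ts, true_class)
#' @export
simulate_training_set <- function(n_per_class = 5000,
                                  ranges = training_ranges(),
                                  seed = NULL) {
  if (n_per_class < 1) {
    abort("`n_per_class` must be >= 1", class = "sptmotion_config_error")
  }
  with_seed_if(seed, {
    classes <- motion_classes()
    parts <- vector("list", length(classes))
    params <- vector("list", length(classes))
    next_id <- 1L
    for (ci in seq_along(classes)) {
      cl <- classes[ci]
      n_steps <- sample(seq(ranges$steps[1], ranges$steps[2]), n_per_class,
                        replace = TRUE)
      snr <- runif(n_per_class, ranges$snr[1], ranges$snr[2])
      par <- switch(cl,
        directed  = runif(n_per_class, ranges$ratio[1], ranges$ratio[2]),
        anomalous = runif(n_per_class, ranges$alpha[1], ranges$alpha[2]),
        confined  = runif(n_per_class, ranges$boundedness[1],
                          ranges$boundedness[2]),
        normal    = rep(NA_real_, n_per_class)
      )
      ids <- next_id + seq_len(n_per_class) - 1L
      next_id <- next_id + n_per_class
      sims <- vector("list", n_per_class)
      sigmas <- numeric(n_per_class)
      for (j in seq_len(n_per_class)) {
        tr <- switch(cl,
          directed  = simulate_dm(n_steps[j], R = par[j], D = ranges$D,
                                  dt = ranges$dt, id = ids[j]),
          anomalous = simulate_ad(n_steps[j], alpha = par[j], D = ranges$D,
                                  dt = ranges$dt, id = ids[j]),
          confined  = simulate_cd(n_steps[j], B = par[j], D = ranges$D,
                                  dt = ranges$dt, id = ids[j]),
          normal    = simulate_nd(n_steps[j], D = ranges$D, dt = ranges$dt,
                                  id = ids[j])
        )
        v <- if (cl == "directed") {
          velocity_from_ratio(par[j], ranges$D, n_steps[j] * ranges$dt)
        } else NULL
        sigmas[j] <- sigma_from_snr(snr[j], ranges$D, ranges$dt, v)
        sims[[j]] <- add_localization_noise(tr, sigmas[j])
      }
      part <- dplyr::bind_rows(sims)
      part$true_class <- factor(cl, levels = classes)
      parts[[ci]] <- part
      params[[ci]] <- tibble(id = ids,
                             true_class = factor(cl, levels = classes),
                             n_steps = n_steps, param = par, snr = snr,
                             sigma = sigmas)
    }
    out <- dplyr::bind_rows(parts)
    attr(out, "sim_params") <- dplyr::bind_rows(params)
    out
  })
}
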