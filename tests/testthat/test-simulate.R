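test_that("derived quantities follow their closed forms", {
  expect_equal(radius_from_boundedness(1, 9.02, 300, 1 / 30), sqrt(90.2))
  expect_equal(radius_from_boundedness(4, 9.02, 300, 1 / 30),
               radius_from_boundedness(1, 9.02, 300, 1 / 30) / 2)
  expect_equal(velocity_from_ratio(1, 9.02, 10), sqrt(4 * 9.02 / 10))
  expect_equal(velocity_from_ratio(0, 9.02, 10), 0)
  expect_equal(velocity_from_ratio(4, 9.02, 10),
               2 * velocity_from_ratio(1, 9.02, 10))
  expect_equal(sigma_from_snr(3, 9.02, 1 / 30), sqrt(9.02 / 30) / 3,
               tolerance = 1e-12)
  expect_equal(sigma_from_snr(3, 9.02, 1 / 30, v = 0),
               sigma_from_snr(3, 9.02, 1 / 30))
  expect_lt(sigma_from_snr(1e9, 9.02, 1 / 30), 1e-8)
})

test_that("normal-diffusion steps follow the Rayleigh step-length law", {
  set.seed(11)
  # ensemble mean first-lag MSD equals 4 D dt
  D <- 9.02; dt <- 1 / 30
  msd1 <- replicate(400, track_msd(simulate_nd(50, D, dt), lags = 1)$msd)
  expect_equal(mean(msd1), 4 * D * dt, tolerance = 0.02)

  # KS test of step lengths against the implied Rayleigh CDF
  tr <- simulate_nd(10000, D, dt)
  u <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
  ks <- stats::ks.test(u, function(q) 1 - exp(-q^2 / (4 * D * dt)))
  expect_gt(ks$p.value, 0.01)

  # D -> 0 keeps the particle at the start
  z <- simulate_nd(20, D = 0, dt = dt)
  expect_true(all(z$x == 0 & z$y == 0))
})

test_that("simulators are reproducible under a fixed seed", {
  gen <- function() {
    list(simulate_nd(30), simulate_ad(30, 0.5), simulate_cd(30, 3),
         simulate_dm(30, 5))
  }
  a <- withr::with_seed(99, gen())
  b <- withr::with_seed(99, gen())
  expect_identical(a, b)
})

test_that("confined trajectories never leave the confinement disc", {
  set.seed(12)
  for (B in c(1, 3, 6)) {
    tr <- simulate_cd(200, B = B)
    r <- radius_from_boundedness(B, 9.02, 200, 1 / 30)
    expect_true(all(tr$x^2 + tr$y^2 < r^2))
  }
})

test_that("confined-diffusion ensemble MSD plateaus near the squared radius", {
  set.seed(13)
  n_steps <- 200; B <- 6
  r <- radius_from_boundedness(B, 9.02, n_steps, 1 / 30)
  curves <- sapply(1:150, function(i)
    track_msd(simulate_cd(n_steps, B = B), lags = 1:100)$msd)
  plateau <- mean(rowMeans(curves)[80:100])
  expect_equal(plateau, r^2, tolerance = 0.15)
})

test_that("anomalous-diffusion tracks reproduce the target exponent and scale", {
  set.seed(14)
  n <- 300
  msd <- sapply(1:n, function(i) track_msd(simulate_ad(100, 0.5), lags = 1:10)$msd)
  m <- rowMeans(msd)
  # imposed first-lag scale
  expect_equal(m[1], 4 * 9.02 / 30, tolerance = 0.02)
  # log-log slope of the ensemble mean over lags 1..10
  slope <- coef(lm(log(m) ~ log(1:10)))[[2]]
  expect_equal(slope, 0.5, tolerance = 0.1)
})

test_that("directed-motion tracks carry the requested active component", {
  set.seed(15)
  # dominant active component (R -> large): step lengths converge to v*dt
  tr <- simulate_dm(50, R = 1e6)
  v <- velocity_from_ratio(1e6, 9.02, 50 / 30)
  steps <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
  expect_equal(steps / (v / 30), rep(1, 50), tolerance = 0.05)

  # fitted directed-motion velocity recovers v within 20% at large R
  ratio <- replicate(60, {
    f <- fit_msd_model(simulate_dm(300, R = 17), "dm", max_lag = 30)
    f$params$v / velocity_from_ratio(17, 9.02, 10)
  })
  expect_equal(mean(ratio), 1, tolerance = 0.2)

  # net displacement exceeds the diffusive expectation for R >= 6
  net <- function(tr) sqrt((tr$x[nrow(tr)] - tr$x[1])^2 +
                             (tr$y[nrow(tr)] - tr$y[1])^2)
  hits <- replicate(100, net(simulate_dm(150, R = 6)) >
                      sqrt(4 * 9.02 * 150 / 30))
  expect_gte(mean(hits), 0.9)
})

test_that("localization noise has the requested per-coordinate deviation", {
  set.seed(16)
  still <- new_tracks_df(x = rep(0, 50000), y = rep(0, 50000))
  noisy <- add_localization_noise(still, 0.25)
  expect_equal(sd(noisy$x), 0.25, tolerance = 0.02)
  expect_equal(sd(noisy$y), 0.25, tolerance = 0.02)
  # MSD of a static noisy track -> 4 sigma^2
  expect_equal(track_msd(noisy, lags = 1)$msd, 4 * 0.25^2, tolerance = 0.05)
  expect_identical(add_localization_noise(still, 0), still)
})

test_that("ensemble MSD curves order as directed > normal > anomalous > confined", {
  set.seed(17)
  n_steps <- 150; lag <- 60; n_rep <- 120
  mean_msd <- function(gen) {
    mean(replicate(n_rep, track_msd(gen(), lags = lag)$msd))
  }
  m_dm <- mean_msd(function() simulate_dm(n_steps, R = 9))
  m_nd <- mean_msd(function() simulate_nd(n_steps))
  m_ad <- mean_msd(function() simulate_ad(n_steps, 0.5))
  m_cd <- mean_msd(function() simulate_cd(n_steps, B = 6))
  expect_true(m_dm > m_nd && m_nd > m_ad && m_ad > m_cd)
})

test_that("the training-set generator labels and parameterizes every class", {
  ts1 <- simulate_training_set(2, seed = 5)
  per_class <- table(unique(ts1[c("id", "true_class")])$true_class)
  expect_equal(unname(c(per_class)), rep(2L, 4))
  expect_equal(names(per_class),
               c("directed", "anomalous", "confined", "normal"))
  pars <- attr(ts1, "sim_params")
  expect_equal(nrow(pars), 8L)
  expect_true(all(pars$n_steps >= 30 & pars$n_steps <= 600))
  expect_true(all(pars$snr >= 1 & pars$snr <= 9))
  expect_true(all(pars$sigma > 0))

  # identical feature tables on regeneration from the same seed
  f1 <- track_features(simulate_training_set(3, seed = 6))
  f2 <- track_features(simulate_training_set(3, seed = 6))
  expect_identical(f1, f2)

  expect_error(simulate_training_set(2, ranges = training_ranges(alpha = c(2, 1))),
               class = "sptmotion_config_error")
  expect_error(training_ranges(bogus = 1), class = "sptmotion_config_error")
})
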