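test_that("features take their closed-form values on a straight line", {
  f <- track_features(straight_track(31))
  expect_equal(f$alpha, 2, tolerance = 1e-8)
  expect_equal(f$asymmetry, -log(1 / 2), tolerance = 1e-8)
  expect_equal(f$efficiency, 1, tolerance = 1e-12)
  expect_equal(f$fractal_dimension, 1, tolerance = 1e-12)
  expect_equal(f$gaussianity, -0.5, tolerance = 1e-12)
  expect_equal(f$straightness, 1, tolerance = 1e-12)
  # quadratic MSD: msd(1)/msd(n2) - 1/n2 = 1/n2^2 - 1/n2 with n2 = 10
  expect_equal(f$msd_ratio, 1 / 100 - 1 / 10, tolerance = 1e-12)
})

test_that("kurtosis of collinear equispaced points matches hand moments", {
  f <- suppressWarnings(track_features(straight_track(4)))
  expect_equal(f$kurtosis, 2.5625 / 1.5625, tolerance = 1e-10)
  # Gaussian projections converge to kurtosis 3
  set.seed(21)
  g <- track_features(new_tracks_df(x = rnorm(20000), y = rnorm(20000, 0, 1e-3)))
  expect_equal(g$kurtosis, 3, tolerance = 0.1)
})

test_that("asymmetry vanishes for four-fold symmetric positions", {
  sq <- new_tracks_df(x = c(1, -1, -1, 1), y = c(1, 1, -1, -1))
  f <- suppressWarnings(track_features(sq))
  expect_equal(f$asymmetry, 0, tolerance = 1e-12)
})

test_that("efficiency and straightness are 0 on closed loops and bounded in [0,1]", {
  th <- seq(0, 2 * pi, length.out = 41)
  loop <- new_tracks_df(x = cos(th), y = sin(th))
  f <- track_features(loop)
  expect_equal(f$efficiency, 0, tolerance = 1e-12)
  expect_equal(f$straightness, 0, tolerance = 1e-10)
  set.seed(22)
  for (i in 1:10) {
    fr <- track_features(random_track(60))
    expect_true(fr$efficiency >= 0 && fr$efficiency <= 1)
    expect_true(fr$straightness >= 0 && fr$straightness <= 1)
    expect_true(fr$trappedness >= 0 && fr$trappedness <= 1)
  }
})

test_that("trappedness crosses zero at D t / r0^2 = 0.2048/0.25117 and clamps", {
  raw <- sptmotion:::trappedness_raw
  crossing <- 0.2048 / 0.25117
  expect_equal(raw(crossing, 1, 1), 0, tolerance = 1e-12)
  expect_equal(raw(0, 1, 1), 0)            # negative raw value clamped
  expect_equal(raw(1e6, 1, 1), 1, tolerance = 1e-12)
  expect_gt(raw(crossing * 1.5, 1, 1), 0)
})

test_that("features are invariant under rigid motion; scale enters only where it should", {
  set.seed(23)
  tr <- random_track(60)
  f0 <- track_features(tr)
  th <- 1.1
  moved <- dplyr::mutate(tr, x0 = x,
                         x = cos(th) * x0 - sin(th) * y + 5,
                         y = sin(th) * x0 + cos(th) * y - 3)
  f1 <- track_features(moved[names(tr)])
  for (col in sptmotion:::feature_names()) {
    expect_equal(f1[[col]], f0[[col]], tolerance = 1e-8, label = col)
  }
  # coordinate rescaling: scale-free features unchanged, trappedness moves
  scaled <- dplyr::mutate(tr, x = 3 * x, y = 3 * y)
  f2 <- track_features(scaled)
  for (col in setdiff(sptmotion:::feature_names(), c("trappedness"))) {
    expect_equal(f2[[col]], f0[[col]], tolerance = 1e-8, label = col)
  }
})

test_that("normal-diffusion ensembles center on the stated feature values", {
  set.seed(24)
  f <- track_features(dplyr::bind_rows(
    lapply(1:150, function(i) simulate_nd(120, id = i))))
  expect_equal(mean(f$alpha), 1, tolerance = 0.05)
  # the time-averaged moment ratio is slightly biased low on finite tracks;
  # it must sit near 0, far from the -0.5 of a deterministic path
  expect_lt(abs(mean(f$gaussianity)), 0.12)
  expect_equal(mean(f$msd_ratio), 0, tolerance = 0.05)
  expect_equal(mean(f$fractal_dimension), 2, tolerance = 0.3)
})

test_that("constrained trajectories show high fractal dimension, confined ones positive msd_ratio", {
  set.seed(25)
  f_cd <- track_features(dplyr::bind_rows(
    lapply(1:50, function(i) simulate_cd(150, B = 5, id = i))))
  expect_equal(mean(f_cd$fractal_dimension), 3, tolerance = 0.4)
  expect_gt(mean(f_cd$msd_ratio), 0)
})

test_that("anomalous exponent fits recover the simulated exponent", {
  set.seed(26)
  a <- vapply(1:100, function(i) fit_alpha(simulate_ad(120, 0.5))$alpha,
              numeric(1))
  expect_equal(mean(a), 0.5, tolerance = 0.1)
})

test_that("straightness separates strong directed from confined motion", {
  set.seed(27)
  n <- 100
  s_dm <- vapply(1:n, function(i) {
    tr <- add_localization_noise(simulate_dm(100, R = 12),
                                 sigma_from_snr(9, 9.02, 1 / 30))
    track_features(tr)$straightness
  }, numeric(1))
  s_cd <- vapply(1:n, function(i) {
    tr <- add_localization_noise(simulate_cd(100, B = 5),
                                 sigma_from_snr(9, 9.02, 1 / 30))
    track_features(tr)$straightness
  }, numeric(1))
  cut <- (median(s_dm) + median(s_cd)) / 2
  acc <- (sum(s_dm > cut) + sum(s_cd <= cut)) / (2 * n)
  expect_gte(acc, 0.9)
})

test_that("degenerate trajectories yield flagged missing features", {
  still <- new_tracks_df(x = rep(1, 31), y = rep(2, 31))
  expect_warning(f <- track_features(still), "degenerate")
  expect_true(all(is.na(f[sptmotion:::feature_names()])))
  expect_error(fit_alpha(still), class = "sptmotion_degenerate_error")
})

test_that("feature computation is deterministic", {
  set.seed(28)
  tr <- random_track(45)
  expect_identical(track_features(tr), track_features(tr))
})
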