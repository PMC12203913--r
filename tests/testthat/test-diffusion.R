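test_that("MSD matches hand enumeration and a brute-force oracle", {
  tr <- path_track(c(0, 1, 2, 3), dt = 1)
  m <- compute_msd(tr, 3)
  expect_equal(m$msd_kbp2, c(1, 4, 9))
  expect_equal(m$n_pairs, c(3, 2, 1))

  # all-pairs brute force on an arbitrary 10-frame track
  set.seed(31)
  x <- cumsum(rnorm(10))
  tr2 <- path_track(x - min(x), dt = 0.5)
  m2 <- compute_msd(tr2, 3)
  brute <- vapply(1:3, function(k) {
    pairs <- vapply(seq_len(10 - k), function(i)
      (tr2$positions_kbp[i + k] - tr2$positions_kbp[i])^2, numeric(1))
    mean(pairs)
  }, numeric(1))
  expect_equal(m2$msd_kbp2, brute)
})

test_that("MSD of a constant track is zero and bad lags error", {
  tr <- stationary_track(10, n = 20)
  expect_equal(compute_msd(tr, 5)$msd_kbp2, rep(0, 5))
  expect_error(compute_msd(tr, 20), class = "smcurtain_invalid_argument")
  expect_error(compute_msd(tr, 0), class = "smcurtain_invalid_argument")
})

test_that("estimate_D inverts the unit conversion exactly", {
  lag_s <- (1:10) * 0.1
  d_kbp2 <- 0.025 / 0.272^2                     # 0.338 kbp^2/s
  m <- make_msd(lag_s, 2 * d_kbp2 * lag_s)
  est <- estimate_D(m)
  expect_equal(est$D_kbp2_s, d_kbp2, tolerance = 1e-9)
  expect_equal(est$D_um2_s, 0.025, tolerance = 1e-9)
  expect_equal(est$intercept_kbp2, 0, tolerance = 1e-9)

  z <- estimate_D(make_msd(lag_s, rep(0, 10)))
  expect_identical(z$D_kbp2_s, 0)
  expect_equal(z$intercept_kbp2, 0, tolerance = 1e-12)

  expect_error(estimate_D(m, fit_lags = 1), class = "smcurtain_invalid_argument")
})

test_that("the MSD intercept recovers twice the localization variance", {
  cfg <- sim_config(n_frames = 400, localization_sigma_kbp = 0.5, rng_seed = 32)
  ints <- vapply(1:60, function(i) {
    tr <- simulate_sliding_trajectory(cfg, seed = split_seed(32, i))
    estimate_D(compute_msd(tr, 10))$intercept_kbp2
  }, numeric(1))
  expect_equal(mean(ints), 2 * 0.5^2, tolerance = 0.25)
})

test_that("displacement Gaussian centers at the symmetry point", {
  # symmetric unimodal walk: steps -1, 0, 0, +1 in balanced numbers
  steps <- rep(c(-1, 0, 0, 1), 15)
  g <- displacement_gaussian(path_track(cumsum(c(5, steps)), dt = 1))
  expect_equal(g$center, 0, tolerance = 1e-6)
})

test_that("displacement Gaussian is centered at zero for sliding and detects drift", {
  cfg <- sim_config(n_frames = 10001, rng_seed = 33)
  tr <- simulate_sliding_trajectory(cfg, start_kbp = 24)
  g <- displacement_gaussian(tr)
  expect_lt(abs(g$center), 3 * g$sigma / sqrt(g$n))

  drift <- path_track(20 + (0:299) * 0.1 +
                        rnorm(300, 0, 0.2), dt = 0.1, L = 100)
  gd <- displacement_gaussian(drift)
  expect_gt(abs(gd$center) / gd$center_se, 5)
})

test_that("displacement Gaussian needs enough data", {
  tr <- path_track(1:10, dt = 1)
  expect_error(displacement_gaussian(tr), class = "smcurtain_insufficient_data")
})

test_that("salt series calls sliding, hopping, and inconclusive correctly", {
  salt <- c(0, 25, 50, 100)
  flat <- salt_series_call(salt, rep(0.025, 4), se_um2_s = rep(0.001, 4))
  expect_identical(flat$mode, "sliding")

  rising <- salt_series_call(salt, 0.025 * (1 + salt / 100),
                             se_um2_s = rep(0.001, 4))
  expect_identical(rising$mode, "hopping")

  weak <- salt_series_call(c(0, 100), c(0.025, 0.027), se_um2_s = c(0.02, 0.02))
  expect_identical(weak$mode, "inconclusive")

  expect_error(salt_series_call(50, 0.025), class = "smcurtain_invalid_argument")
})

test_that("rotational limit matches its closed form and limits", {
  h <- hydro_params(temperature_K = 298, viscosity_Pa_s = 8.9e-4,
                    radius_nm = 20, pitch_nm = 3.57)
  kB <- 1.380649e-23
  wav <- (2 * pi / 3.57e-9)^2
  denom <- 6 * pi * 8.9e-4 * 20e-9 *
    (1 + (4 / 3) * wav * (20e-9)^2 + wav * (20e-9)^2)
  expect_equal(rotational_limit(h), kB * 298 / denom * 1e12, tolerance = 1e-9)
  expect_equal(rotational_limit(h), 4.24e-3, tolerance = 0.01)

  # rotation-free limit: pitch -> Inf reduces to Stokes-Einstein
  free <- hydro_params(temperature_K = 298, viscosity_Pa_s = 8.9e-4,
                       radius_nm = 20, pitch_nm = Inf)
  expect_equal(rotational_limit(free),
               kB * 298 / (6 * pi * 8.9e-4 * 20e-9) * 1e12, tolerance = 1e-9)

  expect_error(hydro_params(radius_nm = -1), class = "smcurtain_invalid_argument")
  expect_error(hydro_params(radius_nm = 20, pitch_nm = 0),
               class = "smcurtain_invalid_argument")
})

test_that("rotational limit is monotone in radius, offset, and pitch", {
  base <- function(R, Roc, p) rotational_limit(
    hydro_params(radius_nm = R, offset_nm = Roc, pitch_nm = p))
  rs <- seq(5, 40, by = 5)
  expect_true(all(diff(vapply(rs, function(R) base(R, 10, 3.57), numeric(1))) < 0))
  expect_true(all(diff(vapply(rs, function(Roc) base(10, Roc, 3.57), numeric(1))) < 0))
  ps <- c(2, 3.57, 5, 10, 50)
  expect_true(all(diff(vapply(ps, function(p) base(10, 10, p), numeric(1))) > 0))
})
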