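test_that("sim_config validates its inputs", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(frame_interval_s = 0), class = "smcurtain_invalid_config")
  expect_error(sim_config(n_frames = 0), class = "smcurtain_invalid_config")
  expect_error(sim_config(diffusion_um2_s = -1), class = "smcurtain_invalid_config")
  expect_error(sim_config(capture_prob_per_pass = 1.2), class = "smcurtain_invalid_config")
  expect_error(sim_config(direct_binding_prob = -0.1), class = "smcurtain_invalid_config")
  expect_error(sim_config(lesion_interval_bp = c(50000, 60000)),
               class = "smcurtain_invalid_config")
})

test_that("zero diffusion without noise gives a constant trajectory", {
  cfg <- sim_config(diffusion_um2_s = 0, localization_sigma_kbp = 0,
                    n_frames = 200, rng_seed = 1)
  tr <- simulate_sliding_trajectory(cfg, start_kbp = 12)
  expect_equal(tr$positions_kbp, rep(12, 200))
})

test_that("sliding displacement variance matches 2 D dt in sequence units", {
  cfg <- sim_config(diffusion_um2_s = 0.025, frame_interval_s = 0.1,
                    localization_sigma_kbp = 0, n_frames = 10001, rng_seed = 2)
  tr <- simulate_sliding_trajectory(cfg, start_kbp = 24)
  v_expected <- 2 * 0.025 * 0.1 / 0.272^2
  expect_lt(abs(stats::var(diff(tr$positions_kbp)) - v_expected) / v_expected, 0.05)
})

test_that("trajectories respect reflecting boundaries and are seed-reproducible", {
  cfg <- sim_config(diffusion_um2_s = 0.25, n_frames = 2000, rng_seed = 3)
  a <- simulate_sliding_trajectory(cfg)
  b <- simulate_sliding_trajectory(cfg)
  expect_identical(a$positions_kbp, b$positions_kbp)
  expect_true(all(a$positions_kbp >= 0 & a$positions_kbp <= cfg$dna_length_kbp))
})

test_that("fast search draws the generative law", {
  cfg <- sim_config(direct_binding_prob = 1, rng_seed = 4)
  ev <- simulate_search_experiment(cfg, 100)$events
  expect_true(all(ev$mode == "direct"))
  expect_true(all(ev$bypass_count == 0))

  cfg2 <- sim_config(direct_binding_prob = 0, capture_prob_per_pass = 0.89,
                     rng_seed = 5)
  ev2 <- simulate_search_experiment(cfg2, 1e5)$events
  emp <- mean(1 / (ev2$bypass_count + 1)) * 100
  expect_lt(abs(emp - geom_efficiency(0.89)) / geom_efficiency(0.89), 0.01)

  expect_error(simulate_search_experiment(cfg, 0), class = "smcurtain_invalid_config")
})

test_that("curtain snapshot respects the specific/background mixture", {
  cfg <- sim_config(rng_seed = 6)
  pure <- simulate_curtain_snapshot(cfg, 500, specific_fraction = 1,
                                    localization_sigma_kbp = 0)
  expect_true(all(pure$position_kbp >= 33.513 & pure$position_kbp <= 33.630))

  bg <- simulate_curtain_snapshot(cfg, 1e4, specific_fraction = 0, seed = 7)
  ks <- suppressWarnings(stats::ks.test(bg$position_kbp, "punif", 0,
                                        cfg$dna_length_kbp))
  expect_lt(unname(ks$statistic), 0.02)

  expect_error(simulate_curtain_snapshot(cfg, 0, 0.5),
               class = "smcurtain_invalid_config")
  expect_error(simulate_curtain_snapshot(cfg, 10, 1.5),
               class = "smcurtain_invalid_config")
})

test_that("noise-free titrations equal the closed-form depletion solution", {
  ladder <- c(0, 3, 5, 10, 15, 20, 30, 50)
  ts <- simulate_titration(ladder, dna_total_nM = 4, kd_nM = 5, noise_sd = 0)
  expect_equal(unname(ts$band_fractions[, "1x"]),
               bound_fraction(ladder, 4, 5))
  expect_identical(unname(ts$band_fractions[1, "1x"]), 0)
  expect_equal(unname(ts$band_fractions[ladder == 10, "1x"]), 0.603,
               tolerance = 1e-3)
  expect_error(simulate_titration(ladder, 4, kd_nM = 5, noise_sd = -1),
               class = "smcurtain_invalid_config")
})

test_that("noisy titrations renormalize per lane and are seed-stable", {
  ts1 <- simulate_titration(kd_nM = 5, noise_sd = 0.05, seed = 11)
  ts2 <- simulate_titration(kd_nM = 5, noise_sd = 0.05, seed = 11)
  expect_identical(ts1$band_fractions, ts2$band_fractions)
  expect_equal(unname(rowSums(ts1$band_fractions)),
               rep(1, length(ts1$protein_concs_nM)))
})

test_that("frap generator matches the two-component closed form", {
  full <- simulate_frap(1, 5, times_s = seq(-5, 200), baseline = 0)
  expect_equal(frap_recovery_at(full, 200), 1, tolerance = 1e-9)

  tr <- simulate_frap(0.5, 20, times_s = seq(-5, 120), baseline = 0.4)
  expect_equal(frap_recovery_at(tr, 120), 0.4 + 0.5 * (1 - exp(-6)),
               tolerance = 1e-9)

  expect_error(simulate_frap(0.5, 20, times_s = numeric(0)),
               class = "smcurtain_invalid_config")
  expect_error(simulate_frap(1.5, 20), class = "smcurtain_invalid_config")
})
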