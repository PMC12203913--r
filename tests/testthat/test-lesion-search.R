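test_that("classify_event identifies direct binding and hand-crafted bypasses", {
  # appears inside the lesion window and never moves: direct, no bypass
  direct <- stationary_track(33.57, n = 400, dt = 0.1)
  ev <- classify_event(direct)
  expect_identical(ev$mode, "direct")
  expect_identical(ev$bypass_count, 0L)
  expect_true(ev$censored)

  # crosses the window twice, then arrests there: diffusion with 2 bypasses
  crossing <- c(20, 25, 30, 40, 45,        # transit 1 (jump across, low->high)
                40, 30, 25, 20,            # transit 2 (high->low)
                25, 30, rep(33.57, 300))   # approach and arrest
  ev2 <- classify_event(path_track(crossing, dt = 0.1, censored_end = TRUE))
  expect_identical(ev2$mode, "diffusion")
  expect_identical(ev2$bypass_count, 2L)

  # never arrested: mode none, transits still counted
  pass <- path_track(c(20, 30, 40, 30, 20, 10, 5, 8, 12), dt = 1)
  ev3 <- classify_event(pass)
  expect_identical(ev3$mode, "none")
  expect_identical(ev3$bypass_count, 2L)

  expect_error(classify_event(direct, lesion_interval_kbp = c(50, 60)),
               class = "smcurtain_invalid_argument")
})

test_that("classify_event recovers ground-truth modes from the explicit simulator", {
  cfg <- sim_config(rng_seed = 42)
  sim <- simulate_search_experiment(cfg, 150, mode = "explicit")
  cl <- classify_events(sim$trajectories,
                        lesion_interval_kbp = cfg$lesion_interval_kbp)
  expect_gte(mean(cl$mode == sim$events$mode), 0.95)
  # dwell durations and censoring flags of correctly classified arrests agree
  ok <- sim$events$mode != "none" & cl$mode == sim$events$mode
  expect_gt(stats::cor(sim$events$dwell_s[ok], cl$dwell_s[ok]), 0.95)
  expect_gte(mean(sim$events$censored[ok] == cl$censored[ok]), 0.95)
})

test_that("recognition efficiency reproduces the weighted bypass sum", {
  all0 <- data.frame(mode = "direct", bypass_count = rep(0L, 10))
  expect_equal(recognition_efficiency(all0)$efficiency_percent, 100)

  all1 <- data.frame(mode = "diffusion", bypass_count = rep(1L, 10))
  expect_equal(recognition_efficiency(all1)$efficiency_percent, 50)

  mixed <- data.frame(mode = "diffusion", bypass_count = c(rep(0L, 8), 1L, 2L))
  expect_equal(recognition_efficiency(mixed)$efficiency_percent,
               (8 + 1 / 2 + 1 / 3) / 10 * 100, tolerance = 1e-12)

  none <- data.frame(mode = "none", bypass_count = 3L)
  expect_error(recognition_efficiency(none), class = "smcurtain_insufficient_data")
})

test_that("recognition efficiency matches the geometric closed form", {
  for (q in c(0.5, 0.89)) {
    cfg <- sim_config(direct_binding_prob = 0, capture_prob_per_pass = q,
                      rng_seed = 50)
    ev <- simulate_search_experiment(cfg, 1e5)$events
    eff <- recognition_efficiency(ev)$efficiency_percent
    expect_lt(abs(eff - geom_efficiency(q)) / geom_efficiency(q), 0.01)
  }
})

test_that("binomial fractions carry the right standard deviation", {
  f <- fraction_with_sd(27, 144)
  expect_equal(f$p_hat, 0.1875)
  expect_equal(f$sd_binomial, sqrt(0.1875 * (1 - 0.1875) / 144), tolerance = 1e-12)
  expect_equal(f$sd_binomial, 0.0325, tolerance = 1e-3)
  expect_identical(fraction_with_sd(0, 50)$sd_binomial, 0)
  expect_error(fraction_with_sd(5, 0), class = "smcurtain_invalid_argument")
  expect_error(fraction_with_sd(10, 5), class = "smcurtain_invalid_argument")
})

test_that("censored-exponential MLE matches its closed form", {
  ev <- data.frame(mode = "diffusion", dwell_s = c(100, 200, 600),
                   censored = c(FALSE, FALSE, TRUE))
  fit <- fit_residence_time(ev, 600, method = "mle")
  expect_equal(fit$tau_s, 450)
  expect_identical(fit$n_censored, 1L)

  all_cens <- data.frame(mode = "diffusion", dwell_s = c(600, 600),
                         censored = c(TRUE, TRUE))
  expect_warning(lb <- fit_residence_time(all_cens, 600, method = "mle"),
                 class = "smcurtain_lower_bound")
  expect_true(lb$lower_bound_only)
  expect_equal(lb$tau_s, 1200)
})

test_that("naive fit recovers tau without censoring but underestimates when tau >= window", {
  # plain exponential dwells, no truncation: the naive fit recovers tau
  set.seed(51)
  ev <- data.frame(mode = "diffusion", dwell_s = rexp(500, 1 / 100),
                   censored = FALSE)
  naive <- fit_residence_time(ev, 600, method = "naive")
  expect_lt(abs(naive$tau_s - 100) / 100, 0.10)

  # tau equal to the window: arrests throughout the window censor long dwells
  # away, so the naive histogram fit is biased low while the MLE is not
  naives <- mles <- numeric(5)
  for (i in 1:5) {
    cfgw <- sim_config(mean_dwell_s = 600, direct_binding_prob = 0,
                       rng_seed = 60 + i)
    evw <- simulate_search_experiment(cfgw, 1000)$events
    naives[i] <- fit_residence_time(evw, 600, method = "naive")$tau_s
    mles[i] <- fit_residence_time(evw, 600, method = "mle")$tau_s
  }
  expect_true(all(naives < 0.8 * 600))
  expect_lt(abs(mean(mles) - 600) / 600, 0.10)

  few <- data.frame(mode = "diffusion", dwell_s = c(10, 20), censored = FALSE)
  expect_error(fit_residence_time(few, 600, method = "naive"),
               class = "smcurtain_insufficient_data")
})
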