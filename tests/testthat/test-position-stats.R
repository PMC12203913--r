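test_that("histograms bin correctly and degenerate data give zero-width intervals", {
  h <- build_histogram(rep(12.3, 40), seed = 1)
  expect_identical(sum(h$count), 40L)
  expect_identical(sum(h$count > 0), 1L)
  nz <- h[h$count > 0, ]
  expect_identical(nz$ci_lo, 40)
  expect_identical(nz$ci_hi, 40)
})

test_that("histogram counts are order-invariant and bootstrap is seed-reproducible", {
  set.seed(2)
  pos <- runif(300, 0, 48.5)
  h1 <- build_histogram(pos, seed = 3)
  h2 <- build_histogram(sample(pos), seed = 3)
  expect_identical(h1$count, h2$count)
  expect_identical(h1$ci_lo, h2$ci_lo)
  expect_error(build_histogram(pos, n_boot = 50), class = "smcurtain_invalid_argument")
  expect_error(build_histogram(numeric(0)), class = "smcurtain_insufficient_data")
  expect_error(build_histogram(c(1, 60)), class = "smcurtain_invalid_argument")
})

test_that("peak fit recovers a dominant bin and the generator's lesion peak", {
  # near-delta histogram at 34 kbp over a sparse background
  pos <- c(rep(34, 200), 5, 15, 25, 40, 45)
  pk <- fit_peak(build_histogram(pos, seed = 4))
  expect_equal(pk$center_kbp, 34, tolerance = 0.51)

  cfg <- sim_config(rng_seed = 5)
  snap <- simulate_curtain_snapshot(cfg, 600, specific_fraction = 0.6,
                                    localization_sigma_kbp = 1)
  pk2 <- fit_peak(build_histogram(snap$position_kbp, L = cfg$dna_length_kbp,
                                  seed = 6))
  lesion_mid <- mean(cfg$lesion_interval_kbp)
  expect_lt(abs(pk2$center_kbp - lesion_mid), max(2 * pk2$center_se, 0.5))

  expect_error(fit_peak(build_histogram(rep(10, 30), seed = 7)),
               class = "smcurtain_insufficient_data")
})

test_that("peak fit is equivariant under coordinate translation", {
  cfg <- sim_config(rng_seed = 8)
  snap <- simulate_curtain_snapshot(cfg, 400, specific_fraction = 0.7,
                                    localization_sigma_kbp = 1)
  c0 <- fit_peak(build_histogram(snap$position_kbp, seed = 9))$center_kbp
  c5 <- fit_peak(build_histogram(snap$position_kbp + 5, L = 60, seed = 9))$center_kbp
  expect_equal(c5 - c0, 5, tolerance = 0.2)
})

test_that("lesion enrichment matches hand arithmetic", {
  set.seed(10)
  unif <- runif(5000, 0, 48.5)
  expect_equal(lesion_enrichment(unif, L = 48.5), 1, tolerance = 0.15)

  pos <- c(runif(40, 32, 36), runif(60, 36.001, 48.5))
  expect_equal(lesion_enrichment(pos, L = 48.5), (40 / 4) / (60 / 44.5),
               tolerance = 1e-12)

  expect_warning(inf <- lesion_enrichment(runif(10, 32, 36), L = 48.5))
  expect_identical(inf, Inf)
  expect_error(lesion_enrichment(numeric(0)), class = "smcurtain_insufficient_data")
})

test_that("binding enhancement is a guarded ratio with bootstrap error", {
  expect_equal(binding_enhancement(10, 10)$fold, 1)
  expect_equal(binding_enhancement(55, 10)$fold, 5.5)
  expect_error(binding_enhancement(10, 0), class = "smcurtain_undefined_fold")
  reps <- binding_enhancement(c(18, 22, 15), c(4, 3, 5), seed = 11)
  expect_gt(reps$se, 0)
})

test_that("lesion burden is the density-times-length product", {
  expect_identical(lesion_burden(0, 3e9), 0)
  expect_identical(lesion_burden(1, 1000), 1)
  expect_equal(lesion_burden(0.027, 3e9), 81000)
  expect_error(lesion_burden(-1, 10), class = "smcurtain_invalid_argument")
})
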