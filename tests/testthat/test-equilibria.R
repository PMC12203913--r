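test_that("bound fraction solves the depletion quadratic", {
  expect_identical(bound_fraction(0, 4, 5), 0)
  expect_equal(bound_fraction(10, 4, 5), 0.603, tolerance = 1e-3)
  # stoichiometric limit: vanishing Kd with protein excess binds all DNA
  expect_equal(bound_fraction(10, 4, 1e-9), 1, tolerance = 1e-4)
  expect_error(bound_fraction(10, 0, 5), class = "smcurtain_undefined_fraction")
  expect_error(bound_fraction(10, 4, 0), class = "smcurtain_invalid_argument")
})

test_that("bound fraction agrees with a brute-force root search", {
  set.seed(20)
  for (i in 1:100) {
    p <- runif(1, 0.1, 100); d <- runif(1, 0.1, 50); kd <- runif(1, 0.1, 100)
    expect_equal(bound_fraction(p, d, kd), bound_fraction_oracle(p, d, kd),
                 tolerance = 1e-10)
  }
})

test_that("fit_kd is exact on noise-free data and rejects uninformative series", {
  ts <- simulate_titration(kd_nM = 5, dna_total_nM = 4, noise_sd = 0)
  fit <- fit_kd(ts)
  expect_equal(fit$kd_nM, 5, tolerance = 1e-6)

  flat <- titration_series(c(0, 1, 2, 3), 4,
                           cbind(free = rep(0.97, 4), `1x` = rep(0.03, 4)))
  expect_error(fit_kd(flat), class = "smcurtain_non_identifiable")
  expect_error(fit_kd(ts[c(1, 2)]), class = "smcurtain_error")
})

test_that("the coupled solver decouples when the protein complex cannot form", {
  p <- equilibrium_params(kd_UX_protein_nM = Inf, totals = c(U = 2, X = 2, D = 10))
  st <- solve_ux(p, "undamaged")
  expect_equal(unname(st$complexes["UX"]), 0)
  expect_equal(unname(st$complexes["UXD"]), 0)
  # without a competitor the solution is the single-protein quadratic
  p0 <- equilibrium_params(kd_UX_protein_nM = Inf, totals = c(U = 2, X = 0, D = 10))
  st0 <- solve_ux(p0, "undamaged")
  expect_equal(unname(st0$complexes["UD"]), bound_fraction(2, 10, 26) * 10,
               tolerance = 1e-8)
  # with X present the only residual effect is competition for DNA
  expect_lt(unname(st$complexes["UD"]), unname(st0$complexes["UD"]))
})

test_that("the coupled solver conserves mass and matches an independent optimizer", {
  set.seed(21)
  for (i in 1:25) {
    p <- equilibrium_params(
      kd_U_und_nM = runif(1, 5, 50), kd_X_und_nM = runif(1, 1, 20),
      kd_UX_protein_nM = runif(1, 0.2, 10),
      totals = c(U = runif(1, 0.5, 20), X = runif(1, 0.5, 20),
                 D = runif(1, 0.5, 20)))
    st <- solve_ux(p, "undamaged")
    cx <- st$complexes
    tot_U <- st$free["U"] + cx["UX"] + cx["UD"] + cx["UXD"]
    tot_X <- st$free["X"] + cx["UX"] + cx["XD"] + cx["UXD"]
    tot_D <- st$free["D"] + cx["UD"] + cx["XD"] + cx["UXD"]
    expect_lt(abs(tot_U - p$totals["U"]) / p$totals["U"], 1e-9)
    expect_lt(abs(tot_X - p$totals["X"]) / p$totals["X"], 1e-9)
    expect_lt(abs(tot_D - p$totals["D"]) / p$totals["D"], 1e-9)
  }

  # independent route: generic quasi-Newton minimization of the squared
  # mass-balance residual, no shared code with the package solver
  p <- equilibrium_params(totals = c(U = 2, X = 2, D = 10))
  k <- smcurtain:::resolve_kds(p, "undamaged")
  obj <- function(lf) {
    u <- exp(lf[1]); x <- exp(lf[2]); d <- exp(lf[3])
    ux <- u * x / k$kP; ud <- u * d / k$kU; xd <- x * d / k$kX
    uxd <- ux * d / k$kUXd
    sum(((c(u + ux + ud + uxd, x + ux + xd + uxd, d + ud + xd + uxd) -
            p$totals) / p$totals)^2)
  }
  opt <- stats::optim(log(c(1, 1, 5)), obj, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-15))
  st <- solve_ux(p, "undamaged")
  expect_equal(unname(st$free), unname(exp(opt$par)), tolerance = 1e-4)
})

test_that("UX complex formation loads U onto DNA but not X", {
  p <- equilibrium_params(totals = c(U = 2, X = 2, D = 10))
  st <- solve_ux(p, "undamaged")
  bound_U <- unname(st$complexes["UD"] + st$complexes["UXD"])
  expect_gt(bound_U, 0.534)  # single-protein quadratic value without X

  ef <- enhancement_fold(p, "undamaged")
  expect_gt(ef$fold_U, 1)
  expect_equal(ef$fold_X, 1, tolerance = 0.05)

  # no partner, no enhancement
  p0 <- equilibrium_params(totals = c(U = 2, X = 0, D = 10))
  expect_equal(enhancement_fold(p0, "undamaged")$fold_U, 1, tolerance = 1e-9)
})

test_that("enhancement is non-increasing in the protein-complex Kd", {
  kps <- c(0.2, 1, 5, 25, 125, Inf)
  fold_at <- function(kp, d_tot) {
    p <- equilibrium_params(kd_UX_protein_nM = kp,
                            totals = c(U = 2, X = 2, D = d_tot))
    enhancement_fold(p, "undamaged")$fold_U
  }
  folds <- vapply(kps, fold_at, numeric(1), d_tot = 10)
  expect_true(all(diff(folds) <= 1e-9))
  # in the non-depleting regime (DNA in vast excess, so competition between
  # the two proteins for DNA vanishes) the infinite-Kd limit is exactly 1
  expect_equal(fold_at(Inf, 1e4), 1, tolerance = 1e-6)
  expect_gt(fold_at(1, 1e4), 1)
})

test_that("asymmetry: the tighter-subunit policy favors U whenever X binds DNA better", {
  set.seed(22)
  for (i in 1:10) {
    kx <- runif(1, 2, 15)
    ku <- kx * runif(1, 1.5, 5)   # X always tighter on undamaged DNA
    p <- equilibrium_params(kd_U_und_nM = ku, kd_X_und_nM = kx,
                            totals = c(U = 2, X = 2, D = 10))
    ef <- enhancement_fold(p, "undamaged")
    expect_gt(ef$fold_U, ef$fold_X)
  }
})

test_that("SPR steady-state fit recovers Kd from the standard ladder", {
  ladder <- c(10, 25, 50, 100, 200, 400, 600)
  ru_true <- 80 * ladder / (120 + ladder)
  set.seed(23)
  errs <- vapply(1:20, function(i) {
    ru <- ru_true * (1 + rnorm(7, 0, 0.03))
    abs(spr_steady_state(ladder, ru)$kd_nM - 120) / 120
  }, numeric(1))
  expect_lt(median(errs), 0.15)

  exact <- spr_steady_state(ladder, ru_true)
  expect_equal(exact$kd_nM, 120, tolerance = 1e-6)
  expect_equal(exact$ru_max / 2, 80 / 2, tolerance = 1e-6) # half-saturation at C = Kd

  expect_warning(spr_steady_state(c(1, 2, 4, 8), 5 * c(1, 2, 4, 8) / 1000),
                 class = "smcurtain_wide_ci")
  expect_error(spr_steady_state(c(1, 2, 3), c(1, 2, 3)),
               class = "smcurtain_invalid_argument")
})
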