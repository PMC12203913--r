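#' Time-averaged mean squared displacement of a trajectory
#'
#' MSD at lag k uses all overlapping ordered pairs
#' `(x[i + k] - x[i])^2, i = 1..n-k`, which maximizes the data available from
#' curtain-length tracks; the pair count per lag is recorded for weighting.
#'
#' @param traj A [curtain_track()].
#' @param max_lag Largest lag in frames (`1 <= max_lag < track length`).
#' @return Object of class `msd_curve`: a data frame with `lag_frames`,
#'   `lag_s`, `msd_kbp2`, `n_pairs`.
#' @export
#' @examples
#' tr <- curtain_track("t", times_s = 0:3, positions_kbp = 0:3)
#' compute_msd(tr, 3)
compute_msd <- function(traj, max_lag) {
  stopifnot(inherits(traj, "curtain_track"))
  n <- length(traj$positions_kbp)
  if (!is_scalar_number(max_lag) || max_lag < 1 || max_lag >= n)
    smc_abort("max_lag must satisfy 1 <= max_lag < track length", "invalid_argument")
  max_lag <- as.integer(max_lag)
  x <- traj$positions_kbp
  dt <- if (n > 1) traj$times_s[2] - traj$times_s[1] else NA_real_
  msd <- vapply(seq_len(max_lag), function(k) mean((x[-seq_len(k)] - x[seq_len(n - k)])^2),
                numeric(1))
  out <- data.frame(lag_frames = seq_len(max_lag),
                    lag_s = seq_len(max_lag) * dt,
                    msd_kbp2 = msd,
                    n_pairs = n - seq_len(max_lag))
  structure(out, class = c("msd_curve", "data.frame"))
}

#' Estimate a diffusion coefficient from an MSD curve
#'
#' Weighted linear fit `MSD = 2 D t + c` over the chosen lags (weights = pair
#' counts), restricted to short lags by default to avoid boundary and
#' censoring bias. `D` is clipped at zero; the intercept estimates twice the
#' localization variance (`2 sigma_loc^2`).
#'
#' @param msd An [compute_msd()] result.
#' @param fit_lags Integer lags (frames) used in the fit; default `1:10`,
#'   intersected with the available lags. At least 2 lags are required.
#' @param extension Extension factor (um/kbp) for unit conversion.
#' @return Object of class `diffusion_estimate`: `D_um2_s`, `D_kbp2_s`,
#'   `intercept_kbp2`, `se_um2_s`, `se_kbp2_s`, `fit_lags`.
#' @export
estimate_D <- function(msd, fit_lags = 1:10, extension = 0.272) {
  stopifnot(inherits(msd, "msd_curve"))
  fit_lags <- intersect(as.integer(fit_lags), msd$lag_frames)
  if (length(fit_lags) < 2L)
    smc_abort("need >= 2 available lags in fit_lags", "invalid_argument")
  sub <- msd[msd$lag_frames %in% fit_lags, ]
  if (max(sub$lag_s) - min(sub$lag_s) <= 0)
    smc_abort("degenerate lag values", "fit_error")
  fit <- stats::lm(msd_kbp2 ~ lag_s, data = sub, weights = sub$n_pairs)
  # exact synthetic MSD curves trigger the "essentially perfect fit" notice
  sl <- suppressWarnings(summary(fit))$coefficients
  slope <- sl["lag_s", "Estimate"]
  slope_se <- sl["lag_s", "Std. Error"]
  d_kbp2 <- max(slope / 2, 0)
  structure(list(
    D_kbp2_s = d_kbp2,
    D_um2_s = kbp2_to_um2(d_kbp2, extension),
    intercept_kbp2 = unname(stats::coef(fit)[1]),
    se_kbp2_s = slope_se / 2,
    se_um2_s = kbp2_to_um2(slope_se / 2, extension),
    fit_lags = fit_lags,
    extension_um_per_kbp = extension
  ), class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("D = %.4g um^2/s (%.4g kbp^2/s), se %.2g, intercept %.3g kbp^2, lags %d-%d\n",
              x$D_um2_s, x$D_kbp2_s, x$se_um2_s, x$intercept_kbp2,
              min(x$fit_lags), max(x$fit_lags)))
  invisible(x)
}

#' Pooled diffusion coefficient over many tracks
#'
#' Per-track MSD fits averaged over molecules, with a bootstrap-over-tracks
#' standard error (per-track D distributions are broad, so the spread between
#' molecules, not the per-fit error, dominates).
#'
#' @param trajs List of [curtain_track()].
#' @param fit_lags,extension Passed to [estimate_D()].
#' @param max_lag Largest lag computed per track.
#' @param n_boot Bootstrap resamples over tracks (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return List with `D_um2_s`, `se_um2_s`, `n_tracks`, `per_track` (vector of
#'   per-track D in um^2/s).
#' @export
estimate_D_tracks <- function(trajs, fit_lags = 1:10, extension = 0.272,
                              max_lag = max(fit_lags), n_boot = 1000,
                              seed = NULL) {
  if (!length(trajs))
    smc_abort("no trajectories", "insufficient_data")
  per <- vapply(trajs, function(tr) {
    if (length(tr$positions_kbp) <= max_lag) return(NA_real_)
    estimate_D(compute_msd(tr, max_lag), fit_lags, extension)$D_um2_s
  }, numeric(1))
  per <- per[!is.na(per)]
  if (!length(per))
    smc_abort("no track long enough for the requested lags", "insufficient_data")
  seed_if(seed)
  boot <- vapply(seq_len(n_boot),
                 function(i) mean(sample(per, length(per), replace = TRUE)),
                 numeric(1))
  list(D_um2_s = mean(per), se_um2_s = stats::sd(boot),
       n_tracks = length(per), per_track = per)
}

#' Gaussian fit to pooled frame-to-frame displacements
#'
#' Pools displacements at the given lag across trajectories, bins them
#' (including empty bins), and least-squares fits a single Gaussian. For pure
#' 1D Brownian motion the center is statistically zero; flow or drift shifts
#' it away.
#'
#' @param trajs List of [curtain_track()] (or a single track).
#' @param lag Lag in frames (default 1).
#' @param n_bins Number of histogram bins; default `max(11, ceiling(sqrt(n)))`.
#' @return List with `center`, `sigma`, `center_se`, `gof` (R^2 of the fit),
#'   `n` (number of displacements), and the binned data.
#' @export
displacement_gaussian <- function(trajs, lag = 1, n_bins = NULL) {
  if (inherits(trajs, "curtain_track")) trajs <- list(trajs)
  disp <- unlist(lapply(trajs, function(tr) {
    x <- tr$positions_kbp
    n <- length(x)
    if (n <= lag) return(numeric(0))
    x[-seq_len(lag)] - x[seq_len(n - lag)]
  }))
  n <- length(disp)
  if (n < 30L)
    smc_abort("need >= 30 pooled displacements", "insufficient_data")
  if (is.null(n_bins)) n_bins <- max(11L, ceiling(sqrt(n)))
  breaks <- seq(min(disp) - 1e-9, max(disp) + 1e-9, length.out = n_bins + 1L)
  h <- graphics::hist(disp, breaks = breaks, plot = FALSE)
  df <- data.frame(x = h$mids, y = h$counts)
  fit <- ls_fit(
    start = list(A = max(df$y), mu = mean(disp),
                 s = max(stats::sd(disp), 1e-6)),
    resid_fn = function(p) df$y - p$A * exp(-(df$x - p$mu)^2 / (2 * p$s^2)),
    lower = c(0, min(disp), 1e-9),
    upper = c(Inf, max(disp), max(disp) - min(disp)))
  ss_tot <- sum((df$y - mean(df$y))^2)
  list(center = unname(fit$par["mu"]),
       sigma = abs(unname(fit$par["s"])),
       center_se = unname(fit$se["mu"]),
       gof = 1 - fit$deviance / ss_tot, n = n, bins = df)
}

#' Classify 1D diffusion as sliding or hopping from a salt series
#'
#' A protein tracking the DNA in continuous contact (sliding) has a
#' salt-insensitive diffusion coefficient, while micro-dissociation (hopping)
#' makes D rise with ionic strength. The call regresses D on salt with
#' measurement-error weights: `"hopping"` when the 95% slope interval excludes
#' zero with positive sign and the fitted relative increase across the range
#' exceeds `rel_threshold`; `"sliding"` when the interval contains zero, the
#' fitted change is below threshold, and the data have the power to exclude an
#' above-threshold increase; otherwise `"inconclusive"`.
#'
#' @param salt_mM Salt concentrations, mM (>= 2 distinct values).
#' @param D_um2_s Diffusion coefficients at each salt.
#' @param se_um2_s Standard errors of each D (used as weights and for the
#'   slope confidence interval); optional but required for two-point designs.
#' @param rel_threshold Relative-change threshold (default 0.25); the boundary
#'   between "flat" and "salt-dependent" is not standardized, so it is exposed.
#' @return List with `mode` (`"sliding"`, `"hopping"`, `"inconclusive"`),
#'   `slope`, `slope_ci`, `rel_change`, `rel_change_ci`.
#' @export
salt_series_call <- function(salt_mM, D_um2_s, se_um2_s = NULL,
                             rel_threshold = 0.25) {
  if (length(unique(salt_mM)) < 2L)
    smc_abort("need >= 2 distinct salt concentrations", "invalid_argument")
  if (length(D_um2_s) != length(salt_mM))
    smc_abort("salt and D lengths differ", "invalid_argument")
  w <- if (is.null(se_um2_s)) rep(1, length(salt_mM)) else 1 / se_um2_s^2
  xb <- sum(w * salt_mM) / sum(w)
  yb <- sum(w * D_um2_s) / sum(w)
  sxx <- sum(w * (salt_mM - xb)^2)
  slope <- sum(w * (salt_mM - xb) * (D_um2_s - yb)) / sxx
  intercept <- yb - slope * xb
  slope_se <- if (is.null(se_um2_s)) {
    # residual-based error; needs residual degrees of freedom
    n <- length(salt_mM)
    if (n <= 2) Inf else sqrt(sum(w * (D_um2_s - intercept - slope * salt_mM)^2) / (n - 2) / sxx)
  } else sqrt(1 / sxx)
  ci <- slope + c(-1, 1) * 1.96 * slope_se
  rng <- range(salt_mM)
  d_lo <- intercept + slope * rng[1]
  span <- diff(rng)
  rel_change <- slope * span / d_lo
  rel_ci <- ci * span / d_lo
  mode <- if (ci[1] > 0 && rel_change > rel_threshold) "hopping"
  else if (ci[1] <= 0 && ci[2] >= 0 && abs(rel_change) <= rel_threshold &&
           rel_ci[2] <= rel_threshold) "sliding"
  else "inconclusive"
  list(mode = mode, slope = slope, slope_ci = ci,
       rel_change = rel_change, rel_change_ci = rel_ci)
}

#' Hydrodynamic parameters for the rotation-coupled diffusion limit
#'
#' @param temperature_K Temperature (default 296.15 K, the 23 C reaction
#'   buffer).
#' @param viscosity_Pa_s Solvent viscosity (default water at 23 C,
#'   9.32e-4 Pa s).
#' @param radius_nm Hydrodynamic radius R of the sliding particle, nm.
#' @param offset_nm Distance R_OC between the particle center and the DNA
#'   helical axis, nm; defaults to `radius_nm`.
#' @param pitch_nm Helical pitch of B-DNA (10.5 bp x 0.34 nm = 3.57 nm).
#' @return Object of class `hydro_params`.
#' @export
hydro_params <- function(temperature_K = 296.15, viscosity_Pa_s = 9.32e-4,
                         radius_nm, offset_nm = radius_nm, pitch_nm = 3.57) {
  vals <- c(temperature_K, viscosity_Pa_s, radius_nm, offset_nm)
  if (any(vals <= 0) || pitch_nm <= 0)
    smc_abort("all hydrodynamic parameters must be positive", "invalid_argument")
  structure(list(temperature_K = temperature_K, viscosity_Pa_s = viscosity_Pa_s,
                 radius_nm = radius_nm, offset_nm = offset_nm,
                 pitch_nm = pitch_nm), class = "hydro_params")
}

#' Theoretical speed limit for rotation-coupled diffusion along DNA
#'
#' Upper bound on the 1D diffusion coefficient of a particle of radius R that
#' tracks the helical groove (one full rotation per pitch p, center offset
#' R_OC from the helix axis):
#' `D_max = kB T / (6 pi eta R * (1 + (4/3) (2 pi / p)^2 R^2 + (2 pi / p)^2 R_OC^2))`.
#' A measured D above this bound implies translation without rotation. As
#' `pitch_nm -> Inf` the bound reduces to the Stokes-Einstein coefficient.
#'
#' @param h A [hydro_params()].
#' @return Maximum diffusion coefficient in um^2/s.
#' @export
#' @examples
#' rotational_limit(hydro_params(radius_nm = 20))
rotational_limit <- function(h) {
  stopifnot(inherits(h, "hydro_params"))
  kB <- 1.380649e-23
  R <- h$radius_nm * 1e-9
  Roc <- h$offset_nm * 1e-9
  wav <- if (is.infinite(h$pitch_nm)) 0 else (2 * pi / (h$pitch_nm * 1e-9))^2
  denom <- 6 * pi * h$viscosity_Pa_s * R * (1 + (4 / 3) * wav * R^2 + wav * Roc^2)
  (kB * h$temperature_K / denom) * 1e12  # m^2/s -> um^2/s
}
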